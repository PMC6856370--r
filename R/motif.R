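#' @include AllClasses.R promoter-io.R
NULL

#' Expand an IUPAC degenerate motif into literal k-mers
#'
#' The Wnt response element (WRE) pattern `WWCAAAG`, i.e. (A/T)(A/T)CAAAG,
#' expands to 4 literal 7-mers on the forward strand; with
#' `bothStrands = TRUE` their reverse complements are added, giving the 8
#' sequences a double-stranded promoter scan must recognise.
#'
#' @param pattern IUPAC nucleotide string.
#' @param bothStrands add reverse complements of the expansions?
#' @return character vector of literal k-mers (deduplicated, sorted).
#' @examples
#' expandMotif("WWCAAAG")                     # 4 variants
#' expandMotif("WWCAAAG", bothStrands = TRUE) # 8 variants
#' @export
expandMotif <- function(pattern, bothStrands = FALSE) {
  pattern <- toupper(pattern)
  codes <- strsplit(pattern, "")[[1]]
  if (length(codes) == 0) stop("empty pattern")
  map <- Biostrings::IUPAC_CODE_MAP
  if (!all(codes %in% names(map)))
    stop("illegal IUPAC code(s): ",
         paste(unique(codes[!codes %in% names(map)]), collapse = ", "))
  perPos <- lapply(map[codes], function(s) strsplit(s, "")[[1]])
  grid <- do.call(expand.grid, c(rev(perPos), stringsAsFactors = FALSE))
  variants <- apply(grid[, rev(seq_along(perPos)), drop = FALSE], 1, paste0,
                    collapse = "")
  if (bothStrands) variants <- union(variants, revcomp(variants))
  sort(unique(variants))
}

#' Construct a degenerate motif object
#'
#' @param pattern IUPAC pattern; the default is the TCF/LEF Wnt response
#'   element 5'-(A/T)(A/T)CAAAG-3'.
#' @return a [DegenerateMotif-class] holding the pattern and the literal
#'   forward and reverse-complement variant sets.
#' @export
wreMotif <- function(pattern = "WWCAAAG") {
  fwd <- expandMotif(pattern, bothStrands = FALSE)
  new("DegenerateMotif", pattern = toupper(pattern),
      forwardVariants = fwd, reverseVariants = sort(revcomp(fwd)))
}

#' Strand overlap of a degenerate motif
#'
#' Variants matched by both strands (palindromic expansions). Empty for the
#' WRE, so its "4 on each strand" sum to 8 distinct sequences.
#'
#' @param motif a [DegenerateMotif-class].
#' @return character vector of shared variants (possibly empty).
#' @export
strandOverlap <- function(motif) {
  intersect(motif@forwardVariants, motif@reverseVariants)
}
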