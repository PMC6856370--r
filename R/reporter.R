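#' @include scan.R promoter-io.R
NULL

# does a 7-mer match the motif on either strand?
.matchesMotif <- function(s, motif) {
  s %in% motif@forwardVariants || revcomp(s) %in% motif@forwardVariants
}

#' Design a WT/mutant promoter reporter insert pair
#'
#' Extracts the reporter window (the published design uses -1635..+86 of the
#' human promoter, a 1,721-base insert), verifies that the 7-mer at
#' `sitePos` matches the motif, and produces the mutant insert by in-place
#' substitution (the published edit replaces `TTCAAAG` at -1587 with
#' `CCGCGGT`). Both inserts are scanned and their hit tables attached.
#' `sitePos` anchors the 7-mer's leftmost base, consistent with
#' [scanPromoter()] coordinates.
#'
#' @param x a [PromoterSet-class]; record `i` supplies the promoter.
#' @param window `c(from, to)` TSS-relative bounds of the insert.
#' @param sitePos TSS-relative position of the site's leftmost base.
#' @param replacement the 7-mer to substitute (must not equal the wild-type
#'   site; a warning is raised if it still matches the motif on either
#'   strand).
#' @param motif a [DegenerateMotif-class].
#' @param name construct label.
#' @param i record index.
#' @return a [ReporterConstruct-class].
#' @export
designReporter <- function(x, window = c(-1635L, 86L), sitePos = -1587L,
                           replacement = "CCGCGGT", motif = wreMotif(),
                           name = "reporter", i = 1L) {
  stopifnot(is(x, "PromoterSet"))
  from <- as.integer(window[1]); to <- as.integer(window[2])
  k <- nchar(motif@pattern)
  wt <- extractWindow(x, from, to, i = i)
  siteEnd <- tssShift(sitePos, k)
  if (sitePos < from || siteEnd > to)
    stop("edit site ", sitePos, " not inside the window ", from, "..", to)
  wtSite <- extractWindow(x, sitePos, siteEnd, i = i)
  if (!.matchesMotif(wtSite, motif))
    stop("no motif match at position ", sitePos, " (found ", wtSite,
         "); refusing to mutate a non-site")
  replacement <- toupper(replacement)
  if (nchar(replacement) != k)
    stop("replacement must be ", k, " bases")
  if (replacement == wtSite)
    stop("no-op replacement: mutant would equal wild type")
  if (.matchesMotif(replacement, motif))
    warning("replacement still matches the motif on one strand")
  off <- tssWindowLength(from, sitePos) # 1-based offset of site in the window
  mut <- wt
  substr(mut, off, off + k - 1L) <- replacement

  # scan both inserts as TSS-anchored records so hit coordinates stay true
  if (from > 0)
    stop("reporter window must start upstream of the TSS")
  u <- tssWindowLength(from, -1L)
  d <- if (to > 0) to else 0L
  mkInfo <- function(iso) data.frame(
    species = x@info$species[i], gene = x@info$gene[i],
    assembly = x@info$assembly[i], isoform_id = iso,
    upstream = u, downstream = d, stringsAsFactors = FALSE)
  wtHits <- scanPromoter(PromoterSet(wt, mkInfo("wt")), motif)
  mutHits <- scanPromoter(PromoterSet(mut, mkInfo("mut")), motif)
  new("ReporterConstruct", name = name,
      windowFrom = from, windowTo = to, wtSeq = wt, mutSeq = mut,
      sitePos = as.integer(sitePos), wtSite = wtSite,
      replacement = replacement, wtHits = wtHits, mutHits = mutHits)
}

#' Validate a reporter construct against its design invariants
#'
#' Checks that the two inserts have equal length and differ only inside the
#' edited 7-mer, that the wild-type 7-mer matches the motif while the
#' replacement does not, and reports the Hamming distance of the edit and
#' the motif hits lost/gained between WT and mutant. Failures are report
#' entries, not errors.
#'
#' @param x a [ReporterConstruct-class].
#' @param motif a [DegenerateMotif-class].
#' @return list with `ok` (logical), `failures` (character), `hamming`
#'   (changed positions within the 7-mer), `hits_lost_at` / `hits_gained_at`
#'   (TSS positions), and `edit_offset` (1-based offset in the insert).
#' @export
validateConstruct <- function(x, motif = wreMotif()) {
  stopifnot(is(x, "ReporterConstruct"))
  failures <- character()
  wt <- strsplit(x@wtSeq, "")[[1]]; mu <- strsplit(x@mutSeq, "")[[1]]
  if (length(wt) != length(mu))
    failures <- c(failures, "wt and mutant lengths differ")
  winLen <- tssWindowLength(x@windowFrom, x@windowTo)
  if (length(wt) != winLen)
    failures <- c(failures, "insert length does not match window")
  k <- nchar(x@wtSite)
  siteEnd <- tssShift(x@sitePos, k)
  inWindow <- x@sitePos >= x@windowFrom && siteEnd <= x@windowTo
  if (!inWindow) failures <- c(failures, "edit outside window")
  off <- if (inWindow) tssWindowLength(x@windowFrom, x@sitePos) else NA_integer_
  diffPos <- which(wt != mu)
  if (length(diffPos) == 0)
    failures <- c(failures, "wt and mutant are identical")
  hamming <- 0L
  if (inWindow && length(diffPos)) {
    inside <- diffPos >= off & diffPos <= off + k - 1L
    if (!all(inside))
      failures <- c(failures, "wt and mutant differ outside the edited 7-mer")
    hamming <- sum(inside)
  } else hamming <- length(diffPos)
  if (!.matchesMotif(x@wtSite, motif))
    failures <- c(failures, "wild-type site does not match the motif")
  if (.matchesMotif(x@replacement, motif))
    failures <- c(failures, "replacement matches the motif")
  key <- function(h) paste(h$position, h$strand)
  lost <- x@wtHits[!key(x@wtHits) %in% key(x@mutHits), , drop = FALSE]
  gained <- x@mutHits[!key(x@mutHits) %in% key(x@wtHits), , drop = FALSE]
  list(ok = length(failures) == 0, failures = failures,
       hamming = as.integer(hamming),
       hits_lost_at = lost$position, hits_gained_at = gained$position,
       edit_offset = off)
}

#' Write a reporter construct as FASTA plus a JSON edit record
#'
#' @param x a [ReporterConstruct-class].
#' @param fastaPath output FASTA (two records: `<name>_WT`, `<name>_Mut`).
#' @param jsonPath optional JSON path for the edit record.
#' @return `fastaPath`, invisibly.
#' @export
writeReporter <- function(x, fastaPath, jsonPath = NULL) {
  seqs <- Biostrings::DNAStringSet(c(x@wtSeq, x@mutSeq))
  names(seqs) <- paste0(x@name, c("_WT", "_Mut"))
  Biostrings::writeXStringSet(seqs, fastaPath)
  if (!is.null(jsonPath)) {
    rec <- list(name = x@name,
                window = c(x@windowFrom, x@windowTo),
                site_pos = x@sitePos, wt_site = x@wtSite,
                replacement = x@replacement,
                wt_hits = x@wtHits$position, mut_hits = x@mutHits$position)
    jsonlite::write_json(rec, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(fastaPath)
}
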