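#' @include motif.R coords.R
NULL

.emptyHits <- function() {
  data.frame(species = character(), isoform_id = character(),
             position = integer(), strand = character(),
             matched_seq = character(), pattern_id = character(),
             stringsAsFactors = FALSE)
}

# scan one sense-oriented sequence; returns start indices/strand/matched 7-mer
.scanOne <- function(seq, motif) {
  subject <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(motif@pattern)
  k <- nchar(motif@pattern)
  if (length(subject) < k)
    return(data.frame(index = integer(), strand = character(),
                      matched_seq = character()))
  # IUPAC codes expanded in the pattern only: N in the subject never matches
  fwd <- Biostrings::matchPattern(pat, subject, fixed = "subject")
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject,
                                  fixed = "subject")
  out <- rbind(
    data.frame(index = Biostrings::start(fwd),
               strand = rep("+", length(fwd)),
               matched_seq = as.character(fwd)),
    data.frame(index = Biostrings::start(rev),
               strand = rep("-", length(rev)),
               matched_seq = revcomp(as.character(rev))))
  out[order(out$index, out$strand), , drop = FALSE]
}

#' Scan promoter records for a degenerate motif on both strands
#'
#' Every k-long window of each sense-oriented record is tested against the
#' motif's forward variants (reported as strand `+`) and, via its reverse
#' complement, against the same variants (strand `-`). Overlapping and nested
#' matches are all reported. Windows containing `N` never match. The reported
#' `position` is the TSS-relative coordinate of the match's leftmost
#' sense-strand base (for both strands); `matched_seq` is the k-mer as read
#' on the matching strand.
#'
#' @param x a [PromoterSet-class].
#' @param motif a [DegenerateMotif-class] (default: the WRE).
#' @return a hit data.frame with columns `species`, `isoform_id`, `position`,
#'   `strand`, `matched_seq`, `pattern_id`, sorted by record then
#'   (position, strand).
#' @export
scanPromoter <- function(x, motif = wreMotif()) {
  stopifnot(is(x, "PromoterSet"))
  inf <- x@info
  res <- lapply(seq_len(length(x)), function(i) {
    h <- .scanOne(as.character(x@sequences[[i]]), motif)
    if (nrow(h) == 0) return(.emptyHits())
    data.frame(species = inf$species[i], isoform_id = inf$isoform_id[i],
               position = as.integer(indexToTss(h$index, inf$upstream[i])),
               strand = h$strand, matched_seq = h$matched_seq,
               pattern_id = motif@pattern, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(.emptyHits())))
  rownames(out) <- NULL
  out
}

#' Per-species motif hits, deduplicated over isoform variants
#'
#' Scans all isoforms of every species and takes the union of hits per
#' species, deduplicated by (species, position, strand); the `isoforms`
#' column records which isoforms contributed each hit.
#'
#' @param x a [PromoterSet-class] (possibly several isoforms per species).
#' @param motif a [DegenerateMotif-class].
#' @return data.frame with columns `species`, `position`, `strand`,
#'   `matched_seq`, `pattern_id`, `isoforms`, `n_isoforms`.
#' @export
scanSpecies <- function(x, motif = wreMotif()) {
  if (length(x) == 0) stop("empty record set")
  hits <- scanPromoter(x, motif)
  if (nrow(hits) == 0)
    return(data.frame(species = character(), position = integer(),
                      strand = character(), matched_seq = character(),
                      pattern_id = character(), isoforms = character(),
                      n_isoforms = integer(), stringsAsFactors = FALSE))
  key <- interaction(hits$species, hits$position, hits$strand, drop = TRUE)
  agg <- lapply(split(hits, key), function(g) {
    data.frame(species = g$species[1], position = g$position[1],
               strand = g$strand[1], matched_seq = g$matched_seq[1],
               pattern_id = g$pattern_id[1],
               isoforms = paste(sort(unique(g$isoform_id)), collapse = ","),
               n_isoforms = length(unique(g$isoform_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$species, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hit table as TSV
#'
#' @param hits a hit data.frame from [scanPromoter()] or [scanSpecies()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
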