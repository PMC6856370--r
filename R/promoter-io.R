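#' @include AllClasses.R coords.R
NULL

#' Construct a PromoterSet
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] of
#'   sense-oriented promoter windows.
#' @param info data.frame with columns `species`, `gene`, `assembly`,
#'   `isoform_id`, `upstream`, `downstream` (one row per sequence).
#' @return a validated [PromoterSet-class].
#' @examples
#' PromoterSet("CCTTCAAA",
#'             data.frame(species = "human", gene = "WNT3A", assembly = "hg19",
#'                        isoform_id = "iso1", upstream = 8, downstream = 0))
#' @export
PromoterSet <- function(sequences, info) {
  seqs <- Biostrings::DNAStringSet(sequences)
  info$upstream <- as.integer(info$upstream)
  info$downstream <- as.integer(info$downstream)
  rownames(info) <- NULL
  names(seqs) <- paste(info$species, info$gene, info$isoform_id, sep = "|")
  new("PromoterSet", sequences = seqs, info = info)
}

.parseHeaderMeta <- function(headers) {
  # header convention: species|gene|isoform|U=<int>|D=<int> (assembly optional
  # as a 6th field); used when no manifest is supplied.
  parts <- strsplit(headers, "|", fixed = TRUE)
  one <- function(p, h) {
    if (length(p) < 5)
      stop("FASTA header not in species|gene|isoform|U=..|D=.. form: ", h)
    u <- grep("^U=", p, value = TRUE); d <- grep("^D=", p, value = TRUE)
    if (length(u) != 1 || length(d) != 1)
      stop("missing U=/D= fields in header: ", h)
    asm <- setdiff(p[-(1:3)], c(u, d))
    data.frame(species = p[1], gene = p[2], isoform_id = p[3],
               assembly = if (length(asm)) asm[1] else NA_character_,
               upstream = as.integer(sub("^U=", "", u)),
               downstream = as.integer(sub("^D=", "", d)))
  }
  do.call(rbind, Map(one, parts, headers))
}

#' Read TSS-anchored promoter windows from FASTA
#'
#' Record metadata (species, gene, isoform, upstream/downstream extents) comes
#' either from a TSV manifest keyed by the FASTA record names, or from headers
#' of the form `species|gene|isoform|U=5000|D=0`. Each record is validated:
#' its length must equal `upstream + downstream` and its alphabet is
#' restricted to A/C/G/T/N.
#'
#' @param path FASTA file of promoter windows, sense-oriented, TSS-anchored.
#' @param manifest optional path to a TSV with columns `name` (FASTA record
#'   name), `species`, `gene`, `assembly`, `isoform_id`, `upstream`,
#'   `downstream`; or a data.frame of the same shape.
#' @return a [PromoterSet-class].
#' @export
readPromoterFasta <- function(path, manifest = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  hdr <- names(seqs)
  if (is.null(manifest)) {
    info <- .parseHeaderMeta(hdr)
  } else {
    man <- if (is.data.frame(manifest)) manifest else
      utils::read.delim(manifest, stringsAsFactors = FALSE)
    req <- c("name", "species", "gene", "assembly", "isoform_id",
             "upstream", "downstream")
    if (!all(req %in% names(man)))
      stop("manifest must have columns: ", paste(req, collapse = ", "))
    first <- vapply(strsplit(hdr, "\\s+"), `[`, "", 1L)
    idx <- match(first, man$name)
    if (anyNA(idx))
      stop("manifest missing record(s): ",
           paste(first[is.na(idx)], collapse = ", "))
    info <- man[idx, setdiff(req, "name"), drop = FALSE]
  }
  PromoterSet(seqs, info)
}

#' Write a PromoterSet as FASTA (+ optional manifest TSV)
#'
#' @param x a [PromoterSet-class].
#' @param path output FASTA path.
#' @param manifest optional path for a TSV manifest sidecar.
#' @return `path`, invisibly.
#' @export
writePromoterFasta <- function(x, path, manifest = NULL) {
  seqs <- x@sequences
  inf <- x@info
  names(seqs) <- paste0(inf$species, "|", inf$gene, "|", inf$isoform_id,
                        "|U=", inf$upstream, "|D=", inf$downstream)
  Biostrings::writeXStringSet(seqs, path)
  if (!is.null(manifest)) {
    man <- cbind(name = names(seqs), inf)
    utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Construct an AlignedPromoterSet
#'
#' @param alignment named character vector or gapped
#'   [Biostrings::DNAStringSet]; names are species labels.
#' @param upstream,downstream integer vectors (recycled) giving each member's
#'   TSS window extents; the degapped member length must equal their sum.
#' @return an [AlignedPromoterSet-class].
#' @export
AlignedPromoterSet <- function(alignment, upstream, downstream = 0L) {
  aln <- Biostrings::DNAStringSet(alignment)
  n <- length(aln)
  u <- as.integer(rep_len(upstream, n)); d <- as.integer(rep_len(downstream, n))
  names(u) <- names(d) <- names(aln)
  new("AlignedPromoterSet", alignment = aln, upstream = u, downstream = d)
}

#' Read a gapped promoter alignment and check it against its source records
#'
#' Degapping every member must reproduce that species' ungapped promoter
#' window in `records` (one record per species is used; isoforms beyond the
#' first are ignored for alignment purposes).
#'
#' @param path aligned (gapped) FASTA; record names are species labels.
#' @param records a [PromoterSet-class] giving the ungapped sources, or NULL
#'   to skip the round-trip check (window extents then default to the
#'   degapped length, all upstream).
#' @return an [AlignedPromoterSet-class].
#' @export
readAlignedFasta <- function(path, records = NULL) {
  aln <- Biostrings::readDNAStringSet(path)
  names(aln) <- vapply(strsplit(names(aln), "\\s+"), `[`, "", 1L)
  gapless <- gsub("-", "", as.character(aln), fixed = TRUE)
  if (is.null(records))
    return(AlignedPromoterSet(aln, upstream = nchar(gapless), downstream = 0L))
  inf <- promoterInfo(records)
  idx <- match(names(aln), inf$species)
  if (anyNA(idx))
    stop("alignment species absent from records: ",
         paste(names(aln)[is.na(idx)], collapse = ", "))
  src <- as.character(promoterSeqs(records))[idx]
  bad <- which(gapless != src)
  if (length(bad))
    stop("degapped alignment member does not reproduce its promoter record: ",
         paste(names(aln)[bad], collapse = ", "))
  AlignedPromoterSet(aln, upstream = inf$upstream[idx],
                     downstream = inf$downstream[idx])
}

#' Extract an inclusive TSS-relative window from a promoter record
#'
#' Bounds follow the no-zero convention: -1 abuts +1, both bounds inclusive.
#' A window with bounds of the same sign spans `to - from + 1` bases; one that
#' straddles the TSS spans `to - from` (position 0 is skipped). The span
#' -1635..+86 therefore has length 1721.
#'
#' @param x a [PromoterSet-class].
#' @param i record index (default 1).
#' @param from,to signed TSS-relative bounds, neither 0, within the record.
#' @return the window as an uppercase DNA character string.
#' @export
extractWindow <- function(x, from, to, i = 1L) {
  stopifnot(is(x, "PromoterSet"))
  inf <- x@info[i, ]
  len <- tssWindowLength(from, to)  # validates no-zero, ordering
  iFrom <- tssToIndex(from, inf$upstream, inf$downstream)
  iTo <- tssToIndex(to, inf$upstream, inf$downstream)
  s <- substr(as.character(x@sequences[[i]]), iFrom, iTo)
  stopifnot(nchar(s) == len)
  s
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; N maps to N. Accepts a character vector.
#'
#' @param x character vector over A/C/G/T/N (case-insensitive).
#' @return reverse-complemented character vector.
#' @examples
#' revcomp("TTCAAAG")  # "CTTTGAA"
#' @export
revcomp <- function(x) {
  ok <- grepl("^[ACGTNacgtn]*$", x)
  if (!all(ok)) stop("illegal character in DNA string")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}
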