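#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString
NULL

PROMOTER_ALPHABET <- c("A", "C", "G", "T", "N")

.checkAlphabet <- function(seqs) {
  freq <- Biostrings::alphabetFrequency(seqs)
  legal <- colnames(freq) %in% PROMOTER_ALPHABET
  bad <- rowSums(freq[, !legal, drop = FALSE]) > 0
  if (any(bad))
    return(paste0("illegal characters (outside A/C/G/T/N) in record(s): ",
                  paste(which(bad), collapse = ", ")))
  NULL
}

#' PromoterSet: TSS-anchored promoter windows
#'
#' A set of promoter records, one per species/isoform. Each sequence is stored
#' 5'->3' in the gene's sense orientation and anchored at the transcriptional
#' start site: with `upstream = U` and `downstream = D` bases the sequence has
#' length `U + D` and covers TSS-relative positions `-U..-1, +1..+D` (there is
#' no position 0). The `info` data.frame carries one row per record with
#' columns `species`, `gene`, `assembly`, `isoform_id`, `upstream`,
#' `downstream`.
#'
#' @slot sequences a [Biostrings::DNAStringSet] over the alphabet A/C/G/T/N.
#' @slot info per-record metadata data.frame (see above).
#' @export
setClass("PromoterSet",
         representation(sequences = "DNAStringSet", info = "data.frame"))

setValidity("PromoterSet", function(object) {
  req <- c("species", "gene", "assembly", "isoform_id", "upstream", "downstream")
  if (!all(req %in% names(object@info)))
    return(paste("info must have columns:", paste(req, collapse = ", ")))
  if (nrow(object@info) != length(object@sequences))
    return("info rows and sequences differ in number")
  u <- object@info$upstream; d <- object@info$downstream
  if (any(u < 0) || any(d < 0)) return("upstream/downstream must be >= 0")
  if (any(u + d < 1)) return("upstream + downstream must be >= 1")
  w <- Biostrings::width(object@sequences)
  if (any(w != u + d))
    return(paste0("length mismatch: sequence width must equal upstream + downstream ",
                  "(records: ", paste(which(w != u + d), collapse = ", "), ")"))
  msg <- .checkAlphabet(object@sequences)
  if (!is.null(msg)) return(msg)
  TRUE
})

#' AlignedPromoterSet: a gapped cross-species promoter alignment
#'
#' Gapped (aligned) promoter sequences, one member per species, all of
#' identical column count. Removing the gaps from a member must reproduce that
#' species' ungapped promoter window, whose TSS anchoring is carried in the
#' `upstream`/`downstream` vectors (named by species).
#'
#' @slot alignment gapped [Biostrings::DNAStringSet], names are species labels.
#' @slot upstream,downstream named integer vectors, one entry per member.
#' @export
setClass("AlignedPromoterSet",
         representation(alignment = "DNAStringSet",
                        upstream = "integer", downstream = "integer"))

setValidity("AlignedPromoterSet", function(object) {
  n <- length(object@alignment)
  if (n < 1) return("empty alignment")
  if (is.null(names(object@alignment))) return("members must be named by species")
  if (anyDuplicated(names(object@alignment))) return("duplicate species names")
  w <- Biostrings::width(object@alignment)
  if (length(unique(w)) != 1)
    return("all gapped members must have identical length")
  if (!identical(names(object@upstream), names(object@alignment)) ||
      !identical(names(object@downstream), names(object@alignment)))
    return("upstream/downstream must be named like the alignment members")
  freq <- Biostrings::alphabetFrequency(object@alignment)
  legal <- colnames(freq) %in% c(PROMOTER_ALPHABET, "-")
  if (any(rowSums(freq[, !legal, drop = FALSE]) > 0))
    return("alignment members restricted to A/C/G/T/N/-")
  ungapped <- w - freq[, "-"]
  if (any(ungapped != object@upstream + object@downstream))
    return("degapped member length must equal upstream + downstream")
  TRUE
})

#' DegenerateMotif: an IUPAC motif and its literal expansions
#'
#' @slot pattern IUPAC nucleotide string (default WRE pattern "WWCAAAG").
#' @slot forwardVariants literal expansions of the pattern.
#' @slot reverseVariants reverse complements of the forward variants.
#' @export
setClass("DegenerateMotif",
         representation(pattern = "character",
                        forwardVariants = "character",
                        reverseVariants = "character"))

setValidity("DegenerateMotif", function(object) {
  if (length(object@pattern) != 1 || nchar(object@pattern) < 1)
    return("pattern must be a single nonempty string")
  if (length(object@forwardVariants) < 1) return("no forward variants")
  if (length(object@reverseVariants) != length(object@forwardVariants))
    return("forward and reverse variant sets differ in size")
  TRUE
})

#' DistanceMatrix: pairwise evolutionary distances
#'
#' Symmetric matrix of pairwise distances in substitutions/site plus the
#' number of alignment columns retained by the deletion step. Pairs whose
#' divergence saturates the estimator (e.g. p >= 3/4 under Jukes-Cantor) are
#' NA in `d` and flagged in `saturated`.
#'
#' @slot d symmetric numeric matrix, taxa in dimnames.
#' @slot usableSites columns retained after gap/missing-data deletion.
#' @slot model the distance model used.
#' @slot saturated logical matrix flagging saturated pairs.
#' @export
setClass("DistanceMatrix",
         representation(d = "matrix", usableSites = "integer",
                        model = "character", saturated = "matrix"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  if (nrow(d) != ncol(d)) return("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("taxa dimnames required and must match")
  if (any(diag(d) != 0, na.rm = TRUE)) return("diagonal must be zero")
  if (!isTRUE(all.equal(d, t(d)))) return("matrix must be symmetric")
  if (any(d < 0, na.rm = TRUE)) return("distances must be >= 0")
  TRUE
})

#' ConservedSiteSet: cross-species conserved-site clusters
#'
#' The result of clustering per-species motif hits into putative orthologous
#' sites. `clusters` has one row per cluster (cluster_id, start_col, end_col,
#' n_species_present, conserved, present_species, absent_species);
#' `members` is a parallel list of per-cluster data.frames holding every hit
#' assigned to the cluster with its column interval; the `representative`
#' column marks the single hit chosen per species.
#'
#' @slot clusters per-cluster summary data.frame.
#' @slot members list of per-cluster member data.frames.
#' @slot species all species considered.
#' @slot minSpecies the conservation threshold m.
#' @slot method "alignment" or "positional".
#' @export
setClass("ConservedSiteSet",
         representation(clusters = "data.frame", members = "list",
                        species = "character", minSpecies = "integer",
                        method = "character"))

setValidity("ConservedSiteSet", function(object) {
  if (nrow(object@clusters) != length(object@members))
    return("clusters and members out of sync")
  for (i in seq_along(object@members)) {
    mem <- object@members[[i]]
    sp <- mem$species[mem$representative]
    if (anyDuplicated(sp))
      return("at most one representative hit per species per cluster")
    if (!all(mem$species %in% object@species))
      return("member species outside species set")
  }
  TRUE
})

#' ReporterConstruct: a WT/mutant promoter reporter insert pair
#'
#' @slot name construct label.
#' @slot windowFrom,windowTo TSS-relative window bounds (inclusive, no 0).
#' @slot wtSeq,mutSeq the insert sequences (equal length).
#' @slot sitePos TSS-relative position of the edited 7-mer's leftmost base.
#' @slot wtSite,replacement the wild-type 7-mer and its replacement.
#' @slot wtHits,mutHits motif hit tables for the two inserts.
#' @export
setClass("ReporterConstruct",
         representation(name = "character",
                        windowFrom = "integer", windowTo = "integer",
                        wtSeq = "character", mutSeq = "character",
                        sitePos = "integer",
                        wtSite = "character", replacement = "character",
                        wtHits = "data.frame", mutHits = "data.frame"))

setValidity("ReporterConstruct", function(object) {
  if (nchar(object@wtSeq) != nchar(object@mutSeq))
    return("wt and mutant inserts must have equal length")
  if (nchar(object@wtSite) != nchar(object@replacement))
    return("site and replacement must have equal length")
  TRUE
})

#' SimulationTruth: ground truth for a simulated promoter set
#'
#' @slot tree the true phylogeny (ape "phylo") with branch lengths in
#'   substitutions/site.
#' @slot seed the RNG seed used.
#' @slot plantedSites data.frame (position, wre, retained, lost) of planted
#'   WRE sites; `retained`/`lost` are comma-joined species lists.
#' @slot model substitution model name.
#' @slot params model parameters.
#' @slot length simulated promoter length (bases).
#' @export
setClass("SimulationTruth",
         representation(tree = "ANY", seed = "integer",
                        plantedSites = "data.frame", model = "character",
                        params = "list", length = "integer"))
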