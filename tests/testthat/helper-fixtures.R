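# Fixtures and independent oracles shared across the suite. The oracles are
# deliberately naive (explicit loops, literal-string comparisons, brute-force
# enumeration) so they stay independent of the implementation they check.

BASES <- c("A", "C", "G", "T")

makePromoters <- function(seqs, upstream, downstream = 0,
                          species = paste0("sp", seq_along(seqs)),
                          gene = "WNT3A", assembly = "sim",
                          isoform = "iso1") {
  PromoterSet(seqs, data.frame(
    species = species, gene = gene, assembly = assembly,
    isoform_id = rep_len(isoform, length(seqs)),
    upstream = rep_len(upstream, length(seqs)),
    downstream = rep_len(downstream, length(seqs)),
    stringsAsFactors = FALSE))
}

randomSeq <- function(L, withN = FALSE) {
  alpha <- if (withN) c(BASES, "N") else BASES
  prob <- if (withN) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  paste(sample(alpha, L, replace = TRUE, prob = prob), collapse = "")
}

# naive complement table, independent of Biostrings
naiveRevcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive double-strand scan: tests each of the literal variants at every
# offset of the sense sequence; positions are TSS-relative leftmost bases
naiveScan <- function(seq, upstream, fwdVariants) {
  k <- nchar(fwdVariants[1])
  L <- nchar(seq)
  out <- data.frame(position = integer(), strand = character(),
                    matched_seq = character(), stringsAsFactors = FALSE)
  if (L < k) return(out)
  for (i in seq_len(L - k + 1)) {
    win <- substr(seq, i, i + k - 1)
    pos <- if (i <= upstream) i - upstream - 1L else i - upstream
    if (win %in% fwdVariants)
      out[nrow(out) + 1L, ] <- list(pos, "+", win)
    rcwin <- naiveRevcomp(win)
    if (rcwin %in% fwdVariants)
      out[nrow(out) + 1L, ] <- list(pos, "-", rcwin)
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

# random additive distance matrix realized on a random unrooted binary tree
randomAdditive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.1, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
}

# canonical bipartition labels and branch lengths of an unrooted tree,
# computed by a hand-rolled tip-descendant recursion (independent of ape's
# split machinery)
edgeSplits <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    side <- sort(desc(tree$edge[e, 2]))
    comp <- sort(setdiff(tree$tip.label, side))
    a <- paste(side, collapse = ","); b <- paste(comp, collapse = ",")
    key <- if (a < b) paste(a, "|", b) else paste(b, "|", a)
    out[[key]] <- max(out[[key]] %||% 0, 0) + tree$edge.length[e]
  }
  unlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical key for the bipartition separating `side` from the rest
splitKey <- function(tips, side) {
  a <- paste(sort(side), collapse = ",")
  b <- paste(sort(setdiff(tips, side)), collapse = ",")
  if (a < b) paste(a, "|", b) else paste(b, "|", a)
}

# standard five-species synthetic design shared by conservation tests
simulateStudy <- function(seed, L = 5000, lost = "rat", position = -1413,
                          wre = "TTCAAAG", nIsoforms = 1) {
  simulatePromoters(defaultSpeciesTree(), L,
                    plantedSites = data.frame(position = position, wre = wre,
                                              lost = lost,
                                              stringsAsFactors = FALSE),
                    seed = seed, nIsoforms = nIsoforms)
}
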