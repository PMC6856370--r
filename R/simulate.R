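#' @include nj.R motif.R
NULL

#' Default five-species trees used by the simulators
#'
#' Both trees share the vertebrate topology (primate, two rodents, bird,
#' fish) with branch lengths in substitutions/site; they differ in scale
#' because promoters and exons diverge at very different rates.
#'
#' `defaultSpeciesTree()` is the promoter-simulation truth: neutral-scale
#' branch lengths (human-zebrafish path 1.5 substitutions/site), so that
#' background motif occurrences decay across clades and only deliberately
#' planted sites are shared by most species — the regime a cross-species
#' promoter conservation scan assumes.
#'
#' `defaultExonTree()` is the protein-coding-scale counterpart for exon
#' simulation, with a branch-length sum of 0.645 matching the scale reported
#' for five-species Wnt3a coding regions.
#'
#' @return an [ape::phylo] with 5 tips.
#' @export
defaultSpeciesTree <- function() {
  ape::read.tree(text = paste0(
    "(((human:0.15,(mouse:0.10,rat:0.10):0.10):0.25,",
    "chicken:0.55):0.20,zebrafish:0.90);"))
}

#' @rdname defaultSpeciesTree
#' @export
defaultExonTree <- function() {
  ape::read.tree(text = paste0(
    "(((human:0.045,(mouse:0.03,rat:0.03):0.035):0.065,",
    "chicken:0.135):0.055,zebrafish:0.25);"))
}

# per-branch 4x4 transition matrix for a branch of length t (subs/site)
.branchPmat <- function(t, model, params) {
  if (model == "JC") {
    same <- 0.25 + 0.75 * exp(-4 * t / 3)
    P <- matrix((1 - same) / 3, 4, 4)
    diag(P) <- same
    dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
    P
  } else if (model == "TN93") {
    eig <- .tn93Eigen(params$kappa[1], params$kappa[2], params$freqs)
    P <- .tn93Pmat(eig, t)
    dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
    P
  } else stop("unknown model: ", model)
}

.rootFreqs <- function(model, params) {
  if (model == "JC") rep(0.25, 4) else params$freqs
}

# evolve integer-coded sequences (1..4) down the tree; returns matrix
# (tips x sites)
.evolveAlongTree <- function(tree, L, model, params) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  seqAt <- vector("list", nt + tree$Nnode)
  pr <- .rootFreqs(model, params)
  seqAt[[root]] <- sample.int(4L, L, replace = TRUE, prob = pr)
  ord <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    t <- ord$edge.length[e]
    par <- seqAt[[parent]]
    if (t <= 0) { seqAt[[child]] <- par; next }
    P <- .branchPmat(t, model, params)
    child_seq <- integer(L)
    for (b in 1:4) {
      idx <- which(par == b)
      if (length(idx))
        child_seq[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                     prob = P[b, ])
    }
    seqAt[[child]] <- child_seq
  }
  tips <- do.call(rbind, seqAt[seq_len(nt)])
  rownames(tips) <- tree$tip.label
  tips
}

.codesToString <- function(v) {
  paste(c("A", "C", "G", "T")[v], collapse = "")
}

#' Simulate promoter evolution along a known tree with planted WRE sites
#'
#' Root sequences are drawn iid (uniform over A/C/G/T under JC, from the
#' stationary frequencies under TN93) and each site evolves independently
#' down the tree, with per-branch substitution probabilities determined by
#' the branch length in substitutions/site. After evolution each planted
#' site is overwritten: species retaining the site receive the designated
#' WRE 7-mer, species losing it receive a non-matching replacement
#' (`CCGCGGT` by default). Sites are thus "frozen", making conservation
#' recovery deterministic; `decaying = TRUE` instead plants the motif in the
#' root before evolution and lets it drift. The simulation is indel-free, so
#' the trivially-true gap-free alignment is returned alongside, and it is
#' fully reproducible from the seed (one global RNG stream per run).
#'
#' @param tree an [ape::phylo] with branch lengths in substitutions/site;
#'   tips are species labels.
#' @param length promoter length L in bases (all upstream: positions -L..-1).
#' @param plantedSites data.frame with columns `position` (TSS-relative
#'   leftmost base of the 7-mer, negative), `wre` (the literal variant to
#'   plant, must match the motif), and `lost` (comma-joined species losing
#'   the site; "" for none). Planted sites must be >= 7 bases apart.
#' @param model `"JC"` or `"TN93"`.
#' @param params for TN93: `list(kappa = c(k1, k2), freqs = c(A,C,G,T))`.
#' @param seed integer RNG seed.
#' @param nIsoforms isoform duplicates emitted per species (identical
#'   windows with distinct isoform ids), emulating multi-isoform promoter
#'   annotations.
#' @param replacement 7-mer written into losing species.
#' @param decaying plant at the root and let sites drift instead of
#'   overwriting tips (no deterministic recovery).
#' @param gene,assembly metadata labels for the emitted records.
#' @param motif the [DegenerateMotif-class] the `wre` column must match.
#' @return list with `records` ([PromoterSet-class]), `aligned`
#'   ([AlignedPromoterSet-class], gap-free), and `truth`
#'   ([SimulationTruth-class]).
#' @export
simulatePromoters <- function(tree, length, plantedSites = NULL,
                              model = "JC", params = list(), seed = 1L,
                              nIsoforms = 1L, replacement = "CCGCGGT",
                              decaying = FALSE, gene = "WNT3A",
                              assembly = "sim1", motif = wreMotif()) {
  set.seed(as.integer(seed))
  L <- as.integer(length)
  species <- tree$tip.label
  if (!is.null(plantedSites) && nrow(plantedSites)) {
    ps <- plantedSites[order(plantedSites$position), , drop = FALSE]
    if (any(ps$position > -1 | ps$position < -L + 6L))
      stop("planted site outside the promoter window")
    if (nrow(ps) > 1 && any(diff(ps$position) < 7L))
      stop("overlapping planted sites (must be >= 7 bases apart)")
    bad <- !(ps$wre %in% motif@forwardVariants)
    if (any(bad)) stop("planted sequence does not match the motif: ",
                       paste(ps$wre[bad], collapse = ", "))
  } else {
    ps <- data.frame(position = integer(), wre = character(),
                     lost = character(), stringsAsFactors = FALSE)
  }

  tips <- .evolveAlongTree(tree, L, model, params)

  baseIdx <- function(pos) pos + L + 1L  # D = 0: index of TSS position `pos`
  code <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  if (decaying && nrow(ps)) {
    # decay mode: evolution already ran from a random root; re-run with the
    # motif planted in the root instead
    set.seed(as.integer(seed))
    pr <- .rootFreqs(model, params)
    rootSeq <- sample.int(4L, L, replace = TRUE, prob = pr)
    for (r in seq_len(nrow(ps)))
      rootSeq[baseIdx(ps$position[r]) + 0:6] <- code(ps$wre[r])
    tips <- .evolveFromRoot(tree, rootSeq, model, params)
  } else if (nrow(ps)) {
    for (r in seq_len(nrow(ps))) {
      lost <- strsplit(ps$lost[r], ",")[[1]]
      lost <- lost[nzchar(lost)]
      unknown <- setdiff(lost, species)
      if (length(unknown)) stop("losing species not in tree: ",
                                paste(unknown, collapse = ", "))
      idx <- baseIdx(ps$position[r]) + 0:6
      for (sp in species) {
        tips[sp, idx] <- if (sp %in% lost) code(replacement) else code(ps$wre[r])
      }
    }
  }

  seqs <- apply(tips, 1, .codesToString)
  nIso <- as.integer(nIsoforms)
  info <- data.frame(
    species = rep(species, each = nIso), gene = gene, assembly = assembly,
    isoform_id = paste0("iso", rep(seq_len(nIso), times = length(species))),
    upstream = L, downstream = 0L, stringsAsFactors = FALSE)
  records <- PromoterSet(rep(seqs, each = nIso), info)
  aligned <- AlignedPromoterSet(seqs, upstream = L, downstream = 0L)
  retained <- vapply(seq_len(nrow(ps)), function(r) {
    lost <- strsplit(ps$lost[r], ",")[[1]]
    paste(sort(setdiff(species, lost)), collapse = ",")
  }, character(1))
  truth <- new("SimulationTruth", tree = tree, seed = as.integer(seed),
               plantedSites = cbind(ps, retained = retained),
               model = model, params = params, length = L)
  list(records = records, aligned = aligned, truth = truth)
}

# re-run evolution from a fixed root sequence (decaying-site mode)
.evolveFromRoot <- function(tree, rootSeq, model, params) {
  nt <- length(tree$tip.label)
  L <- length(rootSeq)
  seqAt <- vector("list", nt + tree$Nnode)
  seqAt[[nt + 1L]] <- rootSeq
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    t <- ord$edge.length[e]
    par <- seqAt[[parent]]
    if (t <= 0) { seqAt[[child]] <- par; next }
    P <- .branchPmat(t, model, params)
    cs <- integer(L)
    for (b in 1:4) {
      idx <- which(par == b)
      if (length(idx))
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
    seqAt[[child]] <- cs
  }
  tips <- do.call(rbind, seqAt[seq_len(nt)])
  rownames(tips) <- tree$tip.label
  tips
}

#' Simulate an exon alignment along a known tree
#'
#' As [simulatePromoters()] without site planting: an indel-free alignment
#' for exercising the distance/tree stage. Optionally masks random positions
#' to `N` and overwrites random columns with gap characters (in one random
#' member each) so that complete deletion has work to do.
#'
#' @param tree an [ape::phylo] with branch lengths in substitutions/site.
#' @param length alignment length in columns before masking.
#' @param model,params substitution model as in [simulatePromoters()].
#' @param seed integer RNG seed.
#' @param gapColumns number of distinct columns to puncture with a gap.
#' @param nColumns number of distinct columns to mask to N.
#' @return list with `alignment` (named character vector of gapped
#'   sequences), `truth` ([SimulationTruth-class]), and `maskedColumns`
#'   (sorted indices of punctured columns).
#' @export
simulateExons <- function(tree, length, model = "JC", params = list(),
                          seed = 1L, gapColumns = 0L, nColumns = 0L) {
  set.seed(as.integer(seed))
  L <- as.integer(length)
  tips <- .evolveAlongTree(tree, L, model, params)
  chars <- matrix(c("A", "C", "G", "T")[tips], nrow = nrow(tips),
                  dimnames = list(rownames(tips), NULL))
  nMask <- as.integer(gapColumns) + as.integer(nColumns)
  masked <- integer(0)
  if (nMask > 0) {
    if (nMask > L) stop("more masked columns than columns")
    masked <- sample.int(L, nMask)
    gapCols <- masked[seq_len(gapColumns)]
    nCols <- masked[-seq_len(gapColumns)]
    if (gapColumns == 0L) { gapCols <- integer(0); nCols <- masked }
    for (cc in gapCols)
      chars[sample.int(nrow(chars), 1L), cc] <- "-"
    for (cc in nCols)
      chars[sample.int(nrow(chars), 1L), cc] <- "N"
  }
  aln <- apply(chars, 1, paste, collapse = "")
  truth <- new("SimulationTruth", tree = tree, seed = as.integer(seed),
               plantedSites = data.frame(position = integer(),
                                         wre = character(),
                                         lost = character(),
                                         retained = character()),
               model = model, params = params, length = L)
  list(alignment = aln, truth = truth, maskedColumns = sort(masked))
}

#' Write a (gapped) named sequence set as FASTA
#'
#' @param seqs named character vector (gaps allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignedFasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  invisible(path)
}
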