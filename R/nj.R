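#' @include distances.R
NULL

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)` (with `R` the row sums over the `r`
#' active nodes) is joined; branch lengths follow the standard formulas
#' `l(i) = d(i,j)/2 + (R(i) - R(j)) / (2(r-2))`, and distances to the new
#' node are `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. The final three-taxon
#' star is resolved exactly by the three-point formulas, yielding an unrooted
#' tree whose internal nodes have degree 3. Ties on Q are broken
#' deterministically by the smallest `(i, j)` index pair in the current node
#' order. Negative branch lengths are clamped to 0; the pre-clamp values are
#' attached as the `"raw_negative"` attribute. Two taxa at distance `d` yield
#' the degenerate tree `(A:d/2, B:d/2)` so that both the leaf-to-leaf path
#' and the branch-length sum equal `d`.
#'
#' @param D a [DistanceMatrix-class] or a symmetric numeric matrix with taxa
#'   dimnames.
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(D) {
  d <- if (is(D, "DistanceMatrix")) D@d else as.matrix(D)
  if (any(!is.finite(d))) stop("non-finite distances (saturated pairs?)")
  taxa <- rownames(d)
  n <- length(taxa)
  if (n < 2) stop("need at least 2 taxa")
  rawNeg <- data.frame(node = character(), length = numeric())
  clamp <- function(x, lab) {
    if (x < 0) rawNeg[nrow(rawNeg) + 1L, ] <<- list(lab, x)
    max(x, 0)
  }
  fmt <- function(x) sprintf("%.15g", x)
  frags <- taxa  # Newick fragment per active node

  if (n == 2) {
    h <- d[1, 2] / 2
    nwk <- paste0("(", frags[1], ":", fmt(h), ",", frags[2], ":", fmt(h), ");")
  } else {
    while (length(frags) > 3) {
      r <- nrow(d)
      R <- rowSums(d)
      best <- c(NA_integer_, NA_integer_); bestQ <- Inf
      for (i in seq_len(r - 1)) for (j in (i + 1):r) {
        q <- (r - 2) * d[i, j] - R[i] - R[j]
        if (q < bestQ) { bestQ <- q; best <- c(i, j) }
      }
      i <- best[1]; j <- best[2]
      li <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)), frags[i])
      lj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))),
                  frags[j])
      newFrag <- paste0("(", frags[i], ":", fmt(li), ",",
                        frags[j], ":", fmt(lj), ")")
      du <- (d[i, ] + d[j, ] - d[i, j]) / 2
      keep <- setdiff(seq_len(r), c(i, j))
      d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                  c(du[keep], 0))
      rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], "u")
      d <- d2
      frags <- c(frags[keep], newFrag)
    }
    a <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2, frags[1])
    b <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2, frags[2])
    cc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2, frags[3])
    nwk <- paste0("(", frags[1], ":", fmt(a), ",", frags[2], ":", fmt(b), ",",
                  frags[3], ":", fmt(cc), ");")
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "raw_negative") <- rawNeg
  tree
}

#' Sum of branch lengths of a tree
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return total branch length (post-clamp).
#' @export
sumBranchLengths <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  sum(tree$edge.length)
}

#' Serialize a tree to Newick text
#'
#' Branch lengths are written with at least 6 significant digits (default 10)
#' so that [parseNewick()] round-trips.
#'
#' @param tree an [ape::phylo].
#' @param path optional file path; when NULL the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when written to `path`).
#' @export
toNewick <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse Newick text into a tree
#'
#' @param text a Newick string, or NULL to read from `path`.
#' @param path optional file to read.
#' @return an [ape::phylo].
#' @export
parseNewick <- function(text = NULL, path = NULL) {
  tree <- tryCatch({
    if (is.null(text)) ape::read.tree(path)
    else ape::read.tree(text = text)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick input")
  tree
}

#' Leaf-to-leaf path-length distances of a tree
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return symmetric matrix of patristic distances, taxa in dimnames.
#' @export
treeDistances <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}
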