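#' @include AllClasses.R
NULL

.alnMatrix <- function(aligned) {
  # rows = taxa, columns = alignment columns, uppercase characters
  seqs <- if (is(aligned, "AlignedPromoterSet")) aligned@alignment
          else Biostrings::DNAStringSet(aligned)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
}

#' Remove alignment columns containing gaps or missing data
#'
#' Complete deletion: only columns where every member carries an unambiguous
#' base (A/C/G/T) are retained; columns with gaps (`-`) or missing/ambiguous
#' data (`N` or any other IUPAC ambiguity) are dropped before distance
#' estimation.
#'
#' @param aligned an [AlignedPromoterSet-class], a named character vector of
#'   gapped sequences, or a gapped [Biostrings::DNAStringSet].
#' @return list with `alignment` (character matrix, taxa x retained columns)
#'   and `usableSites` (retained column count).
#' @export
completeDeletion <- function(aligned) {
  m <- .alnMatrix(aligned)
  if (nrow(m) < 2) stop("need at least 2 members")
  keep <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))) == nrow(m)
  if (!any(keep)) stop("complete deletion removed every column")
  list(alignment = m[, keep, drop = FALSE], usableSites = sum(keep))
}

# pairwise substitution-type proportions for TN93-family estimators
.pairCounts <- function(a, b) {
  n <- length(a)
  pur <- c("A", "G"); pyr <- c("C", "T")
  diff <- a != b
  P1 <- sum(diff & a %in% pur & b %in% pur) / n      # A<->G transitions
  P2 <- sum(diff & a %in% pyr & b %in% pyr) / n      # C<->T transitions
  Q <- sum(diff & ((a %in% pur) != (b %in% pur))) / n  # transversions
  list(P1 = P1, P2 = P2, Q = Q, p = mean(diff), n = n)
}

.jc <- function(p) {
  if (p >= 0.75) return(NA_real_)
  max(0, -0.75 * log(1 - 4 * p / 3))
}

.tn93pair <- function(a, b) {
  # Tamura-Nei (1993) closed form with base frequencies averaged over the pair
  cnt <- .pairCounts(a, b)
  f <- table(factor(c(a, b), levels = c("A", "C", "G", "T"))) / (2 * cnt$n)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - cnt$P1 / k1 - cnt$Q / (2 * gR)
  w2 <- 1 - cnt$P2 / k2 - cnt$Q / (2 * gY)
  w3 <- 1 - cnt$Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  max(0, -k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
}

# TN93 transition-probability machinery -------------------------------------
# rate matrix with transition/transversion rate ratios k1 = alpha1/beta
# (A<->G) and k2 = alpha2/beta (C<->T), normalized to one expected
# substitution per unit branch length; reversible, so exponentiated via the
# symmetrized eigendecomposition.

.tn93Eigen <- function(k1, k2, pi) {
  names(pi) <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  for (i in names(pi)) for (j in names(pi)) {
    if (i == j) next
    rate <- if ((i == "A" && j == "G") || (i == "G" && j == "A")) k1
            else if ((i == "C" && j == "T") || (i == "T" && j == "C")) k2
            else 1
    Q[i, j] <- rate * pi[[j]]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  s <- sqrt(pi)
  S <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(values = e$values, left = diag(1 / s) %*% e$vectors,
       right = t(e$vectors) %*% diag(s), pi = pi)
}

.tn93Pmat <- function(eig, d) {
  P <- eig$left %*% (exp(eig$values * d) * eig$right)
  P[P < 1e-300] <- 1e-300
  P
}

# per-pair profile log-likelihood of distance d given shared parameters
.pairLogLik <- function(N, eig, d) {
  P <- .tn93Pmat(eig, d)
  J <- eig$pi * P  # joint probability pi_x * P_xy(d)
  sum(N * log(J))
}

.mlPairDist <- function(N, eig, upper = 5) {
  if (sum(N[row(N) != col(N)]) == 0) return(0)
  stats::optimize(function(d) .pairLogLik(N, eig, d),
                  interval = c(1e-9, upper), maximum = TRUE,
                  tol = 1e-10)$maximum
}

.pairJointCounts <- function(a, b) {
  lv <- c("A", "C", "G", "T")
  # symmetrized joint count matrix (reversibility makes direction arbitrary)
  N <- table(factor(a, lv), factor(b, lv))
  (N + t(N)) / 2
}

#' Pairwise evolutionary distances from a gap-filtered alignment
#'
#' Estimators, all in substitutions/site:
#' \describe{
#'   \item{`p`}{raw proportion of differing sites.}
#'   \item{`JC`}{Jukes-Cantor, `-(3/4) log(1 - 4p/3)`; pairs with
#'     `p >= 3/4` are saturated (NA, flagged).}
#'   \item{`TN93`}{Tamura-Nei 1993 closed form with base frequencies averaged
#'     over each pair.}
#'   \item{`MCL`}{composite-likelihood TN93: the two transition/transversion
#'     rate ratios are shared across all pairs and chosen to maximize the
#'     summed pairwise log-likelihood (base frequencies taken from the whole
#'     alignment); each pair's distance is then its own likelihood maximum
#'     under the shared rates. `kappa`/`freqs` may be fixed instead of
#'     estimated, which collapses the model (uniform frequencies and
#'     `kappa = c(1, 1)` reproduce Jukes-Cantor).}
#' }
#'
#' @param aligned input accepted by [completeDeletion()], or the list that
#'   function returns (columns are then assumed already filtered).
#' @param model one of `"p"`, `"JC"`, `"TN93"`, `"MCL"`.
#' @param kappa for `"MCL"`: optional fixed `c(k1, k2)` rate ratios
#'   (A<->G and C<->T transitions relative to transversions); estimated by
#'   numerical optimization when NULL.
#' @param freqs for `"MCL"`: optional fixed base frequencies (A,C,G,T);
#'   empirical alignment frequencies when NULL.
#' @return a [DistanceMatrix-class].
#' @export
pairwiseDistances <- function(aligned, model = c("MCL", "p", "JC", "TN93"),
                              kappa = NULL, freqs = NULL) {
  model <- match.arg(model)
  filt <- if (is.list(aligned) && !is(aligned, "AlignedPromoterSet") &&
              all(c("alignment", "usableSites") %in% names(aligned))) aligned
          else completeDeletion(aligned)
  m <- filt$alignment
  taxa <- rownames(m)
  n <- length(taxa)
  if (n < 2) stop("need at least 2 taxa")
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  pairs <- utils::combn(n, 2)

  if (model == "MCL") {
    if (is.null(freqs)) {
      freqs <- as.numeric(table(factor(m, c("A", "C", "G", "T")))) / length(m)
    }
    freqs <- freqs / sum(freqs)
    Ns <- lapply(seq_len(ncol(pairs)), function(k)
      .pairJointCounts(m[pairs[1, k], ], m[pairs[2, k], ]))
    objective <- function(logk) {
      eig <- .tn93Eigen(exp(logk[1]), exp(logk[2]), freqs)
      sum(vapply(Ns, function(N)
        .pairLogLik(N, eig, .mlPairDist(N, eig)), numeric(1)))
    }
    if (is.null(kappa)) {
      opt <- stats::optim(c(0, 0), function(lk) -objective(lk),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-8, maxit = 500))
      kappa <- exp(opt$par)
    }
    eig <- .tn93Eigen(kappa[1], kappa[2], freqs)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      d[i, j] <- d[j, i] <- .mlPairDist(Ns[[k]], eig)
    }
    out <- new("DistanceMatrix", d = d, usableSites = as.integer(filt$usableSites),
               model = "MCL-TN93", saturated = sat)
    attr(out@d, "kappa") <- kappa
    attr(out@d, "freqs") <- freqs
    return(out)
  }

  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- m[i, ]; b <- m[j, ]
    v <- switch(model,
                p = mean(a != b),
                JC = .jc(mean(a != b)),
                TN93 = .tn93pair(a, b))
    if (is.na(v)) sat[i, j] <- sat[j, i] <- TRUE
    d[i, j] <- d[j, i] <- v
  }
  new("DistanceMatrix", d = d, usableSites = as.integer(filt$usableSites),
      model = model, saturated = sat)
}

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' @param p proportion of differing sites in `[0, 0.75)`.
#' @return distance in substitutions/site; NA (saturated) for `p >= 3/4`.
#' @examples
#' jukesCantor(0.1)  # 0.10733...
#' @export
jukesCantor <- function(p) {
  vapply(p, .jc, numeric(1))
}
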