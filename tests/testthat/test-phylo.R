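test_that("complete deletion drops columns with gaps or missing data", {
  out <- completeDeletion(c(a = "AC-GT", b = "ACAGT"))
  expect_equal(out$usableSites, 4L)
  expect_equal(ncol(out$alignment), 4L)
  outN <- completeDeletion(c(a = "ACNGT", b = "ACAGT"))
  expect_equal(outN$usableSites, 4L)       # N counts as missing data
  id <- completeDeletion(c(a = "ACGT", b = "ACGA"))
  expect_equal(id$usableSites, 4L)         # gap-free input is untouched
  expect_error(completeDeletion(c(a = "-A", b = "A-")), "every column")
  expect_error(completeDeletion(c(a = "ACGT")), "at least 2")
})

test_that("distance estimators match their closed forms", {
  # identical sequences: zero under every model
  same <- c(a = strrep("ACGT", 50), b = strrep("ACGT", 50))
  for (mod in c("p", "JC", "TN93"))
    expect_equal(max(as.matrix(pairwiseDistances(same, model = mod))), 0)

  # 1000 sites with exactly 100 differences: p = 0.1, JC = 0.10733
  a <- strrep("A", 1000)
  b <- paste0(strrep("C", 100), strrep("A", 900))
  D <- pairwiseDistances(c(a = a, b = b), model = "JC")
  expect_equal(as.matrix(D)["a", "b"], -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-12)
  expect_equal(round(as.matrix(D)["a", "b"], 5), 0.10733)
  Dp <- pairwiseDistances(c(a = a, b = b), model = "p")
  expect_equal(as.matrix(Dp)["a", "b"], 0.1)

  # saturation: p >= 3/4 has no JC distance; pair flagged
  sat <- c(a = strrep("ACGT", 25), b = strrep("CGTA", 25))  # p = 1
  Ds <- pairwiseDistances(sat, model = "JC")
  expect_true(is.na(as.matrix(Ds)["a", "b"]))
  expect_true(Ds@saturated["a", "b"])
  expect_error(njTree(Ds), "non-finite")
})

test_that("JC is monotone in p and never below p", {
  p <- seq(0.005, 0.74, by = 0.005)
  d <- jukesCantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("TN93 closed form agrees with an independent implementation on pairs", {
  for (seed in 1:5) {
    ex <- simulateExons(ape::read.tree(text = "(a:0.12,b:0.12);"), 3000,
                        model = "TN93",
                        params = list(kappa = c(4, 2),
                                      freqs = c(0.3, 0.2, 0.3, 0.2)),
                        seed = seed)
    mine <- as.matrix(pairwiseDistances(ex$alignment, model = "TN93"))["a", "b"]
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(strsplit(ex$alignment, "")),
                                   model = "TN93"))["a", "b"]
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("composite-likelihood TN93 collapses to JC under the uniform model", {
  ex <- simulateExons(defaultExonTree(), 2000, seed = 21)
  filt <- completeDeletion(ex$alignment)
  Dj <- as.matrix(pairwiseDistances(filt, model = "JC"))
  Dm <- as.matrix(pairwiseDistances(filt, model = "MCL",
                                    kappa = c(1, 1), freqs = rep(0.25, 4)))
  expect_lt(max(abs(Dj - Dm)), 1e-6)
})

test_that("NJ reproduces the worked 3- and 4-taxon examples exactly", {
  d3 <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njTree(d3)
  expect_equal(sumBranchLengths(t3), 0.6)
  sp3 <- edgeSplits(t3)
  abc <- c("A", "B", "C")
  expect_equal(unname(sp3[[splitKey(abc, "A")]]), 0.1)
  expect_equal(unname(sp3[[splitKey(abc, "B")]]), 0.2)
  expect_equal(unname(sp3[[splitKey(abc, "C")]]), 0.3)

  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- 3; d4["A", "C"] <- 5; d4["A", "D"] <- 6
  d4["B", "C"] <- 6; d4["B", "D"] <- 7; d4["C", "D"] <- 7
  d4 <- d4 + t(d4)
  t4 <- njTree(d4)
  expect_equal(sumBranchLengths(t4), 11)
  sp4 <- edgeSplits(t4)
  abcd <- LETTERS[1:4]
  expect_equal(unname(sp4[[splitKey(abcd, "A")]]), 1)
  expect_equal(unname(sp4[[splitKey(abcd, "B")]]), 2)
  expect_equal(unname(sp4[[splitKey(abcd, "C")]]), 3)
  expect_equal(unname(sp4[[splitKey(abcd, "D")]]), 4)
  expect_equal(unname(sp4[[splitKey(abcd, c("A", "B"))]]), 1)  # AB|CD topology

  # degenerate 2-taxon case: path length and branch sum both equal d
  t2 <- njTree(matrix(c(0, .4, .4, 0), 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(sumBranchLengths(t2), 0.4)
  expect_equal(treeDistances(t2)["A", "B"], 0.4)
})

test_that("NJ recovers random additive trees to 1e-9", {
  set.seed(202)
  for (r in 1:12) {
    n <- sample(4:12, 1)
    ad <- randomAdditive(n)
    est <- njTree(ad$d)
    # topology identical to the generating tree
    expect_equal(ape::dist.topo(ape::unroot(ad$tree), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    # branch lengths via canonical splits
    want <- edgeSplits(ad$tree); got <- edgeSplits(est)
    expect_setequal(names(want), names(got))
    expect_lt(max(abs(want - got[names(want)])), 1e-9)
    # path-length metric equals the input matrix
    expect_lt(max(abs(treeDistances(est)[rownames(ad$d), colnames(ad$d)] -
                        ad$d)), 1e-9)
    # independent cross-check: ape's NJ finds the same topology
    expect_equal(ape::dist.topo(ape::nj(ad$d), est), 0, ignore_attr = TRUE)
  }
})

test_that("negative NJ branch lengths are clamped with the raw value logged", {
  d <- matrix(c(0, 0.1, 0.1, 0.1, 0, 0.5, 0.1, 0.5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)  # three-point formula gives A a negative branch
  expect_true(all(tr$edge.length >= 0))
  raw <- attr(tr, "raw_negative")
  expect_equal(nrow(raw), 1L)
  expect_equal(raw$length, -0.15)
})

test_that("Newick serialization round-trips and rejects malformed text", {
  txt <- toNewick(njTree(matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
                                dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))))
  expect_equal(txt, "(A:0.1,B:0.2,C:0.3);")
  set.seed(7)
  for (r in 1:5) {
    ad <- randomAdditive(sample(4:9, 1))
    t1 <- njTree(ad$d)
    t2 <- parseNewick(toNewick(t1, digits = 10))
    expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
    expect_equal(sumBranchLengths(t2), sumBranchLengths(t1), tolerance = 1e-8)
  }
  expect_error(parseNewick("((A:1,B:2;"), "malformed")
  # file round trip
  f <- tempfile(fileext = ".nwk")
  toNewick(njTree(matrix(c(0, .4, .4, 0), 2,
                         dimnames = list(c("A", "B"), c("A", "B")))), path = f)
  expect_equal(parseNewick(path = f)$tip.label, c("A", "B"))
})

test_that("ties on the Q criterion resolve deterministically", {
  # fully symmetric matrix: every Q equal; smallest index pair joins first
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t1 <- njTree(d); t2 <- njTree(d)
  expect_equal(toNewick(t1), toNewick(t2))
  expect_true(grepl("\\(A:[^,]+,B:", toNewick(t1)))  # (A,B) joined first
})
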