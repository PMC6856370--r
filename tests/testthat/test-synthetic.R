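test_that("zero branch lengths leave all species identical to the root", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simulatePromoters(tr, 500, seed = 3)
  seqs <- as.character(promoterSeqs(sim$records))
  expect_equal(length(unique(seqs)), 1L)
})

test_that("simulation is byte-identical under a repeated seed", {
  s1 <- simulateStudy(17)
  s2 <- simulateStudy(17)
  expect_identical(as.character(promoterSeqs(s1$records)),
                   as.character(promoterSeqs(s2$records)))
  s3 <- simulateStudy(18)
  expect_false(identical(as.character(promoterSeqs(s1$records)),
                         as.character(promoterSeqs(s3$records))))
  e1 <- simulateExons(defaultSpeciesTree(), 1000, seed = 5, gapColumns = 50)
  e2 <- simulateExons(defaultSpeciesTree(), 1000, seed = 5, gapColumns = 50)
  expect_identical(e1$alignment, e2$alignment)
})

test_that("JC substitution marginals match the closed form", {
  # one branch of length t: expected differing fraction (3/4)(1 - e^{-4t/3})
  t <- 0.1; L <- 10000
  tr <- ape::read.tree(text = sprintf("(a:%g,b:0);", t))
  sim <- simulatePromoters(tr, L, seed = 41)
  seqs <- as.character(promoterSeqs(sim$records))
  p <- mean(strsplit(seqs[1], "")[[1]] != strsplit(seqs[2], "")[[1]])
  expected <- 0.75 * (1 - exp(-4 * t / 3))  # 0.09362
  se <- sqrt(expected * (1 - expected) / L)
  expect_lt(abs(p - expected), 3 * se)
})

test_that("planted sites are recovered exactly; background is monitored", {
  falseConserved <- 0L
  backgroundHits <- 0L
  positions <- 0L
  seeds <- 1:20
  for (seed in seeds) {
    L <- 3000L
    sim <- simulateStudy(seed, L = L)
    hits <- scanSpecies(sim$records)
    cons <- callConserved(hits, sim$aligned, m = 4)
    cl <- conservedClusters(cons)
    # recall 1.0: the planted column interval (leftmost base -1413 maps to
    # column L - 1413 + 1 in the gap-free alignment) is a conserved cluster
    # whose absent set equals the planted loss set
    planted <- cl[cl$start_col == L - 1413L + 1L, , drop = FALSE]
    expect_equal(nrow(planted), 1L)
    expect_true(planted$conserved)
    expect_equal(planted$absent_species, "rat")
    falseConserved <- falseConserved + sum(cl$conserved) - 1L
    backgroundHits <- backgroundHits + nrow(hits) - 4L
    positions <- positions + 5L * (L - 6L)
  }
  # monitored statistics, no hard bounds: the per-position background hit
  # rate should sit near the strandless expectation 8/4^7, and chance
  # conservation across >= 4 species should be (close to) absent
  rate <- backgroundHits / positions
  expect_lt(abs(rate - 8 / 4^7), 4 * sqrt(8 / 4^7 / positions))
  expect_lte(falseConserved, 1L)
})

test_that("two planted sites with different loss sets are both recovered", {
  ps <- data.frame(position = c(-2500, -1413), wre = c("AACAAAG", "TTCAAAG"),
                   lost = c("", "rat"), stringsAsFactors = FALSE)
  sim <- simulatePromoters(defaultSpeciesTree(), 3000, plantedSites = ps,
                           seed = 8)
  cons <- callConserved(scanSpecies(sim$records), sim$aligned, m = 4)
  cl <- conservedClusters(cons)
  cl <- cl[cl$conserved, , drop = FALSE]
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$absent_species[order(cl$start_col)], c("", "rat"))
})

test_that("planting refuses overlaps, off-window sites and non-motif 7-mers", {
  tr <- defaultSpeciesTree()
  bad1 <- data.frame(position = c(-100, -95), wre = "TTCAAAG", lost = "")
  expect_error(simulatePromoters(tr, 500, plantedSites = bad1), "overlap")
  bad2 <- data.frame(position = -600, wre = "TTCAAAG", lost = "")
  expect_error(simulatePromoters(tr, 500, plantedSites = bad2), "outside")
  bad3 <- data.frame(position = -100, wre = "CCGCGGT", lost = "")
  expect_error(simulatePromoters(tr, 500, plantedSites = bad3),
               "does not match")
  bad4 <- data.frame(position = -100, wre = "TTCAAAG", lost = "dog")
  expect_error(simulatePromoters(tr, 500, plantedSites = bad4), "not in tree")
})

test_that("isoform duplicates share the species window under distinct ids", {
  sim <- simulateStudy(5, L = 400, position = -200, nIsoforms = 2)
  inf <- promoterInfo(sim$records)
  expect_equal(nrow(inf), 10L)
  expect_equal(sort(unique(inf$isoform_id)), c("iso1", "iso2"))
  seqs <- unname(as.character(promoterSeqs(sim$records)))
  expect_identical(seqs[inf$species == "human"][1],
                   seqs[inf$species == "human"][2])
})

test_that("gap and N injection bookkeeping matches complete deletion", {
  L <- 2000
  ex <- simulateExons(defaultExonTree(), L, seed = 9,
                      gapColumns = 150, nColumns = 50)
  filt <- completeDeletion(ex$alignment)
  expect_equal(filt$usableSites, L - 200L)
  expect_length(ex$maskedColumns, 200L)
  # untouched alignment: identity
  ex0 <- simulateExons(defaultExonTree(), 500, seed = 9)
  expect_equal(completeDeletion(ex0$alignment)$usableSites, 500L)
})

test_that("NJ on simulated exon distances recovers the generating topology", {
  ex <- simulateExons(defaultExonTree(), 8000, seed = 31)
  D <- pairwiseDistances(ex$alignment, model = "JC")
  est <- njTree(D)
  expect_equal(ape::dist.topo(ape::unroot(defaultExonTree()),
                              ape::unroot(est)), 0, ignore_attr = TRUE)
})

test_that("decaying-site mode plants at the root without tip overwrite", {
  ps <- data.frame(position = -200, wre = "TTCAAAG", lost = "",
                   stringsAsFactors = FALSE)
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simulatePromoters(tr0, 400, plantedSites = ps, seed = 6,
                           decaying = TRUE)
  # zero branch lengths: the root motif survives in every tip
  hits <- scanSpecies(sim$records)
  expect_true(all(table(hits$species[hits$position == -200]) == 1))
  expect_setequal(unique(hits$species), c("a", "b", "c", "d"))
})
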