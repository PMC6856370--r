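test_that("hits project onto alignment columns through gaps", {
  # member "A-CG": ungapped ACG, U=3 (positions -3..-1); the C is ungapped
  # index 2 = position -2 and sits in column 3
  aln <- AlignedPromoterSet(c(x = "A-CG"), upstream = 3)
  expect_equal(mapHitToColumns(aln, "x", -2, k = 1), c(3L, 3L))
  # gap-free member: columns equal ungapped indices
  aln2 <- AlignedPromoterSet(c(x = "ACGTACGT"), upstream = 8)
  expect_equal(mapHitToColumns(aln2, "x", -8, k = 7), c(1L, 7L))
  # two internal gaps widen a 7-mer to a 9-column interval
  aln3 <- AlignedPromoterSet(c(x = "TT--CAAAG"), upstream = 7)
  expect_equal(mapHitToColumns(aln3, "x", -7, k = 7), c(1L, 9L))
  expect_error(mapHitToColumns(aln3, "y", -7), "not in alignment")
  expect_error(mapHitToColumns(aln3, "x", -2, k = 7), "beyond")
})

.fiveSpeciesAln <- function() {
  # 30-column gap-free alignment; TTCAAAG planted at columns 11..17 in all
  # but rat; every member U=30
  site <- "TTCAAAG"
  mk <- function(withSite) paste0(strrep("C", 10),
                                  if (withSite) site else "GGGGGGG",
                                  strrep("C", 13))
  seqs <- c(human = mk(TRUE), mouse = mk(TRUE), rat = mk(FALSE),
            chicken = mk(TRUE), zebrafish = mk(TRUE))
  AlignedPromoterSet(seqs, upstream = 30)
}

.hitsFor <- function(species, position, strand = "+",
                     matched = "TTCAAAG") {
  data.frame(species = species, position = position,
             strand = rep_len(strand, length(species)),
             matched_seq = rep_len(matched, length(species)),
             stringsAsFactors = FALSE)
}

test_that("overlapping hits across species form one conserved cluster", {
  aln <- .fiveSpeciesAln()
  hits <- .hitsFor(c("human", "mouse", "rat", "chicken", "zebrafish"),
                   rep(-20, 5))
  cons <- callConserved(hits, aln, m = 4)
  cl <- conservedClusters(cons)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_species_present, 5L)
  expect_true(cl$conserved)
  expect_equal(cl$absent_species, "")
})

test_that("a site absent from rat is still called conserved at m = 4", {
  aln <- .fiveSpeciesAln()
  hits <- .hitsFor(c("human", "mouse", "chicken", "zebrafish"), rep(-20, 4))
  cons <- callConserved(hits, aln, m = 4)
  cl <- conservedClusters(cons)
  expect_equal(nrow(cl), 1L)
  expect_true(cl$conserved)
  expect_equal(cl$absent_species, "rat")
  expect_equal(cl$present_species, "chicken,human,mouse,zebrafish")
})

test_that("single-species hits and species mismatches are handled", {
  aln <- .fiveSpeciesAln()
  cons <- callConserved(.hitsFor("human", -20), aln, m = 4)
  expect_false(conservedClusters(cons)$conserved)
  expect_error(callConserved(.hitsFor("dog", -20), aln, m = 4),
               "absent from alignment")
  expect_error(callConserved(.hitsFor("human", -20), aln, m = 1), "m must be")
})

test_that("strand is ignored for clustering but kept per member", {
  aln <- .fiveSpeciesAln()
  hits <- .hitsFor(c("human", "mouse", "chicken", "zebrafish"), rep(-20, 4),
                   strand = c("+", "-", "+", "-"))
  cons <- callConserved(hits, aln, m = 4)
  expect_equal(nrow(conservedClusters(cons)), 1L)
  expect_setequal(clusterMembers(cons)[[1]]$strand, c("+", "-"))
})

test_that("one representative per species: largest overlap, ties to smaller position", {
  aln <- AlignedPromoterSet(
    c(a = strrep("A", 40), b = strrep("A", 40)), upstream = 40)
  hits <- rbind(.hitsFor("a", -30), .hitsFor("a", -29), .hitsFor("b", -30))
  cons <- callConserved(hits, aln, m = 2)
  mem <- clusterMembers(cons)[[1]]
  expect_equal(nrow(mem), 3L)               # every hit assigned to the cluster
  rep_a <- mem[mem$representative & mem$species == "a", ]
  expect_equal(nrow(rep_a), 1L)
  expect_equal(rep_a$position, -30L)        # larger overlap with b's hit

  # symmetric flanking hits tie on overlap; the smaller position wins
  hits2 <- rbind(.hitsFor("a", -31), .hitsFor("a", -29), .hitsFor("b", -30))
  mem2 <- clusterMembers(callConserved(hits2, aln, m = 2))[[1]]
  expect_equal(mem2$position[mem2$representative & mem2$species == "a"], -31L)
})

test_that("clustering is invariant under species order and covers every hit", {
  for (seed in 1:5) {
    sim <- simulateStudy(seed, L = 2000)
    hits <- scanSpecies(sim$records)
    cons <- callConserved(hits, sim$aligned, m = 4)
    shuffled <- hits[sample(nrow(hits)), , drop = FALSE]
    cons2 <- callConserved(shuffled, sim$aligned, m = 4)
    expect_equal(conservedClusters(cons), conservedClusters(cons2))
    assigned <- do.call(rbind, clusterMembers(cons))
    expect_equal(nrow(assigned), nrow(hits))   # each hit in exactly one cluster
    expect_equal(sort(paste(assigned$species, assigned$position,
                            assigned$strand)),
                 sort(paste(hits$species, hits$position, hits$strand)))
  }
})

test_that("positional fallback clusters by TSS distance", {
  hits <- .hitsFor(c("human", "mouse", "chicken", "zebrafish"),
                   c(-1413, -1413, -1410, -1420))
  cons <- positionalFallback(hits, toleranceW = 50, m = 4,
                             species = c("human", "mouse", "rat", "chicken",
                                         "zebrafish"))
  cl <- conservedClusters(cons)
  expect_equal(nrow(cl), 1L)
  expect_true(cl$conserved)
  expect_equal(cl$absent_species, "rat")

  hits2 <- rbind(hits, .hitsFor("rat", -2000))
  cl2 <- conservedClusters(positionalFallback(hits2, 50, 4))
  expect_equal(nrow(cl2), 2L)
  expect_equal(sum(cl2$conserved), 1L)

  # degenerate tolerance: exact-position clustering only
  hits3 <- .hitsFor(c("human", "mouse"), c(-100, -101))
  cl3 <- conservedClusters(positionalFallback(hits3, 0, 2))
  expect_equal(nrow(cl3), 2L)
  expect_error(positionalFallback(hits3, -1, 2), "toleranceW")
})

test_that("conserved-site TSV export carries per-species positions", {
  aln <- .fiveSpeciesAln()
  hits <- .hitsFor(c("human", "mouse", "chicken", "zebrafish"), rep(-20, 4))
  cons <- callConserved(hits, aln, m = 4)
  out <- tempfile(fileext = ".tsv")
  writeConservedSites(cons, out)
  tab <- read.delim(out)
  expect_equal(tab$human_site, "-20+")
  expect_equal(tab$rat_site, ".")
})
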