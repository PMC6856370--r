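# wreconserve

Cross-species conservation analysis of TCF/LEF (Wnt response element)
promoter binding sites, for regulatory genomicists doing phylogenetic
footprinting of Wnt pathway genes.

β-catenin/TCF-LEF transcription factors bind the degenerate Wnt response
element (WRE) 5′-(A/T)(A/T)CAAAG-3′ — four literal 7-mers per strand, eight
over both strands. `wreconserve` scans TSS-anchored promoter windows on both
strands for these sites, calls sites conserved across species from a gapped
promoter alignment, builds the accompanying species phylogeny
(Neighbor-Joining on p / Jukes–Cantor / Tamura–Nei 93 / composite-likelihood
TN93 distances after complete deletion of gapped columns), designs wild-type
versus site-mutant luciferase reporter inserts, and simulates promoter
evolution along a known tree with planted sites so the whole pipeline can be
validated against ground truth.

Coordinates are TSS-relative with no position 0 (−1 abuts +1, bounds
inclusive), so the classic reporter window −1635..+86 spans 1,721 bases.
Hit positions anchor the motif's leftmost sense-strand base on either strand.

## Worked example

Simulate the five-species study design — 5-kb promoters evolved along a
neutral-scale vertebrate tree, with `TTCAAAG` planted at −1413 in every
species except rat — then scan and call conserved sites:

```r
library(wreconserve)

wreMotif()
#> DegenerateMotif WWCAAAG
#>   forward: AACAAAG ATCAAAG TACAAAG TTCAAAG
#>   reverse: CTTTGAA CTTTGAT CTTTGTA CTTTGTT

sim <- simulatePromoters(defaultSpeciesTree(), 5000,
  plantedSites = data.frame(position = -1413, wre = "TTCAAAG", lost = "rat"),
  seed = 17)
hits <- scanSpecies(sim$records)
head(hits, 4)
#>   species position strand matched_seq pattern_id isoforms n_isoforms
#> 1 chicken    -4926      -     ATCAAAG    WWCAAAG     iso1          1
#> 2 chicken    -1413      +     TTCAAAG    WWCAAAG     iso1          1
#> 3   human    -3674      +     TTCAAAG    WWCAAAG     iso1          1
#> 4   human    -1652      -     AACAAAG    WWCAAAG     iso1          1

callConserved(hits, sim$aligned, m = 4)
#> ConservedSiteSet: 13 cluster(s), 1 conserved (m = 4 of 5 species; alignment clustering)
#> ...
#> 7  3588  3594  4  TRUE  chicken,human,mouse,zebrafish  rat
```

Thirteen clusters: twelve are single-species background hits (the expected
background rate is `8/4^7 ≈ 4.9e-4` per position per species), and exactly
one — alignment columns 3588–3594, i.e. position −1413 of the 5-kb window —
is conserved in four of five species with rat as the only absence, exactly
the planted truth.

The tree stage, on a simulated exon alignment sized so that complete
deletion retains 1,052 columns:

```r
ex <- simulateExons(defaultExonTree(), 1200, seed = 17,
                    gapColumns = 100, nColumns = 48)
D <- pairwiseDistances(ex$alignment, model = "MCL")
tree <- njTree(D)
usableSites(D)          #> 1052
sumBranchLengths(tree)  #> 0.642 (truth: 0.645)
```

Reporter design mirrors the published WT/mutant promoter assay: a 1,721-base
insert (−1635..+86) whose WRE at −1587 is replaced by `CCGCGGT` in the
mutant; `validateConstruct()` confirms the mutant lost exactly that hit and
that the edit changes all 7 positions.

```r
rc <- designReporter(promoters, window = c(-1635, 86),
                     sitePos = -1587, replacement = "CCGCGGT")
validateConstruct(rc)$hits_lost_at   #> -1587
```

`runPipeline(config)` chains scan → conserve → tree → design from a strict
JSON config and writes TSV/Newick/FASTA outputs plus a checksummed run
manifest; reruns with the same config and seed reproduce the manifest hash.

See the vignette (`vignettes/wre-conservation.Rmd`) for the models,
conventions and design decisions.

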