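---
title: "Cross-species conservation analysis of TCF/LEF (WRE) promoter sites"
author: "wreconserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species conservation analysis of TCF/LEF (WRE) promoter sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wreconserve)
```

## The problem

β-catenin-dependent Wnt signalling activates transcription through TCF/LEF
transcription factors, which bind the degenerate Wnt response element (WRE)
5′-(A/T)(A/T)CAAAG-3′. A standard way to argue that a particular WRE in a
promoter is functional is phylogenetic footprinting: scan the promoter of a
gene and of its orthologs in other species, and ask whether a site occurs at
the orthologous place in most of them. A site conserved across, say, four of
five vertebrates despite hundreds of millions of years of promoter turnover
is a strong regulatory candidate, which can then be tested directly with a
luciferase reporter carrying the wild-type promoter fragment versus one with
the site mutated away.

`wreconserve` implements that workflow end to end for TSS-anchored promoter
windows: degenerate motif expansion and double-stranded scanning,
cross-species conserved-site calling from a gapped promoter alignment,
distance estimation and Neighbor-Joining tree construction for the
accompanying species phylogeny, design and validation of WT/mutant reporter
inserts, and a promoter-evolution simulator that provides ground truth for
every stage.

## Coordinate model

All promoter sequences are stored 5′→3′ in the gene's sense orientation and
anchored at the transcriptional start site. A record with `upstream = U` and
`downstream = D` covers positions `-U..-1, +1..+D`; **there is no position
0** — `-1` abuts `+1` — and all window bounds are inclusive. Under this
convention a window from −1635 to +86 spans `86 - (-1635) = 1721` bases,
which is exactly how published promoter-fragment lengths in this field are
reported. `extractWindow()` enforces the convention; every hit coordinate in
the package is the TSS-relative position of the motif's leftmost
sense-strand base, on both strands. (Published site coordinates rarely state
whether they anchor the 5′ or 3′ end of a motif; the leftmost-base
convention is used consistently here and should be kept in mind when
comparing to external coordinates.)

## Motif scanning

`wreMotif("WWCAAAG")` expands the IUPAC pattern into its 4 literal forward
7-mers (`AACAAAG`, `ATCAAAG`, `TACAAAG`, `TTCAAAG`) and their 4 reverse
complements; the two sets are disjoint, so a double-stranded scan recognises
8 distinct strings. `scanPromoter()` tests every 7-base window of the sense
sequence against the forward set directly (strand `+`) and via reverse
complement (strand `-`). Design choices:

* overlapping and nested matches are all reported — the semantics are those
  of a literal string search, with no merging;
* `N` is a legal input character but never matches any motif base;
* `scanSpecies()` unions hits over promoter isoform variants of a species and
  deduplicates them by (species, position, strand), keeping the isoform
  provenance, since multi-isoform gene annotations otherwise double-count
  shared promoter sequence.

The test suite checks the scanner against a naive oracle that tries all 8
strings at every offset of 1000 random sequences.

## Conserved-site calling

Conservation is defined operationally: project each species' hit onto the
columns of the supplied promoter alignment (`mapHitToColumns()`, a 7-mer may
span more than 7 columns through internal gaps), and single-linkage cluster
hits whose column intervals overlap. Each connected component becomes one
cluster; a cluster is **conserved** when at least `m` species are present,
with `m` defaulting to all-but-one of the aligned species — the natural
threshold when one expects reports of the form "conserved in every species
except one". Within a cluster at most one hit per species is marked as the
representative (largest column overlap with the other species' hits; ties go
to the smaller, i.e. more upstream, position), but every input hit is
assigned to exactly one cluster. Strand is ignored when clustering — a site
may sit on opposite strands in different species — and recorded per member.

When no alignment is available, `positionalFallback()` clusters hits whose
TSS-relative positions differ by at most a tolerance `w` (default 50 bases in
the pipeline); this is cruder, since orthologous positions drift with indels,
but useful for quick screens.

The alignment itself is consumed, never computed: multiple-alignment
construction is out of scope, and reproducing any particular published site
map exactly would require the (typically unstated) aligner and parameters
behind it.

## Distances and the Neighbor-Joining tree

`completeDeletion()` removes every alignment column containing a gap or an
ambiguous base before distances are computed, reporting the retained column
count. `pairwiseDistances()` then offers four estimators, all in
substitutions/site:

* `p` — raw mismatch fraction;
* `JC` — Jukes–Cantor, `d = -(3/4) ln(1 - 4p/3)`; pairs with `p >= 3/4`
  are reported as saturated (NA plus a flag) rather than silently clipped;
* `TN93` — the Tamura–Nei (1993) closed form with base frequencies averaged
  over each pair (cross-checked in the tests against an independent
  implementation);
* `MCL` — composite-likelihood TN93: the two transition/transversion rate
  ratios are **shared across all pairs** and chosen to maximise the summed
  pairwise log-likelihood (Nelder–Mead over the log-ratios, relative
  tolerance 1e-8), with base frequencies taken from the whole alignment;
  each pair's distance is then its own one-dimensional likelihood maximum
  (golden-section, tolerance 1e-10) under the shared rates. This follows the
  "maximum composite likelihood" approach popularised by the MEGA software;
  since that program's exact internals are not fully published, the
  closed-form JC/TN93 estimators double as verifiable cross-checks: with
  frequencies fixed uniform and both rate ratios fixed at 1 the TN93
  likelihood collapses analytically to JC, and the optimizer reproduces the
  JC closed form to better than 1e-6, which the tests assert.

`njTree()` implements Saitou–Nei Neighbor-Joining directly: the Q-criterion
pair is joined at each step (ties broken deterministically by the smallest
index pair), branch lengths follow the standard formulas, and the final
three-taxon star is resolved exactly. Negative branch lengths — a normal NJ
artefact on noisy matrices — are clamped to zero with the raw value kept in
the tree's `"raw_negative"` attribute. Two further conventions: a 2-taxon
input yields the degenerate tree `(A:d/2, B:d/2)`, so both the leaf-to-leaf
path and the branch-length sum equal `d`; and trees serialize through
`toNewick()`/`parseNewick()` with 10 significant digits. On additive
matrices (generated from random trees with up to 12 taxa) NJ provably
recovers the topology and all branch lengths; the tests assert this to
1e-9 and additionally cross-check the topology against an independent NJ
implementation.

## Reporter design

`designReporter()` extracts the reporter window (default −1635..+86, the
1,721-base insert used in the published WT/mutant promoter assay this models),
verifies that the 7-mer at the edit position matches the WRE — it refuses to
"mutate" a non-site — and substitutes the replacement (default `CCGCGGT`)
in place. It rejects a no-op replacement and warns if the replacement still
matches the motif on either strand. Both inserts are rescanned so the
construct carries its own evidence: the WT hit list contains the edited
site, the mutant list does not, and all hits away from the edit locus are
identical. `validateConstruct()` re-derives these invariants plus the edit's
Hamming distance; note that `TTCAAAG → CCGCGGT` changes all 7 positions.

## The simulator and what passing tests mean

`simulatePromoters()` draws a root promoter iid over A/C/G/T, evolves each
site independently down a given tree (JC or TN93 per-branch transition
matrices, branch lengths in substitutions/site), and then **overwrites**
each planted site: retaining species receive the designated WRE variant,
losing species a non-matching 7-mer (`CCGCGGT`). Freezing sites after
evolution makes recovery deterministic — the planted truth registry is
exactly what a perfect caller should report — while a `decaying = TRUE` mode
plants at the root and lets sites drift, for power exploration. The
simulation is indel-free, so the gap-free alignment is known exactly and is
emitted alongside; `simulateExons()` additionally punctures chosen numbers
of columns with gaps or `N`s to give complete deletion work to do. A single
global RNG stream per run makes every output byte-reproducible from the
seed.

Two default trees encode the study conditions for the five-species
(human, mouse, rat, chicken, zebrafish) design:

* `defaultSpeciesTree()` — the promoter truth, at **neutral** divergence
  (human–zebrafish path 1.5 substitutions/site). Promoters turn over fast;
  at this scale a background WRE occurrence inherited from an ancestor
  almost never survives intact in four of five species, so the background
  behaves as independent per-species noise at the expected rate
  `8/4^7 ≈ 4.9e-4` per position, and only planted sites are shared. At
  coding-sequence divergences this would not hold: ancestrally shared
  background motifs would themselves be (correctly) called conserved, which
  is a real phenomenon but not the controlled ground truth a generator
  should produce.
* `defaultExonTree()` — the coding-region truth for the tree stage, with a
  branch-length sum of 0.645, matching the scale reported for five-species
  Wnt3a exon phylogenies; the acceptance script sizes its simulated exon
  alignment so that complete deletion retains 1,052 columns, the
  filtered-alignment size of that analysis, and recovers a tree of
  approximately that total length.

What the simulator does **not** emulate: indels and alignment uncertainty
(real promoter alignments are noisy and aligner-dependent), context-dependent
substitution, selection on background sequence, and motif gain by drift
(except in decaying mode). Passing the recovery tests therefore shows the
pipeline is correct given a trustworthy alignment; it does not certify
performance on diverged real promoters, where alignment error dominates.

## Problem sizes and numerical choices

The test suite works at deliberately modest sizes — 5-kb promoters for 20
seeds in the conservation-recovery check, 10,000-site exon alignments for
branch-length recovery, 1000 random sequences for the scan oracle, additive
matrices up to 12 taxa — chosen to exercise every code path with comfortable
statistical margins. Tolerances: NJ on additive input 1e-9; JC closed form
to printed precision; MCL-to-JC collapse 1e-6; stochastic recovery checks
use 3 standard errors (for branch lengths, the delta-method SE of a JC
distance, `sqrt(p(1-p)/L)/(1-4p/3)`, maximised over pairs, bounds the SE of
the branch-length contrasts).

## Pipeline

`runPipeline()` chains the stages under a strict JSON-style config (unknown
keys are rejected before anything runs; `min_species` must not exceed the
species count), writes each stage's TSV/Newick/FASTA output plus a manifest
with file checksums and per-stage counts, and is idempotent: the same
inputs, config and seed give the same manifest hash. The per-species gene
table in the config is where ortholog choices live (e.g. selecting the
`DRD2b` paralog for zebrafish when extending the analysis to a second
gene); the pipeline never infers them.

## Known limitations

* Conservation is purely presence/absence by positional overlap; no
  branch-length-aware footprinting score is computed.
* The MCL mode shares rate parameters but not among-site rate variation;
  no gamma correction is offered.
* Saturated pairs abort tree building rather than being imputed.
* Published figure-level site maps depend on the alignments behind them and
  are not reproduced; on user-supplied alignments the package reports the
  same kinds of quantities (usable sites, branch-length sum, site maps) for
  comparison.
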