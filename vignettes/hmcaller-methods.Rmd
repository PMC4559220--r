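---
title: "Calling and characterizing 5-hydroxymethylcytosine from AbaSI digest sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing 5-hydroxymethylcytosine from AbaSI digest sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcaller)
```

## The problem and the measurement model

5-hydroxymethylcytosine (5hmC) is the oxidation product of 5-methylcytosine
produced by TET enzymes. In brain tissue it is abundant, occurs almost
exclusively at CpG dinucleotides, and is of interest as a regulatory mark.
One route to single-base 5hmC maps is a restriction-digest protocol: 5hmC is
glucosylated, the AbaSI enzyme recognizes the glucosylated base and cleaves
11–13 bp downstream of it, adaptors are ligated at the cut, and 50 bp
single-end reads are sequenced from the cut site. The modified cytosine then
sits at a predictable offset — the 11th to 13th base — from the 5' end of
each read, on the read's own strand.

`hmcaller` implements the downstream half of this design: from aligned reads
to single-base site calls, multi-individual consensus, densities, binned
profiles, clusters, and sex comparisons. Alignment itself (and duplicate
marking and realignment as done with standard tools) is out of scope; input
is aligned SAM/BAM, and a lightweight positional duplicate collapse
(`collapse_duplicates()`) stands in for an upstream duplicate-marking step.

### The site caller

For a filtered read, each configured offset `d` in ascending order defines a
candidate cytosine `d` bases into the read from its 5' aligned end, counted
along the read's own strand — for a minus-strand read, leftward from its
rightmost aligned base. A site is emitted when the reference shows a CpG at
the candidate (C on the read strand, G adjacent 3' on that strand); the
first matching offset wins and later offsets are not tested, a deterministic
resolution for the rare read with CpGs at two offsets. Reads with no CpG at
any tested offset are discarded — this is the expected fate of roughly half
of all fragments in the wet protocol, whose cuts are not informative.
Sites are single-base, strand-aware calls: `pos` is always the plus-strand C
of the CpG, and hydroxymethylation of the complementary cytosine is the same
`pos` with strand `-`. We keep the two strands of a CpG distinct throughout
(they are chemically distinct marks); `merge_cpg_strands()` collapses them
for analyses that want CpG-level units.

Read filtering keeps reads with mean base quality strictly greater than 30
and mapping quality at least 10. The mean over base qualities is our
operationalization of a per-read "quality score"; thresholds and their
inclusive/exclusive senses are configurable in `caller_config()`.

### Consensus and stringency tiers

Per-individual site sets are combined by exact (chrom, pos, strand) identity
into a consensus table counting carriers per site. Stringency tiers keep
sites carried by at least `ceiling(f * n)` individuals with `f` = 0.25, 0.50
and 0.75 — for a 19-individual cohort, thresholds 5, 10 and 15. Tiers nest
by construction.

### Overlap testing in log space

Whether two individuals share more sites than chance is tested against a
hypergeometric null: draw `n` sites from a universe of `N` (default 27
million, an external estimate of the total 5hmC sites in brain), `K` of
which belong to the other sample, and compute the upper tail P(X ≥ k). At
these scales the probability underflows double precision by five orders of
magnitude *in the exponent*, so the tail is accumulated entirely in log
space: the starting term by log-gamma factorials, successive terms through
the term ratio, stopping when a term changes the running sum by less than a
relative 1e-12. When `k` lies at or below the distribution mode, the
complement (lower tail) is summed instead — it is the short, well-conditioned
side. The unit tests check this machinery against exhaustive enumeration for
every feasible configuration with N ≤ 12 and against `stats::phyper` in log
space; `phyper` is deliberately the cross-check, not the implementation.

### Densities and profiles

Density is the site count corrected for both interval length and CpG
content: `n_sites / (n_cg × span_bp)`. "Corrected for" is not given an
explicit algebra in the protocols this follows; plain division by the
product is the simplest reading, is stated in output headers, and cancels in
the within-analysis comparisons the package draws. Units with no CpGs are
flagged undefined rather than zero.

Three binned profile schemes are provided:

* **Peak-centered** (`peak_profile()`): mean site count per contiguous
  100 bp bin, ±3 kb around each peak's central position (`start +
  floor(len/2)`); the mean is over peaks, so duplicated peaks do not distort
  it, and windows clipped at chromosome edges contribute truncated counts.
* **Metagene** (`metagene_profile()`): gene bodies and fixed-width flanks
  (defaults 20 kb) each divided into 50 intervals, orientation flipped for
  minus-strand genes, the TSS belonging to the first body bin. Per-bin
  values are counts normalized by bin width in bp, then averaged across
  genes with equal gene weights (per-gene averaging, not read pooling, so
  long genes do not dominate). Genes shorter than the bin count are skipped.
  Profiles are stratified by expression quartile (1 lowest, sizes equal ±1).
  An optional `per_cpg` mode divides by bin CpG content instead of width.
* **Exon boundary** (`exon_boundary_profile()`): per-position counts ±20 bp
  around the 5' and 3' boundaries of internal exons (first and last exons
  and single-exon genes excluded), transcript-oriented, reported separately
  for sites on the gene's strand (sense) and the opposite strand.

### Clusters, gene assignment and enrichment

A 5hmC cluster is a maximal single-linkage run of at least 3 sites with
consecutive gaps ≤ 200 bp, strands pooled. We read "each within 200 bp of
each other" as consecutive-gap chaining rather than a pairwise-diameter
bound: chaining is the standard agglomerative reading and does not cap the
span of a dense region; the diameter reading is available behind
`cluster_config(method = "diameter")` for comparison. Cluster midpoints
(`floor((start + end) / 2)`) are assigned to the enclosing gene body
(smallest body when nested), else the nearest TSS by absolute distance with
lexicographic tie-break, else left unassigned beyond 250 kb.

Enrichment of the assigned gene list against a flat term→gene map uses the
same hypergeometric tail machinery (upper tail when observed ≥ expected,
else lower), with Benjamini–Hochberg correction across terms and a 0.05 FDR
cut. Ontology structure (term ancestry) is intentionally not modelled: the
statistics, not the curation, are the reproducible part.

### Sex comparisons and X-inactivation escape

Female-unique sites are the set difference of the female union against the
male union. Male-specific clusters use a subsampling scheme: 5 random sets
of 5 males, each set's unique-versus-females sites clustered, and only
clusters recurring in all 5 sets kept. "Recurring" is operationalized as ≥1
bp overlap (exact-coordinate matching is available); subsets are drawn
without replacement within a set and may overlap across sets. The procedure
is deterministic given its seed.

Escape from X-inactivation is scored 0–9 per X-linked gene (0 fully
inactivated, 9 complete escape). For each scored gene we compute gene-body
5hmC per CpG from the female union and compare escaping (score ≥ 1) against
inactivated (score 0) genes with a two-sided Wilcoxon rank-sum test — a
deliberate choice of a distribution-free test for small, skewed per-gene
rates; a fully tied comparison is reported as p = 1. A `region = "flank"`
option measures the 2 kb flanks outside gene bodies instead, since
"intragenic" and "intergenic" readings of this comparison both occur in the
literature this package follows.

## The synthetic-data generator

Every stage is exercised end-to-end on generated data; no download is
needed. The generator's defaults are the study conditions the package is
designed around: 19-individual (all-male) cohorts — 19 males + 5 females in
the full pipeline default — 50 bp single-end reads, offsets 11–13 with
weights {0.25, 0.5, 0.25} over {11, 12, 13} (the protocol gives only the
range; the middle value is favoured as the modal cut distance), and a
CpG-depleted toy genome (default 2 chromosomes × 100 kb at CG frequency
0.02, the last chromosome designated `chrX`).

Design choices worth knowing when interpreting test results:

* **Genome construction.** Chromosomes are i.i.d. bases with every chance
  CG removed and exactly `round(cpg_rate × length)` CG dinucleotides
  injected, at positions ≥ 4 bp apart (when the density allows). The spacing
  mirrors real CpG depletion and has a second purpose: no CpG can sit 2 bp
  upstream of another, so the caller's first-matching-offset rule always
  attributes a read to the CpG it was generated from. Realized CpG counts
  are exact up to rounding.
* **Truth planting.** A core fraction (default 0.3) of all CpGs is planted
  in every individual; each individual independently adds private sites at
  0.05 per remaining CpG, strands uniform. This emulates a stable shared
  backbone plus inter-individual variability — it does not emulate the
  *graded* sharing of real cohorts (sites carried by, say, exactly 8 of 19
  individuals arise here only by coincidence of private draws), so
  consensus-tier *percentages* on synthetic data are not comparable to
  cohort values; tier mechanics and nesting are.
* **Read counts.** Reads per site are 1 + Poisson(mean − 1): Poisson-like
  dispersion, but zero-truncated so every planted site is sequenced. A plain
  Poisson would silently drop ~e^−λ of sites and make exact recovery
  impossible by construction, which would conflate generator shot noise with
  caller defects in the recovery tests. Sites closer than one read length to
  a chromosome edge are never planted, for the same reason.
* **Noise.** Background reads at `noise_read_rate` per kb (default 5) with
  mixed mapping and base qualities approximate the non-informative fragment
  fraction of the protocol; a noise read only produces a false call if it
  passes both quality filters and happens to overlook a CpG at a tested
  offset, which is why precision stays above 0.9 even at 10 noise reads/kb
  on a CG-0.02 genome.
* **What is not modelled.** Sequencing errors, indels, PCR duplicates,
  fragment-length and adaptor mechanics, mappability. Passing tests
  demonstrate the pipeline's internal correctness and statistical behaviour
  under its stated model — not robustness to alignment artifacts in real
  libraries.

Annotation fixtures tile non-overlapping multi-exon genes with intergenic
gaps, place CpG islands on the most CG-dense 1 kb windows, scatter
enhancer/peak intervals intergenically, draw log-normal expression values
(quartiled with equal sizes ±1), and assign escape scores 0–9 stratified
over `chrX` genes.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; BED on disk;
  SAM's 1-based positions are converted at the boundary.
* The hypergeometric early-termination tolerance is a relative 1e-12,
  matched by the enumeration tests.
* `cor.test` correlations are reported as undefined (with a reason) for
  fewer than 3 individuals or zero-variance covariates.
* Clusters on unsorted input sort internally with a logged notice; duplicate
  positions (both strands of one CpG) count as distinct member sites.
* Gene bodies shorter than the metagene bin count are skipped with a log
  message, as are escape genes whose bodies contain no CpG.
* All randomness is seeded; a single pipeline seed derives per-stage child
  seeds (`derive_seed`), so stages are individually reproducible and reruns
  are byte-identical (verified by manifest checksums).

## Problem sizes used by the test-suite and acceptance runs

The shipped tests run the full machinery at deliberately small scale —
genomes of 20–500 kb, cohorts of up to 24, hundreds to thousands of planted
sites — which exercises every code path in well under two minutes per
module. These sizes are the package's own test design: statistical
assertions state their tolerance explicitly (3σ binomial/Poisson bounds,
ratio windows, KS at α = 0.01) so they hold with margin at these sizes.

## A worked sketch

```{r example, eval = FALSE}
cfg <- pipeline_config(outdir = "hmc_demo", seed = 42)
run <- run_pipeline(cfg)
run$consensus                      # union sites and tier counts
head(run$clusters)                 # clusters with gene assignment
overlap_hypergeometric(K = 6793582, n = 3818749, k = 1999493)
```

## Known limitations

* The caller assumes ungapped alignments; reads with non-trivial CIGAR are
  dropped (with a count), so indel-rich regions are invisible.
* Quantitative hydroxymethylation levels (β-value analogues) are out of
  scope; sites are present/absent per individual, as in the design this
  follows.
* The enrichment module tests a flat gene-set map; ontology-aware analyses
  need an external tool.
* Consensus matching is exact-coordinate; assemblies must agree across
  individuals (no liftover).
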