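---
title: "Calling and comparing A-to-I RNA editing in paired tumor/normal cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing A-to-I RNA editing in paired tumor/normal cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscape)
```

## The problem

A-to-I editing by the ADAR deaminases is read by sequencers as an A>G
substitution, so in principle an editing site is just a position where a
sample's RNA disagrees with its own DNA. In practice the raw set of
RNA–DNA differences is dominated by artifacts: sequencing error at high
depth, germline polymorphism, somatic mutation, mapping noise producing
multi-allelic piles, and low-coverage positions where a couple of reads
mimic a 10–30% editing level. The pipeline in this package takes matched
per-site base-count tables (the output of pileup-based callers) for RNA
and DNA of each sample and distills them into a high-confidence editing
matrix, then layers the comparative analyses a paired tumor/normal
design supports: differential-editing classification, deaminase
association, sequence context, an editing-frequency selection scan, and
intersections with expression and splicing.

## Site calling and the filter cascade

For each sample, every position with at least one non-reference RNA read
and a genotyped DNA position (DNA depth ≥ 5 by default) is a candidate.
Candidates then pass a fixed-order cascade — mean base quality ≥ 30, RNA
depth ≥ 10, at most one RNA alternative allele (an allele needs ≥ 2
supporting reads), DNA-variant removal, SNP-mask removal, and finally
the editing-level window `0.1 ≤ alt/(ref+alt) < 1`. The order is fixed
so that the single removal flag each rejected candidate carries is
deterministic; the flags partition the candidates, and the per-sample
log records every threshold applied.

Three choices deserve comment.

* **DNA-variant evidence** is the conjunction "alternative fraction
  > 0.01 *and* alternative count ≥ 2". A disjunction would let a single
  error read in a depth-50 DNA library (fraction 0.02) discard ~5% of
  true sites per sample; the conjunction is robust at both low and high
  DNA depth.
* **The cohort veto**: a DNA mutation is a property of the position, not
  of one library. If any sample shows DNA-variant evidence at a
  position, the position is removed in every sample. Without the veto, a
  somatic variant passes as "editing" in precisely those tumor samples
  whose DNA library happens to be shallow.
* **Per-sample filtering**: depth and level thresholds are applied
  independently per sample, so a site may be observed in some samples
  and missing in others. Missingness is preserved (never zero-filled) in
  the editing matrix; "not covered" and "not edited" are different
  facts.

Unstranded pileups report mismatches on the plus strand. A site inside
exactly one annotated gene inherits the gene strand and minus-strand
mismatches are complemented, so a raw T>C inside a minus-strand gene is
counted as A>G, i.e. A-to-I. Gene-ambiguous and intergenic sites keep
strand `unknown` and their raw mismatch class. Region classes resolve
with precedence exonic > 3'UTR > 5'UTR > intronic > intergenic, ties
between genes broken lexicographically — real transcriptomes overlap,
and a site must get one reportable class.

Intervals are held internally as `GenomicRanges` (1-based closed, the
native Bioconductor convention); GFF3 (1-based closed) and BED (0-based
half-open) are converted on import by `rtracklayer`, which removes
coordinate ambiguity at the module boundaries just as well as any single
internal convention.

## Differential editing

Sites are classified by per-condition *sample coverage* (number of
samples with a passing observation): **shared** sites need coverage
≥ 10 in both conditions; **tumor-** and **normal-specific** sites need
≥ 4 in their condition and 0 in the other; everything else is dropped
with a logged reason. The "≥ 10" reading of the shared rule is
inclusive by default and a strict `>` is selectable, because with either
reading the boundary must be testable.

Each shared site gets one two-sided Fisher exact test on the 2×2 table
of pooled read counts (tumor edited/unedited vs normal
edited/unedited). Pooling reads across samples within a condition is the
only construction that yields a single p per site; the alternative —
comparing per-sample level vectors — is a different test with different
operating characteristics, and the pooled version is what a single
2×2-per-site analysis implies. No multiplicity correction is applied to
the significance call (`p < 0.05`), matching the way such screens are
usually reported; a Benjamini–Hochberg column is emitted alongside so
the reader can apply one. Zero-margin tables (e.g. the pooled table of a
specific-group site) are degenerate and reported with p = 1.

Pooling has a cost the user should understand: read counts within a
condition are overdispersed whenever samples differ in their true
levels, and the pooled Fisher test does not model that. With the
generator's default sample-level dispersion the realized type-I rate at
nominal 0.05 is about 0.11 rather than 0.05 (and exactly nominal when
sample-level dispersion is switched off). The default dispersion
(`sample_dispersion = 0.01`, a Beta concentration of 99 around the site
mean) was chosen so that this inflation stays within the moderate range
the method is calibrated for; pushing dispersion higher makes the pooled
test anti-conservative quickly.

## Sequence context

For strand-resolved A>G sites, the `±k` reference window is read on the
editing strand and per-offset base frequencies are compared with a
background of adenosines drawn from the same genes (controlling for
local composition), as `log2(edited/background)` with a Laplace
pseudocount of 0.5. By default the background uses *all* gene-matched
adenosines rather than a size-matched subsample: the background is then
essentially noise-free, and the enrichment variance is set by the edited
set alone. (With a size-matched background the noise doubles; with ~1000
sites the null maximum enrichment then exceeds 0.2 log2 units in well
over 5% of runs, which makes a calibration bound at that level
meaningless. Roughly 2500 sites are needed for a 0.2-unit null bound to
hold at the 95% level even with the noise-free background.) When a
subsample is requested, candidates are ordered by transcript-relative
offset before the seeded draw, so the background — and with it the whole
profile — is invariant under reverse-complementing the genome and
flipping all gene strands.

## ADAR association

Per-sample mean editing level averages over the sites observed in that
sample. Global association with each deaminase is a Spearman rank
correlation (ties mid-ranked) across all samples of both conditions;
Spearman is also used per site and in the ADAR1 up/down-stratified
analysis (Pearson is available by flag), since monotone association is
the scientific claim and rank invariance under expression
renormalization is a property worth having. Differential ADAR expression
between conditions is a paired t-test on `log2(x + 1)`; the transform
stabilizes the multiplicative scale of expression data and the
pseudocount keeps zero-expression samples finite.

## Editing-frequency F_ST

Each sample contributes its editing frequency as one observation, and
the tumor/normal contrast is scored with the Weir–Cockerham
variance-component estimator computed from the one-way layout of
per-sample frequencies (method-of-moments on between- and within-group
mean squares with the unbalanced-design correction `n_c`). Negative raw
estimates are preserved in `fst_raw` and clamped to `[0, 1]` for the
headline column; `fst ≥ 0.25` flags a candidate positively selected
site. A pooled-read-count Hudson estimator is available as an
alternative.

Two caveats are documented rather than hidden. First, with 10 samples
per group the null distribution of the variance-ratio estimator has an
F(1, 18)-type tail: a non-diverged site that reaches the scan has
roughly a 5% chance of exceeding 0.25 regardless of depth or
dispersion; at 40+ samples per group this tail is negligible. Second,
the scan's input is the DRE table, so a truly null site can only be
scanned after being selected by the Fisher test — and conditional on
that selection its F_ST is inflated by construction (the same noise
drives both statistics). End to end this matters little — of all planted
null sites, about 1% end up spuriously flagged — but F_ST values of
*test-selected* sites should never be interpreted as unbiased
estimates of differentiation.

## Functional integration

eDREs are DREs whose gene passes the differential-expression thresholds
(|log2FC| ≥ 1, adjusted p < 0.05) in a user-supplied DEG table; when no
external analysis is available, `paired_log2fc()` provides a documented
stand-in (per-gene median paired log2 fold-change on `log2(x+1)`, paired
t-test, BH correction) — it shares the output schema of a DESeq2 result,
not its model. No direction-consistency between editing group and
expression direction is imposed.

sDREs are DREs inside a differential splicing event's containment span.
The span per event type covers the defining exons plus the
flanking/internal introns (skipped exon ± both flanking introns;
alternative splice-site region plus its intron; the retained intron;
both mutually exclusive exons plus internal introns): regulatory edits
sit in the surrounding introns at least as often as in the exons, so
exon-only spans would miss the causal cases. The fraction of events
containing at least one DRE is reported.

For structure analysis the package extracts, for each site, the
unedited reference window and the same window with the central A
replaced by G (±250 or ±1000 nt, on the editing strand, clipped at
contig edges with a warning); the pair differs at exactly one position.
Thermodynamic folding itself is delegated to external tools, and
`summarize_delta_mfe()` ingests their results.

## The synthetic-data generator

`sim_config()` defines the study conditions the package is tested
under; `simulate_reference()` builds a two-chromosome 200 kb genome with
30 genes (exons, introns, UTRs, alternating strands) and plants site
positions, and `simulate_counts()` draws the data:

* **Editing levels** are hierarchical: a site-level mean from
  Beta(2, 8) — mean 0.2, most mass between 0.1 and 0.3, matching the
  level range reported for differential sites in tumor cohorts — and
  per-sample levels from a Beta around that mean
  (`sample_dispersion = 0.01`, see above; 0 collapses to pure binomial
  sampling).
* **Depth** is negative-binomial, mean 50, dispersion 0.3 — the
  standard RNA-seq coverage model; there is no authoritative depth
  distribution to copy, so defaults are chosen at typical bulk coverage.
* **Groups**: 150 shared sites (50 with a planted +0.2 tumor shift, 40
  with diverged frequencies 0.8/0.2 for the selection scan), 60
  tumor-specific and 60 normal-specific sites (absent-condition
  frequency exactly 0); 30 SNPs (germline, variant in DNA+RNA of every
  sample), 30 somatic DNA variants (tumor-only, fraction 0.35), and
  2000 error-only background positions.
* **ADAR coupling**: each sample's ADAR1 expression deviates on the
  log2 scale (sd 0.5, +1 in tumors), and its global editing multiplier
  is `2^(coupling × deviation)` with coupling 0.5 — editing rises with
  ADAR1, and tumors edit more, as the bulk data this emulates show.
* **Motif bias** 0.8: a planted site carries the ADAR neighbor
  preference (no G at −1, G at +1 on the editing strand) with
  probability 0.8 — strong but not absolute, as in real ADAR substrate
  data. Setting it to 1 makes the −1/+1 G frequencies exactly 0 and 1,
  which is the calibration used in tests.
* **Splicing/expression**: 50 events (SE-weighted type mix), 42%
  anchored to contain a planted specific-group site with mean level
  ≥ 0.2 (robustly detectable, so the planted overlap fraction is
  recoverable); 10 DE genes with |log2FC| = 2 chosen among genes
  carrying planted sites.

Everything is a deterministic function of the configuration including
the seed, down to bytes on disk.

What the generator does **not** emulate: alignment artifacts and mapping
bias, hyper-edited reads lost at alignment, strand-specific library
errors, clustered editing (sites are planted ≥ 12 bp apart), copy-number
variation distorting DNA allele fractions, and real Alu topology (the
"repeats" are random Alu-length intervals). Passing tests on this
generator therefore demonstrates the pipeline's statistical behavior
under the stated model, not robustness to upstream artifacts — those
live in the aligner and pileup caller, which are out of scope here.

## Numerical and degenerate-input policy

Fisher tests on zero-margin tables return p = 1 with a `degenerate`
flag; Spearman correlations on constant vectors are reported missing,
and fewer than 3 paired observations (10 by default per site) are
refused as missing rather than computed; paired t-tests are skipped with
a notice below 2 pairs, and a zero-variance difference vector reports
t = 0, p = 1. The F_ST estimator refuses groups of fewer than 2 samples
(its variance components are undefined) and defines the all-equal
configuration as 0. Merged sites that disagree on the top alternative
base across samples (error reads at a true site) keep the
lexicographically first; duplicate positions within one sample are an
integrity error, not a silent merge.

## Problem sizes used in the shipped checks

The test suite and acceptance script run desk-scale configurations: 10
pairs at the generator defaults for the recovery checks, 50 replicates
of a 30-site configuration for power, 200 replicates of a minimal
configuration for the null ADAR calibration, ~2500 planted sites for
the context-null bound, and 10+10 samples for the selection scan —
sizes chosen so each property is measured with enough events to be
stable while the whole suite stays interactive. A full-cohort regime
(dozens of pairs, millions of sites) changes none of the algorithms,
only the runtimes and the small-sample caveats noted above.

## Known limitations

* The pooled Fisher test is anti-conservative under strong sample-level
  overdispersion; a beta-binomial or per-sample-level test would be the
  next step if cohorts show high dispersion.
* Specific-group membership is driven by the detectability threshold
  (level ≥ 0.1), so "tumor-specific" means "never detected in normal
  under these filters", not biological absence.
* The coverage rules (≥ 10 shared, ≥ 4 specific) are absolute counts
  sized for cohorts of dozens of pairs; with 10 pairs the shared rule demands
  every sample, which is deliberately strict and drops many genuinely
  shared sites. They are parameters, not constants.
* F_ST of DRE-selected sites is biased upward (see above); treat the
  scan as a ranking with a fixed operating point, not as inference.
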