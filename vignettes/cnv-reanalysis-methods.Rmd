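---
title: "Depth-of-coverage CNV reanalysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-of-coverage CNV reanalysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcnv)
```

## The problem

Rare-disease exome cohorts accumulated across many centres are sequenced
with different enrichment kits, library preparations and depths. Copy
number variants (CNVs) must then be detected from depth of coverage alone:
the read count over each capture target is compared with the counts of a
matched control pool, and stretches of targets with consistently aberrant
coverage become deletion or duplication calls. Because no single read-depth
algorithm is uniformly sensitive, the re-analysis workflow implemented here
runs three complementary callers per enrichment kit, pools their calls, and
then triages aggressively — cohort frequency filtering, gene-panel
restriction, classification into interpretation classes and per-ERN
(European Reference Network) prioritisation — so that each affected
individual ends up with a handful of interpretable candidate CNVs.

This vignette records the models, the tunable parameters, the synthetic
cohort that stands in for access-controlled patient data, and the design
choices made where the published workflow descriptions leave the details
open.

## The synthetic cohort

Real multi-centre exome data cannot be redistributed, so the package ships
a generator (`simulate_cohort()`) whose output has the statistical features
the three callers are built to exploit or to suffer from:

* **Target sets.** Each kit draws exon-like targets (60–300 bp) across all
  autosomes plus X and Y, proportional to chromosome length, with a small
  pseudo-autosomal stub forced onto Xp. GC fractions follow a Beta mixture
  around 0.45 with a deliberate ~0.3% tail above 0.8, so the GC-extreme
  target filter (strictly > 0.80) removes a realistic, sub-0.5% share.
* **Count model.** The count for sample *s* at target *t* is negative
  binomial with mean
  `depth_s * capture_t * gc_kit(gc_t) * batch_{b(s),t} * CN_st / 2`.
  Ploidy enters through the baseline copy number (2 on autosomes and the
  pseudo-autosomal region, sex-dependent on X/Y; females carry no Y), so a
  hemizygous male X target has half the female mean — the physical model.
* **Capture efficiency** `capture_t` is log-normal with sd 1.0. This
  heavy-tailed spread is what makes same-kit coverage profiles correlate at
  ~0.97–0.99 (as real exomes do) and leaves a tail of weak targets that the
  systematically-low exclusion rule (< 0.3 of typical coverage in ≥ 90% of
  samples) removes.
* **Batch structure.** Each kit contains two sequencing batches with their
  own per-target multiplicative bias (log-normal sd 0.6). This is the
  heterogeneity the workflow is designed around: coverage-profile
  clustering recovers the batches, correlation-matched references select
  within batch, and the SVD caller's per-target standardisation inherits
  the batch contrast in its denominator — which is precisely why it misses
  short CNVs on heterogeneous data.
* **Noise level.** The residual (non-shot) overdispersion default is
  0.005, i.e. a ~7% systematic coefficient of variation on top of counting
  noise, and per-sample median depth is uniform on 150–250 reads. These
  are the conditions of a deeply sequenced, well-matched modern kit. They
  were fixed by a power analysis of the calling operating point: at the
  workflow's log-likelihood threshold of 20, a two-target heterozygous
  deletion carries fewer than 20 units of expected evidence once the
  median depth falls below roughly 140 reads or the systematic CV rises
  towards 15%, so under noisier conditions *no* depth-of-coverage caller
  can recover short events — the thresholds themselves presuppose
  conditions like these.
* **Events.** Each sample receives on average two rare CNVs (copy numbers
  0–6, from one target to whole gonosomes), placed on targets and kept
  locus-unique across samples; designated common loci are planted in 5% of
  samples so the cohort frequency filter has true positives; a configurable
  fraction of samples form parent–child trios, where half the proband
  events are de novo and the rest are copied into a parent; heterozygous
  deletions in biallelic-disease genes can be paired with heterozygous,
  pathogenic SNVs on the other allele (`generate_snv_partners()`).

What the generator does *not* emulate: alignment-level artefacts
(mappability, duplicate reads, insert-size effects), segmental
duplications, mosaicism, allele-balance evidence, and correlated
within-sample waviness of real capture data. Tests that pass on this cohort
therefore demonstrate algorithmic correctness and the relative behaviour of
the callers under controlled heterogeneity — not clinical-grade sensitivity
on real exomes.

## The log-likelihood segmentation caller

`clincnv_call_cnvs()` is the fully modelled caller.

1. **Preprocessing** (shared module, fixed order): GC-extreme target
   removal → per-sample coverage QC (≥ 70% of target bases at ≥ 10 reads)
   → kit gate (≥ 30 samples) → 120 bp windowing → GC/library-size
   correction → exclusion of systematically low windows → square-root
   variance stabilisation. GC correction uses bins of width 0.05 in GC
   fraction with median scaling per bin and merging of bins under 10
   windows; library size is the per-sample median window coverage (robust
   to CNVs).
2. **Clustering.** Sample profiles (autosomes only — sex must not define a
   batch) are trimmed of top/bottom variance-quintile windows, smoothed
   with a rolling median (window 11), embedded by two-dimensional PCA
   (deterministic; a UMAP-style embedding would serve the same contract
   but is not bit-reproducible), and density-clustered with a minimum
   cluster size of 15. The clustering radius is the 95th percentile of
   15-nearest-neighbour distances: the knee-of-the-curve heuristic proved
   unstable on smooth distance curves (it can choose a radius below every
   within-cluster neighbour distance and dissolve a perfectly separated
   cohort), whereas the quantile radius clusters any group of ≥ 15
   mutually close samples and leaves the 5% most isolated profiles to be
   reassigned to the nearest centroid.
3. **Normalisation.** Each window is divided by its cluster median
   (sex-stratified on the gonosomes so a baseline male X window also
   normalises to 1).
4. **Likelihood.** In sqrt space a window at copy number *c* has mean
   `sqrt(c / ploidy)` and a per-window Gaussian spread estimated by the
   within-cluster MAD, moderated halfway towards a lowess trend of spread
   against mean window coverage. The moderation matters: raw per-window
   MADs from a few dozen samples are noisy, and windows whose spread is
   underestimated otherwise produce borderline false segments. The CN 0
   mean is floored at `sqrt(0.05)`; spreads are floored at 0.01. States
   0–6 are modelled.
5. **Segmentation.** Per chromosome (with the pseudo-autosomal stub as its
   own block) the score of window *w* under alternative state *c* is
   `loglik_c(w) − loglik_baseline(w)`; the maximum-sum contiguous segment
   over all states is found (vectorised Kadane scan with deterministic
   tie-breaking: sum, then length, then leftmost, then lowest state),
   emitted if its sum reaches 20, masked, and the search repeats.
   Boundaries are then refined by trimming edge windows contributing less
   than 0.5 log-likelihood units — without this, weakly covered flanking
   windows stretch calls across hundreds of kb and recurrent calls escape
   the 50% reciprocal-overlap rule downstream. Detection still happens on
   the untrimmed sum, which is also the reported quality.
6. **Sample QC.** A Huber robust regression of the 75th percentile of
   per-chromosome call counts on median depth, kit and ancestry label
   flags samples outside the 99.5% prediction interval (z × robust
   residual scale); the percentile response keeps one shredded long CNV
   from failing an otherwise typical sample.
7. **De novo flags.** For trio probands, a call is de novo when both
   parents' mean normalised coverage over the interval lies within ±0.2 of
   baseline in sqrt space; a missing parent yields "unknown".

## The SVD/RPKM caller

`conifer_call_cnvs()` computes RPKM per kit, standardises each target
across samples, removes the leading singular components (start at the
elbow of the singular-value curve, clipped to \[3, 15\]; sign convention
fixed for reproducibility), and calls maximal runs of targets with
residual z beyond ±1.75 (no copy number is estimated — the residual has no
absolute scale). Chromosome X runs in sex-specific pools; Y is not
analysed. The batch QC loop accepts a batch when every sample has fewer
than 30 calls, discards runaway samples (> 30 calls) when the batch median
is below 10, and otherwise removes one more component and reruns, stopping
as "unresolved" past 15 components. Before standardisation the same
systematically-low exclusion as the shared preprocessing is applied at
target resolution; weakly captured targets otherwise flood the caller with
single-target noise excursions.

Because the per-target standardisation denominator contains the full
cross-sample spread — batch contrast included — a heterozygous deletion's
z is roughly `0.5 × mean / sd_total` and drops below 1.75 wherever batch
contrast dominates. This is the mechanism behind the caller's published
weakness on short CNVs in heterogeneous cohorts, and the synthetic default
conditions reproduce it: short-deletion recall is strictly below the
log-likelihood caller's on identical input.

## The reference-matched beta-binomial caller

`exomedepth_call_cnvs()` selects, per test sample, the most-correlated
samples greedily while the test-vs-aggregate correlation keeps improving
(gain ≥ 1e−4, at most 10 members; same-sex only for the gonosomes), and
fails QC below correlation 0.97. The test count at each target is
beta-binomial out of test + reference totals with expected proportion
`(c/ploidy · e) / (c/ploidy · e + r)` under copy number *c* (`e` the
reference-profile expectation); overdispersion is estimated by method of
moments on presumed-diploid targets (5% trimmed), with a binomial fallback.
Adjacent targets agreeing on a non-baseline maximum-likelihood state merge;
the segment's Bayes factor is the log10 likelihood ratio against the
baseline, retained above 15. The observed/expected read ratio over a
segment maps to copy-number bins on diploid chromosomes:
\[0, 0.10) → CN 0, \[0.10, 0.75) → CN 1, \[0.75, 1.25) → CN 2,
\[1.25, 1.75) → CN 3, \[1.75, 2.25) → CN 4, \[2.25, ∞) → OTHER. Lower
bounds are inclusive and upper bounds exclusive; the printed bin
definitions overlap at the boundaries, so exact membership was an open
choice, documented and configurable here. At ~150–250× with ten reference
samples, a single-target heterozygous deletion carries only ~6 log10 units
and even two-target events sit near 12, so the BF > 15 rule structurally
restricts this caller to events of three targets and more — visible in all
comparative results.

## Cohort triage

* **Frequency filter.** A call is removed when strictly more than 1% of
  individuals carry a same-type call with ≥ 50% reciprocal overlap
  (pairwise; the overlap fraction is configurable — the published rule
  names no criterion). The filter is caller-agnostic and counts distinct
  individuals, so trio members sharing an inherited event both count.
* **Gene-panel restriction.** Calls must overlap ≥ 1 bp of a panel gene,
  except long CNVs (> 500 kb), which are kept regardless; on chrY only
  long calls survive (no panel contains Y genes).
* **Classes.** LONG > GONOSOMAL > HOM_DEL > HIGH_CN > DOUBLE_HIT > HET_AD,
  precedence chosen so the broadest evidence class wins; z-score calls
  without a copy number class as CN 1 / CN 3 by sign; an autosomal CN 2
  segment fits no class and is dropped.
* **Double hits.** Heterozygous CNV deletion + flagged heterozygous SNV in
  the same biallelic-disease (AR) gene and sample; homozygous deletions
  are already explanatory alone and never pair.
* **ERN strategies.** EURO-NMD discards heterozygous deletions in genes
  with haploinsufficiency score > 90 or pLI < 0.1, CN1/CN3 calls below
  log-likelihood 30, recessive-only-gene calls, and blacklisted long
  calls. GENTURIS tiers by multi-tool support, then single-tool calls at
  log-likelihood ≥ 20 or BF ≥ 15. ITHACA discards low-QC, benign and
  blacklisted calls and deletions < 10 kb / duplications < 20 kb except
  homozygous deletions and trio de novo calls, prioritises validity-score
  ≥ 3 genes, and keeps everything ≥ 200 kb. RND discards log-likelihood
  < 30 (prioritises > 200), keeps all z-score calls, and discards
  unsupported beta-binomial calls under three targets or BF < 30.
  Blacklist/benign/low-QC indicators are input flags on the call table;
  producing them (external annotation) is out of scope.

## Reporting

Coordinates are 0-based half-open throughout, so a CNV's length is
`end − start` — the convention that reproduces the printed lengths of the
curated result set shipped with the package
(`read_reported_cnvs()`; 103 CNV records and 8 SNV partners from the
Solve-RD exome re-analysis, transcribed once and kept byte-exact,
including a handful of typographical slips in the printed source).
`hgvs_name()` renders the uncertain-breakpoint nomenclature on GRCh37
RefSeq accessions; `summarize_calls()` tabulates calls per caller and
copy-number category with gonosomal sub-counts and a half-up-rounded
percentage row; `diagnostic_yield()` reports solved-family proportions to
one decimal.

## Numerical choices and degenerate inputs

* Zero medians during normalisation are floored at 1e−9; zero estimated
  spreads at the `min_sd` floor.
* Cohorts below 15 samples fall back to a single cluster with a warning;
  singular QC-regression designs drop collinear predictors with a warning;
  overdispersion-estimation failure falls back to binomial with a warning.
* Segmentation ties (exact score equality) resolve deterministically:
  longest segment, then leftmost, then lowest state.
* All generator functions run under seeds derived from the configuration
  seed and restore the caller's RNG state, so outputs are bit-identical
  across runs and independent of surrounding code.

## Problem sizes used by the test-suite

Unit tests run on 40-sample, 800-target kits; the property checks use a
100-sample, 5000-target cohort and 200 random segmentation instances
against a brute-force all-segments oracle. These sizes keep every quantity
measurable (≈ 70 eligible deletions per cohort for recovery estimates)
while the whole suite completes in about a minute.

## Known limitations

Windows derived from per-target counts are pseudo-replicates (each
target's count is spread uniformly over its windows), so evidence within a
target is perfectly correlated; with real window-level coverage the same
code applies unchanged and windows carry independent shot noise. The
interface is an analysis package, not a shell tool: the exported functions
plus `scripts/acceptance.R` are the entry points, and alignment-level
coverage extraction from BAM/CRAM is out of scope (the pipeline starts
from a counts matrix).
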