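---
title: "Quantifying PRS variability under replicate genotype imputation"
author: "prsvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PRS variability under replicate genotype imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A polygenic risk score (PRS) is a weighted sum of effect-allele dosages,

$$\mathrm{PRS}_i = \sum_{j=1}^{n} x_{ij}\,\beta_j,$$

with $x_{ij} \in [0,2]$ the dosage of the effect allele for individual $i$
at variant $j$ and $\beta_j$ the per-dosage log odds ratio. Most score
variants are not on genotyping arrays and must be imputed from a haplotype
reference panel. Some imputation pipelines — in particular those whose
pre-phasing step is stochastic — do not return the same dosages when run
twice on identical input. Because clinical interpretation of a PRS is
percentile- and tier-based ("top 5%", "bottom 20%"), run-to-run dosage
jitter can silently move an individual across a risk-tier boundary even
though neither the genotypes nor the score weights changed.

`prsvar` makes that phenomenon measurable on fully synthetic data: it
generates a cohort with known truth genotypes, emulates replicate
imputation with controllable stochasticity, and quantifies the resulting
percentile and tier instability per individual and per SNP.

## Pipeline overview

1. **Synthetic cohort** (`simulate_study()`): two populations with
   Balding–Nichols frequency divergence, block-LD haplotype panels, a PRS
   weight model, and a typed/untyped variant mask.
2. **Imputation emulator** (`emulate_hmm()`, `emulate_parametric()`): K
   replicate dosage matrices per process.
3. **Scoring and ranking** (`compute_prs()`, `percentile_rank()`,
   `build_percentile_frame()`): ancestry-stratified midrank percentiles for
   the truth and each replicate.
4. **Variability statistics** (`percentile_range_table()`,
   `deviation_by_bin()`, `reclassification_matrix()`,
   `highrisk_reclassification()`).
5. **Accuracy metrics** (`dosage_r2()`, `genotype_fscore()`, `iqs()`,
   `per_individual_r2_summary()`, `maf_binned_accuracy()`,
   `best_tag_ld()`, `paired_process_comparison()`).
6. **Per-SNP decomposition** (`snp_gini()`,
   `percent_variance_explained()`, `contribution_quadrants()`).

The numbered scripts under `analysis/` run these stages end to end and
write their tables under `results/`; every number they print is computed
by the package functions above.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis needs, not
human demography.

* **Ancestral frequencies** are drawn with minor-allele frequency uniform
  on a configurable range (default 0.05–0.5) and random allele
  orientation. Uniform is the simplest controllable choice; nothing
  downstream assumes a frequency spectrum shape.
* **Population divergence** follows the Balding–Nichols model: population
  frequencies are Beta-distributed with mean $p$ and variance
  $F_{ST}\,p(1-p)$ (shapes $p(1-F_{ST})/F_{ST}$ and
  $(1-p)(1-F_{ST})/F_{ST}$). The default $F_{ST}=0.15$ is the classic
  European–African scale of divergence.
* **Haplotype panels** get linkage disequilibrium from founder copying:
  variants are partitioned into blocks (default 100 variants); within a
  block each haplotype copies one of `n_founders` (default 4) founder
  patterns and each allele is re-drawn at the target frequency with a
  small mutation probability (default 0.005). Marginal frequencies stay
  unbiased while haplotypes sharing a founder are strongly correlated, so
  LD is high within blocks and zero across them. With `block_length = 1`
  alleles are drawn iid Bernoulli — with copying, even a one-variant block
  would carry founder-driven frequency noise of order $p(1-p)/n_\mathrm{founders}$,
  which would break the frequency-recovery property.
* **Cohort and reference panel share one draw.** The population-A cohort
  pool and the imputation reference panel are disjoint subsets of a single
  generated panel, so they share founder/LD structure the way a study
  cohort and a matched reference resource do. Population B gets an
  independent draw at its diverged frequencies: the reference panel is
  mismatched to B in both frequency and haplotype structure, which is what
  makes B's imputation — and hence its score percentiles — visibly less
  stable.
* **PRS weights** are Normal(0, `weight_scale`) with a handful of
  variants multiplied by `high_weight_multiplier` (default 4 variants,
  times 5), emulating scores dominated by a few large-effect loci.

What the generator does **not** emulate: recombination maps, admixed
individuals, strand/allele harmonization issues, genotyping error in the
typed variants, and realistic rare-variant spectra (with 4 founders per
block, realized cohort frequencies cluster coarsely; rare-MAF accuracy
bins exist but are sparsely populated under defaults). Passing tests
therefore demonstrate the statistical machinery, not engine-level realism
on real cohorts.

## The imputation emulator

### Haplotype-copying (Li–Stephens) mode

Each truth haplotype is treated as a mosaic of reference-panel
haplotypes. The copying chain has states = panel haplotypes, switches to a
uniformly random haplotype with probability `rho` per site (default
0.005), and emits the copied allele with mismatch probability `theta`
(default 0.01) at typed sites; untyped sites emit nothing. Forward–backward
is computed with per-site scaling, batched over chains as matrix
operations.

Two modes operationalize the deterministic-vs-stochastic engine contrast:

* **deterministic** — the untyped dosage is the posterior mean
  (sum of the two haplotypes' posterior allele probabilities); replicates
  are identical by construction, like an engine whose pre-phasing is
  deterministic.
* **sampled** — each replicate backward-samples one copying path per
  haplotype and emits the path's alleles, so replicates differ run to
  run, like an engine with stochastic pre-phasing. The mean of many
  sampled replicates converges to the deterministic dosage.

Diplotypes are treated as two independent haploid chains conditional on
the known truth phase; phase-switch error itself is not modelled. The
defaults were calibrated so that deterministic-mode aggregate accuracy
sits in the realistic > 0.9 dosage-$R^2$ regime reported for production
engines on common variants; with less haplotype sharing (shorter blocks,
more founders, higher mutation) the emulator degrades into an
unrealistically hard imputation problem.

### Parametric mode

For studying noise structure in isolation, `emulate_parametric()` skips
haplotypes entirely: for each untyped variant with truth variance $V$, it
adds Gaussian error with total variance $V(1-R^2_\mathrm{target})/R^2_\mathrm{target}$,
so the expected imputed-vs-truth squared correlation equals
`r2_target`. The error is split into a per-(individual, variant) component
shared by all replicates (systematic difficulty) and an independent
per-replicate component with standard deviation `sigma_run` (run
stochasticity). Dosages are clipped to $[0,2]$ and the achieved
post-clipping $R^2$ is recorded; if `sigma_run` exceeds the total error
budget it is capped and noted.

A consequence of this *partition* design worth stating explicitly:
because the total error variance is pinned by `r2_target`, increasing
`sigma_run` redistributes error from the shared to the per-run component
without changing any replicate's marginal deviation from the truth. So
between-replicate summaries (percentile range, replicate-vs-mean
re-classification, spread around the replicate mean, the per-individual
*minimum* accuracy) grow with `sigma_run`, while population-mean accuracy
and the typical deviation from the truth-based percentile stay flat.
That is exactly the masking phenomenon the package exists to expose: two
processes with indistinguishable average accuracy can differ sharply in
individual-level stability.

## Scoring, ranking, tiers

* **Percentiles** use the midrank convention within each ancestry group:
  $100\,(c_< + 0.5\,c_=)/n$. The group mean is exactly 50 regardless of
  ties, and percentiles are invariant to shifting or positively rescaling
  the scores.
* **Replicate ranking**: by default each replicate's scores are ranked
  within that replicate's own distribution (per ancestry group), the
  natural reading of within-cohort ranking; ranking replicate scores
  against the truth-score distribution is available via
  `rank_within = "truth"`.
* **Tiers**: quintile tiers use strict outer inequalities — percentile
  < 20 is low, > 80 is high, boundaries fall in the intermediate tier —
  matching the "< 20%tile" / "> 80%tile" phrasing of tier tables. Refined
  one-sided tiers (`< 5`, …, `> 95`) use strict inequalities in the stated
  direction.
* **Missing score variants are an error**, not silently dropped: variant
  exclusion is a modelling decision that belongs upstream, and an
  effect allele matching neither REF nor ALT is likewise refused rather
  than guessed.

## Variability and re-classification statistics

* The **percentile-change table** counts individuals whose replicate
  range (max − min of the K replicate percentiles) exceeds 1/5/10/20
  points, per stratum and combined; "≤ 1" and "> 1" partition each
  stratum exactly at range = 1.
* **Deviation by bin** bins individuals by truth percentile (default 10
  equal-width bins) and summarizes each individual's mean and maximum
  absolute replicate deviation from the truth percentile with quartiles
  and Tukey whiskers. Percentile variability peaks mid-distribution and
  shrinks at the tails: equal-sized raw-score perturbations move ranks
  most where the score density is highest.
* The **tier matrix** is accumulated over all (individual, replicate)
  pairs as (single-replicate tier) × (tier of the individual's mean
  replicate percentile). The published table this mirrors is ambiguous
  about its row/column semantics, so the replicate-vs-truth confusion
  matrix is also emitted as a secondary output.
* **Refined-tier re-classification**: among individuals whose truth
  percentile is inside a one-sided tier, the rate of those with ≥ 2
  replicates outside it, with an *untruncated* Wald 95% CI
  $\hat{p} \pm 1.96\sqrt{\hat{p}(100-\hat{p})/m}$. Wald is the
  deliberate choice because the reference tables print negative lower
  bounds, which only an untruncated normal interval produces; empty tiers
  report NA.

## Accuracy metrics

Dosage $R^2$ is the squared Pearson correlation, defined as 0 for a
constant vector (the conservative reading of an undefined correlation).
Genotype F-score is macro-averaged F1 over the genotype classes present
in the truth; IQS is the chance-adjusted agreement (kappa-type) of the
3×3 genotype table, 1 only under perfect agreement and possibly negative.
Hard calls derive from dosages by rounding to the nearest of {0,1,2} with
ties (0.5, 1.5) rounding down. Per-individual accuracy is computed across
untyped variants only by default — typed variants are copied from the
truth and would inflate accuracy. MAF bins are half-open `(a, b]` with
default edges 0.005/0.01/0.05/0.1/0.5, so a variant exactly on an edge
falls in the lower bin.

## Per-SNP decomposition

For each variant, each individual's K replicate dosages give a Gini
coefficient $\sum_{a,b}|x_a-x_b| / (2K^2\bar{x})$ (0 when $\bar x = 0$ or
all values are equal); the variant's Gini is the mean over individuals,
so 0 means perfectly consistent imputation and typed variants are 0
exactly. Aggregating per individual first (rather than pooling all
individual × replicate dosages) keeps the statistic a pure
*within-individual* consistency measure; the pooled variant is available
behind a switch but excluded from the invariance guarantees. Percent
variance explained is $\beta_j^2\,\widehat{\mathrm{Var}}(x_j)$ normalized
to 100 using the empirical truth-dosage variance — defined without any
Hardy–Weinberg assumption ($2p(1-p)$ serves only as a test oracle).
Quadrant labels separate high-PVE variants with nonzero imputation
variability (single-SNP score excursions) from low-PVE/high-Gini variants
(error accumulation across many small effects).

## Numerical and reproducibility choices

* All randomness flows from one master seed through
  `derive_seeds()`; per-stage streams are restored after use, so stages
  are insensitive to evaluation order and identical configurations give
  bit-identical outputs.
* Forward–backward uses per-site scaling; a zero forward mass raises an
  error naming the offending position (reachable only with `theta = 0`).
* Dosages are validated into $[0,2]$ with a 1e-9 float tolerance.
* VCF I/O uses `vcfR`; dosages round-trip at the written 3-decimal
  precision, records are ordered by (chromosome, position), and
  multiallelic records are rejected by site (they must be excluded
  upstream).

## Problem sizes used by the test suite

The packaged analyses run at desk scale, chosen to keep the full suite
fast while leaving the qualitative contrasts unambiguous: the
stochastic-vs-deterministic contrast uses one cohort of 2,000 individuals
with 200 score SNPs (25% typed, K = 6) on a matched single-population
panel; the reference-mismatch contrast uses 600 + 600 individuals across
two populations at $F_{ST} = 0.15$; noise-monotonicity uses 800
individuals × 150 SNPs with `sigma_run` ∈ {0, 0.05, 0.15}. The default
`analysis/` configuration is a 1,700 + 300 two-population cohort,
mirroring a majority-ancestry study with a majority-matched reference
panel.

## Limitations

The emulator's sampled mode draws one copying path per haplotype per
replicate, which makes it *more* dispersed than production stochastic
engines (those average internal iterations); its tables are therefore
qualitative analogues, not calibrated reproductions, of engine-level
results on real cohorts. Real-data effects that are out of scope here:
reference panels at biobank scale, phase-switch error, genotyping error,
multiallelic and duplicated sites, and LD-aware score re-weighting.
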