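---
title: "Screening tumor cohorts for magnesium-associated multi-omics signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tumor cohorts for magnesium-associated multi-omics signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgscreen)
```

## The scientific problem

Intratumoral magnesium content — micrograms of Mg per gram of extracted
protein, measured by ICP-MS — varies severalfold between colorectal tumors
and is associated with patient survival. mgscreen implements the desk
workflow for asking, cohort-wide, which molecular features track that
variation: which proteins and phosphosites correlate with Mg content, which
genes are differentially mutated between High-Mg and Low-Mg tumors, whether
mutations co-occur or exclude one another within each group, and how Mg
content relates to overall survival.

The package has six coordinated parts: a quantification-cleaning pipeline
for batched isobaric-label (TMT) data, a Spearman screening layer, a
somatic-mutation association layer, a self-contained survival kit, local
enrichment statistics, and a synthetic-cohort generator that plants known
effects so every claim the other five parts make can be checked against a
ground truth.

## Cleaning batched TMT quantification tables

Multi-batch TMT designs are only comparable through a common reference: each
batch carries one internal-standard (IS) channel, a pooled sample labeled
and measured alongside the real samples. The cleaning pipeline is a fixed
sequence of stages, and each matrix carries a stage tag so that operations
refuse inputs in the wrong order:

1. **Read and flag-filter** (`read_quant_table()`): potential contaminants
   and reverse-database hits are dropped; a zero intensity is treated as a
   non-detection from the start.
2. **Identification-quality filters** (`filter_features()`): proteins need
   at least 2 unique peptides; phosphosites need localization probability
   strictly above 0.75 (a site at exactly 0.75 is dropped — the inequality
   is deliberately strict, and the boundary is tested).
3. **Equal-total scaling** (`scale_total_intensity()`): channel sums over
   observed values are equalized within the batch, absorbing loading
   differences. Sums use observed (nonzero) values only, since a zero is a
   non-detection rather than a measurement of zero.
4. **IS bridging** (`bridge_to_is()`): sample channels are divided row-wise
   by the IS channel, giving sample-to-standard (S/S) ratios comparable
   across batches; a row with a missing IS value becomes missing for the
   whole batch.
5. **Combination and log2** (`combine_batches()`): outer join across
   batches on feature ids, then log2.
6. **Dual z-scoring** (`zscore()`): column (sample) z-scores then row
   (feature) z-scores over observed entries. The column-then-row order is
   a package decision — column standardization first removes residual
   per-sample loading before features are standardized — and the order is
   exposed as an argument and recorded in the matrix provenance notes,
   since the reverse order is also defensible.
7. **Missingness filter** (`filter_missing()`): features missing in
   strictly more than 50% of samples are removed; exactly 50% survives.

Because bridging divides by the IS and z-scoring standardizes each sample,
multiplying every intensity of a batch by a constant leaves the final
matrix unchanged — an invariance the test suite asserts end to end.

Differential abundance between paired tumor and normal samples uses the
two-sided Wilcoxon rank-sum test (exact for small groups without ties,
normal approximation with tie correction otherwise, as provided by
`stats::wilcox.test`) with the effect summarized as the median log2 fold
change; for cell-line experiments the conventional flagging rule
(ratio > 1.2 or < 0.83 and p < 0.05) is provided as
`flag_cell_differential()`.

## Screening features against Mg content

`spearman_screen()` computes per-feature Spearman correlations against Mg
content on pairwise-complete observations, with average ranks for ties.
P-values come from exhaustive permutation enumeration for n ≤ 9 — valid
under ties, where the usual exact algorithms are not — and from the t
approximation on n − 2 degrees of freedom otherwise. Screening is at raw
p < 0.05, matching the field convention for this kind of hypothesis-free
screen; Benjamini–Hochberg q-values are reported alongside so users can
apply a stricter criterion. Features with fewer than `min_pairs = 10`
complete pairs are reported untested rather than silently dropped.

Side-stratified screening (`stratified_screen()`) re-screens within each
stratum at the same level and reports the per-direction overlap algebra
(both / left-only / right-only), mirroring how left- and right-sided
tumors are contrasted in colorectal work.

For phosphosites the interesting claim is that a site tracks Mg
*independently of its parent protein's abundance*. That phrase is not an
algorithm, so the package defines one: `protein_adjusted_phospho_screen()`
computes a partial Spearman correlation — ranks of site, Mg and parent
protein; correlation of the residuals after regressing on the protein
ranks, which reduces to the standard partial-correlation formula — and
flags a site as protein-independent only when the marginal and partial
tests are both significant with concordant sign. Sites whose parent is
absent are reported marginal-only; a parent missing in more than half of a
site's complete pairs skips the partial test rather than fabricating one.

## Mg groups, mutations, and somatic interactions

The cohort is dichotomized on Mg content (`dichotomize_mg()`), by default
at the maximally selected log-rank cutpoint against overall survival, with
median and fixed-threshold modes for sensitivity analysis. A sample is
Low-Mg iff its Mg content is strictly below the threshold, and the fitted
threshold is reusable on a subcohort (e.g., the subset with exome data) via
`label_mg()`.

The mutation layer follows the conventions of exome cohort analysis:

- **Burden and hypermutation** (`compute_tmb()`,
  `hypermutation_filter()`): mutations per Mb on a 38-Mb exome (the
  denominator is configurable — capture kits differ and the convention is
  not universal); samples above 10/Mb *that also carry a non-silent
  mutation in a mismatch-repair or replicative-polymerase gene* (MSH2,
  MSH6, MLH1, PMS2, POLD1, POLE) are excluded. Hypermutated samples
  without such a mutation are retained — the filter removes explained
  hypermutation, not high burden per se.
- **Gene-size filter** (`gene_size_filter()`): genes of 5000 or more amino
  acids are removed (strictly "fewer than 5000" survive), since giant
  genes accumulate passenger mutations in proportion to their length; a
  minimal annotation ships with the package.
- **Per-gene screen** (`fisher_gene_screen()`): 2×2 mutated/wild-type ×
  High/Low-Mg tables, two-sided Fisher exact p by the probability-mass
  convention (all tables with point probability at or below the observed),
  odds ratio (a·d)/(b·c) with a 0.5-continuity value reported separately
  for zero cells. Genes mutated in fewer than 3 samples are not tested —
  their tables cannot be informative.
- **Substitution spectra** (`snv_class_summary()`): SNVs collapse to the
  six pyrimidine-referenced classes by complementing purine references.
- **Somatic interactions** (`somatic_interactions()`): pairwise Fisher
  tests over the top-20 most mutated genes, calling co-occurrence (odds
  ratio > 1) or mutual exclusivity, flagged at p < 0.01 and p < 0.05.

## Survival statistics

The survival kit is self-contained: Kaplan–Meier with Greenwood standard
errors and log-log bands; the k-group log-rank test; Cox regression by
Newton–Raphson on the Breslow partial likelihood (months-resolution
survival guarantees ties, and Breslow is the simplest defensible tie
convention; convergence at max |score| < 1e-8 or relative log-likelihood
change < 1e-10, with step-halving, and monotone likelihoods flagged
non-converged rather than reported); and the maximally selected log-rank
cutpoint. The cutpoint scan considers midpoints between sorted distinct
covariate values leaving at least `ceil(minprop × n)` samples per side
(minprop = 0.1, the conventional default). Its p-value is computed by
permuting the covariate against the (time, event) pairs and comparing the
observed maximal statistic with the permutation distribution of maxima;
the naive p-value that ignores the maximal selection is reported too, and
a test asserts it is anti-conservative. Permutation was preferred over the
analytic improved-Bonferroni approximation because it is exact up to Monte
Carlo error, verifiable, and seed-controlled.

The test suite cross-checks every one of these against the survival
package (coefficients and standard errors to ~1e-7) while the
implementations remain independent. One identity worth noting: the Cox
score test at β = 0 for a two-group covariate equals the log-rank
statistic in the absence of ties, which is asserted numerically. The
partial-likelihood estimate and the closed-form two-sample exponential MLE
are distinct finite-sample estimators that agree only asymptotically;
agreement is therefore asserted at n = 2000 with a 2% tolerance rather
than at machine precision.

## Enrichment

`preranked_gsea()` implements the weighted Kolmogorov–Smirnov running sum:
walking down the list ranked by score (here, typically Spearman rho
against Mg), hits add |score|^weight normalized over the set, misses
subtract 1/(N − set size); the enrichment score is the maximal deviation.
The null is gene-label permutation — the natural choice for a preranked
list, where no phenotype labels exist to permute. NES divides ES by the
mean same-sign null |ES|; nominal p is the same-sign null tail; FDR pools
the set-wise normalized null separately for positive and negative scores.
Weight = 1 is the default (classic weighted statistic) and weight = 0
gives the rank-only statistic that is invariant under monotone transforms
of the scores. The ES computation is asserted equal to
`fgsea::calcGseaStat` to 1e-12 on random inputs, with fgsea serving only
as a cross-check. `ora_hypergeom()` provides local hypergeometric
over-representation with BH q-values as a replacement for web-service
enrichment tools.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions end to end: 115 patients
(tumor + paired distant normal tissue), 27 batches of a 10-plex with one
IS channel each, Mg content uniform on 162–920 µg/g, roughly a quarter of
proteins positively and a quarter negatively Mg-correlated, about half the
patients censored, and a small set of hypermutators of which ~70% carry a
mismatch-repair mutation (scaled from 14 of 20). Feature-space sizes
default to desk scale (2000 proteins, 600 phosphosites, 400 background
genes): the real identification counts are outcomes of an experiment, not
parameters of it, and the statistical behavior under test does not depend
on them. The tests and acceptance script run on cohorts of 30–115 patients
and 80–300 proteins, sizes at which every Monte-Carlo check completes in
seconds to a few minutes.

**Correlation planting.** A latent standard-normal patient score drives
both Mg (by the probability-integral transform, hence rank-preserving) and
planted feature abundances through a Gaussian copula. For a bivariate
Gaussian pair, Spearman's rho relates to the Pearson correlation by
ρ_s = (6/π)·asin(r/2), so the base latent coupling is r = 2·sin(πρ_s/6),
inflated for measurement and IS noise. One further correction matters:
equal-total scaling followed by per-sample centering subtracts the
feature-average coupling from every feature (a compositional effect), so
unbalanced plantings would otherwise be attenuated and, in the extreme,
planting *all* features in one direction is impossible — the generator
solves the post-centering calibration exactly (a quadratic per direction,
iterated with the mean constraint) and raises an explicit error for
infeasible targets instead of clipping. Planted Spearman targets are
recovered within ±0.05 at cohort scale; the acceptance suite asserts ±0.1
at n = 100.

**What the generator does not emulate.** Missingness is MCAR by default
(an intensity-dependent MNAR option exists) because the source data's
missingness mechanism is uncharacterized; there is no peptide-level
structure (a per-protein unique-peptide count suffices to exercise the
filter); no copy-number events; no correlation structure between features
beyond the shared Mg driver and phosphosite–parent coupling. Passing tests
therefore demonstrate that the statistics do what they claim under a known
generative model — not that real colorectal data satisfies that model.

**Mutations and survival.** Background genes mutate independently at 5%;
planted genes use group-specific frequencies relative to the true Mg
cutpoint (the midpoint of the Mg range); Low-Mg SNVs are drawn with a T>C
heavy spectrum; hypermutators receive 12–20 mutations/Mb. Survival is
exponential with log-hazard linear in standardized Mg (default −0.7 per
SD: higher Mg, lower hazard), independent exponential censoring calibrated
to the target censoring fraction, and administrative capping at 120
months, with times rounded up to whole months to guarantee the tie
structure that months-resolution follow-up produces.

**Determinism.** Identical configurations (including the seed) produce
identical bundles, byte-identical files from `write_cohort()`, and
byte-identical pipeline outputs from `run_pipeline()`.

## Numerical and design choices collected

- Exact Spearman p by full enumeration up to n = 9 (valid under ties);
  beyond that, the t approximation. Exact Fisher p by the probability-mass
  two-sided convention, the mainstream choice.
- The maximally selected cutpoint recovers a planted threshold reliably
  when the covariate separates groups coarsely; with a continuous
  covariate and overlapping lifetime distributions the argmax can land a
  few order statistics outside a planted gap because the standardized
  statistic's variance term varies with the split — the recovery checks
  use coarse, well-separated clusters for that reason.
- Degenerate inputs error loudly: all-zero channels, absent IS channels,
  constant covariates, no events, perfect separation (flagged
  non-converged), infeasible copula targets.
- Tie conventions: at a tied event and censoring time the censored subject
  is still at risk (standard KM); Breslow for Cox.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  synthesize = list(n_patients = 40, n_batches = 10, plex_size = 9,
                    n_proteins = 300, n_phosphosites = 80, n_genes = 60),
  seed = 101)
manifest <- run_pipeline(cfg, "mgscreen_out")
results <- attr(manifest, "results")
results$screen[results$screen$significant, ][1:5, ]
results$survival$cox
```

The run writes per-stage TSV/JSON outputs plus a manifest recording the
package version, seed, thresholds, input checksums and stage status;
re-running with the same configuration reproduces the outputs byte for
byte.
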