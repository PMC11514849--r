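# mgscreen

Magnesium-associated multi-omics screening for tumor cohorts.

## What problem this solves

Intratumoral magnesium content (µg Mg per g extracted protein, by ICP-MS)
varies severalfold across colorectal tumors and carries prognostic
information. Given a cohort with batched TMT proteomics/phosphoproteomics,
somatic mutation calls, Mg measurements and survival follow-up, mgscreen
answers the screening questions end to end:

- which proteins and phosphosites correlate with Mg content
  (Spearman screen; side-stratified; partial-correlation adjustment for
  the parent protein of each phosphosite);
- which genes are differentially mutated between High-Mg and Low-Mg
  tumors, after hypermutation/mismatch-repair exclusion and gene-size
  filtering, and whether mutations co-occur or are mutually exclusive;
- how Mg content relates to overall survival (Kaplan–Meier, log-rank,
  maximally selected cutpoint with a permutation p-value, Cox regression);
- which gene sets are enriched in the Mg-ranked feature list (local
  preranked GSEA and hypergeometric over-representation).

A synthetic-cohort generator with planted, analytically calibrated effects
makes the whole pipeline testable without access to restricted
patient-level data.

## The statistics at the core

**Internal-standard bridging.** Each TMT batch carries an internal-standard
(IS) channel. After equalizing channel totals within a batch, sample
intensities are divided row-wise by the IS channel, giving
sample-to-standard values S/S that are comparable across batches; the
combined matrix is log2-transformed, column- then row-z-scored, and
features missing in > 50% of samples are dropped. Zeros are
non-detections and become missing.

**Mg screen.** For feature *x* and Mg content *m*, Spearman's ρ on
pairwise-complete observations; two-sided p by exhaustive permutation for
n ≤ 9 (valid under ties) and by t = ρ√((n−2)/(1−ρ²)) otherwise.
Phosphosite independence from the parent protein uses the partial rank
correlation ρ(site, Mg | protein) with both marginal and partial
significance required at concordant sign.

**Mutation screen.** Per gene, the 2×2 table (mutated/wild-type ×
High/Low-Mg) with two-sided Fisher exact p (probability-mass convention)
and odds ratio (a·d)/(b·c). Hypermutated samples (TMB > 10/Mb on a 38-Mb
exome) are excluded only when they carry a non-silent mutation in
MSH2/MSH6/MLH1/PMS2/POLD1/POLE.

**Survival.** Kaplan–Meier with Greenwood errors; k-group log-rank;
maximally selected log-rank cutpoint over admissible splits
(≥ 10% of samples per side) with a permutation p-value for the maximum;
Cox partial likelihood (Breslow ties) by Newton–Raphson.

**Enrichment.** Weighted Kolmogorov–Smirnov running sum (hits add
|score|^w normalized over the set, misses subtract 1/(N−|S|)); null by
gene-label permutation; NES, same-sign nominal p, and sign-pooled FDR.

## Worked example

```r
library(mgscreen)
cfg <- pipeline_config(
  synthesize = list(n_patients = 40, n_batches = 10, plex_size = 9,
                    n_proteins = 300, n_phosphosites = 80, n_genes = 60),
  seed = 101)
manifest <- run_pipeline(cfg, "mgscreen_out")
results <- attr(manifest, "results")

results$protein
#> <mg_expr> 269 features x 80 samples | stage: zscore | 10 batch(es) | 14.8% missing

head(results$screen[results$screen$significant, ], 4)
#>     feature   rho        p        q  n direction
#> 62 PROT0067 0.727 5.23e-07 0.000121 36  positive
#> 46 PROT0051 0.733 1.23e-06 0.000121 33  positive
#> 1  PROT0001 0.716 1.35e-06 0.000121 35  positive
#> 17 PROT0018 0.701 2.68e-06 0.000164 35  positive

results$groups
#> <mg_groups> threshold 315.3 (max_logrank): High-Mg n=33, Low-Mg n=7

results$survival$cox
#> <mg_cox> converged
#>            coef        se        hr  lower95  upper95
#> mg_z -0.4581769 0.2518155 0.6324356 0.386074 1.036005

head(results$somatic$screen[, c("gene", "freq_high", "freq_low", "p")], 2)
#>    gene freq_high freq_low       p
#> 29 LMG2    0.1724    0.857 0.00142
#> 30 LMG3    0.1724    0.857 0.00142
```

Reading the output: 114 of 269 retained proteins screen significant at
p < 0.05 (147 were planted as Mg-correlated in this cohort's truth
ledger); the Cox hazard ratio of 0.63 per SD of Mg reflects the planted
protective effect of higher Mg; genes LMG2/LMG3 were planted with higher
mutation frequency in Low-Mg tumors and are recovered by the Fisher
screen. Every run writes per-stage TSV/JSON outputs and a manifest (seed,
thresholds, input checksums, stage status); identical configurations
reproduce outputs byte for byte.

A thin command-line wrapper is available at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --synthetic --seed 7 --out out/
```

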