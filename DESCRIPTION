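Package: mgscreen
Title: Magnesium-Associated Multi-Omics Screening for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening tumor cohorts for associations between
    intratumoral magnesium content and proteomic, phosphoproteomic, genomic
    and survival data. Implements internal-standard bridging normalization of
    batched isobaric-label (TMT) quantification tables, Spearman screening of
    features against metal content (marginal, side-stratified and
    protein-adjusted partial correlation for phosphosites), somatic-mutation
    association between metal-content groups (tumor mutational burden,
    hypermutation and mismatch-repair exclusion, per-gene Fisher screening,
    substitution spectra, pairwise co-occurrence and mutual exclusivity),
    self-contained survival statistics (Kaplan-Meier, log-rank, maximally
    selected log-rank cutpoint with permutation p-values, Cox partial
    likelihood), local preranked gene-set enrichment (weighted
    Kolmogorov-Smirnov running sum) and hypergeometric over-representation.
    A synthetic-cohort generator with planted effects makes the full pipeline
    testable without access to restricted patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    fgsea,
    optparse
Config/testthat/edition: 3
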