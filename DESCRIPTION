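Package: vepbench
Title: Benchmarking Variant Effect Predictors in Population Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cohort-based benchmarking of computational variant effect
    predictors against participant genotypes and phenotypes. Applies
    site- and call-level genotype quality control with a dual cohort and
    reference rarity filter to rare missense variants, orients and
    winsorizes predictor scores, aggregates them into participant-centric
    additive burden scores, and measures per gene-trait performance as
    the area under the balanced precision-recall curve (binary traits) or
    the squared Pearson correlation of variant-mean trait values
    (quantitative traits). Uncertainty is estimated by paired bootstrap
    resampling of participants; predictors statistically indistinguishable
    from the per-combination top performer are called ties via empirical
    p-values and Storey q-values, and an overall tie-broken ranking is
    built from best-or-tied counts and a pairwise Wilcoxon signed-rank
    matrix. A synthetic cohort simulator with configurable predictor
    fidelity, orientation and missingness makes the full pipeline testable
    without access to controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
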