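# vepbench

Benchmarking computational variant effect predictors (VEPs) against
population cohorts of genotyped and phenotyped participants.

Dozens of computational predictors assign each missense variant a score
reflecting how damaging it is expected to be. Classical evaluations rank
them against curated clinical labels, which raises circularity concerns:
many predictors were trained on, or indirectly informed by, the same
label sets. An alternative is to ask how well each predictor's scores
explain *human traits* in a sequenced cohort: for gene–trait pairs with a
known rare-variant burden association, a better predictor should separate
trait carriers from non-carriers (binary traits) or track quantitative
trait values (continuous traits) using nothing but its per-variant
scores. `vepbench` implements that benchmarking framework as a tested R
pipeline, together with a synthetic cohort simulator so the whole
analysis is reproducible without access to controlled cohort data.

## Method

For each gene–trait combination:

- **Genotype QC.** Variants must have site Phred quality > 20, call
  missingness < 10%, at least one carrier with read depth ≥ 7 passing the
  allele-balance threshold (0.15 discovery profile, 0.20 validation
  profile), and minor allele frequency < 0.1% in **both** the cohort and
  a reference panel.
- **Score preparation.** Predictors that assign low scores to damaging
  variants are negated; a predictor joins a gene's comparison only if it
  scores ≥ 10 of the gene's variants. For binary traits, scores are
  winsorized at the 5th/95th percentiles, normalized to [0, 1], and
  summed per participant over carried variants (additive model: two
  variants scored 0.5 give a participant-centric score of 1).
- **Performance.** Binary traits: the area under the balanced
  precision–recall curve (AUBPRC), where balanced precision
  `TPR / (TPR + FPR)` is the precision expected at a 50% prior on
  positives. Quantitative traits: the squared Pearson correlation (PCC²)
  between variant scores and variant-mean trait values.
- **Uncertainty and ties.** Participants are bootstrap-resampled (10k
  iterations by default) with the *same* resamples applied to every
  predictor. For each predictor pair, the empirical p-value is the
  fraction of iterations in which the better-on-average predictor is
  outperformed (ties count). Storey q-values convert the pooled p-value
  family to FDRs; predictors with q ≥ 10% against the per-combination top
  performer are *tied for best*.
- **Overall ranking.** Predictors are ranked by the number of
  combinations where they are best or tied. Ties are broken by the number
  of rivals each predictor significantly outperforms in a pairwise
  two-tailed Wilcoxon signed-rank matrix over per-combination means, then
  by head-to-head comparison of q-value rows. Cross-cohort agreement
  between two rankings is Kendall's tau-b.

The synthetic cohort simulator emulates the statistical structure this
analysis expects: rare (MAF < 0.1%) missense variants, additive
per-variant effects on a quantitative trait and a liability-threshold
binary trait, roughly 1–2% of carriers holding multiple variants in a
gene, and a panel of predictors whose scores are noisy monotone
transforms of the true effect magnitudes with configurable noise,
orientation and missingness.

## Worked example

```r
library(vepbench)
cfg <- run_config(simulation = sim_config(seed = 42),
                  iterations = 1000, seed = 7, verbose = FALSE)
res <- run_pipeline(cfg)
print(res)
```

```
vepbench benchmarking report
seed: 7  iterations: 1000

== gene01|bt1 (AUBPRC) ==
  pred_hi          mean 0.7208  [0.5961, 0.8367]  (dropped 0) *tied-for-best*
  pred_mid         mean 0.7041  [0.5620, 0.8291]  (dropped 0) *tied-for-best*
  pred_lo          mean 0.6613  [0.5060, 0.8045]  (dropped 0) *tied-for-best*

== gene01|qt1 (PCC2) ==
  pred_hi          mean 0.5513  [0.2921, 0.7035]  (dropped 0) *tied-for-best*
  pred_mid         mean 0.5014  [0.2385, 0.6987]  (dropped 0) *tied-for-best*
  pred_lo          mean 0.0157  [0.0000, 0.0726]  (dropped 0)

== gene02|bt1 (AUBPRC) ==
  pred_hi          mean 0.8267  [0.7345, 0.9032]  (dropped 0) *tied-for-best*
  pred_mid         mean 0.8109  [0.7120, 0.8939]  (dropped 0) *tied-for-best*
  pred_lo          mean 0.6677  [0.5457, 0.7843]  (dropped 0)

== gene02|qt1 (PCC2) ==
  pred_hi          mean 0.5008  [0.2673, 0.7297]  (dropped 0) *tied-for-best*
  pred_mid         mean 0.4651  [0.2878, 0.6460]  (dropped 0) *tied-for-best*
  pred_lo          mean 0.1848  [0.0354, 0.3791]  (dropped 0) *tied-for-best*

== overall ranking ==
  rank  1=  pred_hi          best-or-tied 4  wins 0
  rank  1=  pred_mid         best-or-tied 4  wins 0
  rank  3   pred_lo          best-or-tied 2  wins 0
```

The default synthetic panel has three predictors whose score noise
standard deviations are 0.1 (`pred_hi`), 0.5 (`pred_mid`) and 2.0
(`pred_lo`). Each per-combination block reports the bootstrap mean of
the metric with its percentile 95% CI; `*tied-for-best*` marks
predictors statistically indistinguishable (FDR ≥ 10%) from the top
performer of that combination. Here the low-fidelity predictor is
excluded from the tied set in two of four combinations and ranks last
overall; the two high-fidelity predictors remain tied at four combos
each — with only four combinations the pairwise Wilcoxon matrix (minimum
two-tailed p of 0.125 at n = 4) cannot separate them, which is the
expected behaviour at this problem size.

Real cohort data enter through `run_config(vcf = ..., phenotypes = ...,
scores = ..., predictors = ..., combos = ...)` using a VCF plus
tab-separated phenotype, score, predictor-orientation and gene–trait
tables; `write_cohort_fixture()` documents the exact formats by example.

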