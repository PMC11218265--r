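---
title: "Cohort-based benchmarking of variant effect predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-based benchmarking of variant effect predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vepbench)
```

## The problem

Computational variant effect predictors assign each missense variant a
score for predicted functional damage. Evaluating them against curated
clinical labels invites circularity, because many predictors were trained
on those same labels. `vepbench` instead scores predictors by how well
their per-variant scores explain participant traits in a sequenced
cohort, for gene–trait pairs with an established rare-variant burden
association. The unit of evaluation is the *gene–trait combination*; the
two performance measures are the area under the balanced precision-recall
curve (binary traits) and the squared Pearson correlation of variant-mean
trait values (quantitative traits).

This vignette records the model, the tunable parameters, the numerical
choices, and the design decisions taken where the procedure was genuinely
open — the things a maintainer would want written down.

## Genotype quality control

Sites pass QC when

* site Phred quality strictly exceeds 20 (`min_quality`, exclusive,
  matching the wording "quality score > 20"),
* call missingness is strictly below 10% (`max_missingness`, exclusive),
* at least one carrier call with read depth ≥ 7 (`min_depth`,
  inclusive — "minimum depth of 7" reads naturally as ≥ 7) meets the
  allele-balance threshold (`min_allele_balance`, inclusive; 0.15 for the
  discovery profile, 0.20 for the validation profile).

Carrier calls below the depth threshold are dropped before the
allele-balance check; a site whose carriers are all dropped fails.
Allele balance is alt-supporting reads over total reads at the call;
homozygous-alt calls auto-pass the rule, which the source procedure never
defines for them. The allele-balance wording is ambiguous between a
site-level rule (one qualifying carrier rescues the site, sub-threshold
carriers retained) and a call-level rule (sub-threshold heterozygous
calls are themselves removed); the site-level reading is the default and
`qc_thresholds(ab_rule = "call")` selects the other.

Rarity is enforced in two populations at once: the folded cohort minor
allele frequency (allele count over `2N`, folded at 0.5) and the
reference-panel frequency must both be strictly below 0.1%. A variant
absent from the reference panel is treated as frequency 0 — absence from
a large reference implies, at most, extreme rarity. Per-sample fields
missing from a VCF (no DP or AD) auto-pass their filters with a logged
warning rather than discarding the cohort.

## Score preparation

Orientation: predictors that assign *low* scores to damaging variants are
negated, so that "high = damaging" holds everywhere downstream.
A predictor participates in a gene's comparisons only when it scores at
least 10 of the gene's post-QC rare variants; an excluded predictor takes
no part in any comparison for combinations involving that gene, and its
best-or-tied denominator shrinks accordingly.

For binary traits, each predictor's scores over a gene are winsorized at
the 5th and 95th percentiles (linear-interpolation percentiles, the
`quantile` type-7 convention — the source names none) and mapped affinely
to [0, 1]. The normalization scope is per predictor per gene: the
procedure is defined inside the per-combination comparison, and per-gene
is the only scope under which the percentiles are well defined for every
comparison. A degenerate scale (floor equal to ceiling) maps every
variant to 0.5 with a warning inside the pipeline; the low-level
`winsorize_normalize()` raises a classed error by default so programmatic
callers can decide.

Participant-centric scores are additive: the sum over carried, scored
variants of dosage times normalized score. Homozygous carriage counts the
score twice, consistent with the additive model. The evaluation set of a
binary combination is the set of carriers of at least one post-QC rare
variant in the gene — chosen predictor-independently so that the paired
bootstrap can share resamples across predictors; a carrier whose variants
a given predictor did not score receives 0 for that predictor. Whether
non-carriers belong in the evaluation set is not determined by the source
procedure; carrier-only is the default and
`run_config(include_noncarriers = TRUE)` adds phenotyped non-carriers at
score 0.

Quantitative traits use raw oriented (un-winsorized) scores: Pearson
correlation is affine-invariant, so normalization could matter only
through clipping, and the rescaling step is described only for binary
traits. Trait values of participants sharing a variant are averaged per
carrier (dosage does not weight the average), and PCC² is computed across
the gene's variants.

## Performance measures

Balanced precision at a threshold is `TPR / (TPR + FPR)` — the precision
expected in an evaluation set with equally many positives and negatives.
The balanced precision-recall curve is built over all distinct
participant-score thresholds in descending order; tied scores move
together. The most lenient threshold predicts everyone positive, so
recall 1 is always achieved; the curve is anchored at recall 0 by
constant extension of the balanced precision at the most stringent
achieved threshold, and the area is the trapezoidal integral over recall.
This construction is exactly invariant under strictly increasing score
transforms, reproducible, and gives area 0.5 for constant scores. An
evaluation set with a single class yields an undefined metric (`NA`),
which the bootstrap layer consumes.

PCC² is squared per bootstrap iteration (the distribution is of squared
values, then summarized); whether the source squared per iteration or
squared the summarized mean is not stated, and per-iteration squaring is
the implemented reading.

## Bootstrap, ties, ranking

Each combination's evaluation set is resampled with replacement,
`iterations` times (default 10000; the recovery analyses below use 1000),
with the *same* resample indices applied to every included predictor —
per-iteration differences between predictors are therefore meaningful.
Iterations where any included predictor's metric is undefined (e.g. a
single-class resample) are dropped for the whole combination to preserve
pairing, the count is reported, and a combination losing more than half
its iterations is flagged unreliable rather than silently summarized.

The empirical p-value for an ordered pair (a better-on-average, b) is the
fraction of retained iterations with `a − b ≤ 0`; ties count, so a
predictor compared with itself gets p = 1 and
`p(a,b) + p(b,a) = 1 + tie fraction` exactly. Zero p-values are kept as
zeros — the counting formula admits them and the q-value machinery
handles them.

Storey q-values use the smoother pi0 estimate: `pi0(lambda) =
#{p > lambda} / (m (1 − lambda))` on `lambda = 0.05, …, 0.95`, a df-3
cubic smoothing spline evaluated at the largest lambda, clipped to
(0, 1]. Families smaller than 100 p-values fix pi0 at 1, where the
q-value reduces to the Benjamini–Hochberg step-up adjustment. All
per-combination pairwise p-values of a run are pooled into one q-value
family; the overall Wilcoxon matrix forms its own separate family.
Whether the source pooled one family or used per-combination families is
not stated; pooling is the default here because the p-value distribution
is described as one distribution with one q-value calculation.

Per combination, the top predictor is the one with the highest bootstrap
mean and the tied set is the top plus every predictor whose comparison
against the top has q ≥ 10% — membership is tested against the top only,
not pairwise within the set. Overall, predictors are ranked by the count
of combinations where they are best or tied. Equal counts are broken
first by the number of rivals a predictor significantly outperforms
(q < 10% with favorable direction) in the pairwise two-tailed Wilcoxon
signed-rank matrix over per-combination means (pairs use only
combinations where both participated; fewer than two shared combinations
makes a pair incomparable). Remaining ties are broken by head-to-head
comparison of q-value rows: for tied a and b, count rivals r with
`q(a,r) < q(b,r)` *among comparisons whose direction favors a*. The
directional gate matters: a q-value measures how clearly two predictors
differ, not which is better, so small q-values earned by being decisively
beaten must not count as merit. Residual full ties are reported as shared
ranks rather than broken arbitrarily. Cross-cohort agreement between two
final rankings is Kendall's tau-b on the shared predictor set.

The Wilcoxon signed-rank test drops zero differences, midranks ties, and
uses the exact null distribution (computed by convolution over doubled
midranks, so ties stay exact) up to 25 nonzero pairs, then a
tie-corrected normal approximation with continuity correction. Kendall's
tau-b uses exact permutation enumeration up to 8 items and the full
tie-corrected normal approximation above.

## The synthetic cohort simulator

The simulator generates the statistical structure the analysis assumes,
not a population-genetic model: no linkage disequilibrium, relatedness,
population structure, or covariates (all out of scope). Per variant, the
minor allele frequency is drawn log-uniformly from `maf_range` (default
2×10⁻⁴ to 9×10⁻⁴, keeping every variant rare by the < 0.1% rule);
genotype dosage is binomial with two trials at that frequency. True
effects are 0 for `null_fraction` (default 0.3) of variants, otherwise
exponential magnitudes with mean `effect_scale` (default 1 trait standard
deviation). Effect direction defaults to positive — gene–trait pairs
enter this kind of benchmark *because* a burden of damaging variants
shifts the trait consistently, so damaging-increases-trait is the
ascertained regime; per-gene random signs (`effect_sign = "gene"`) and
per-variant signs (`"variant"`) are available for robustness studies, but
per-variant signs make both metrics degenerate by construction (scores
track `|beta|` while traits track signed beta).

The quantitative trait is the dosage-weighted effect sum plus
`N(0, trait_noise_sd²)` noise; each binary trait thresholds an
independent liability of the same form with unit-variance noise at
`qnorm(1 − prevalence)` — the rare-variant genetic variance is negligible,
so realized prevalence concentrates at the target. The binary trait is an
independent liability rather than a thresholded copy of the quantitative
trait so the two trait kinds are not redundant in tests. Default
prevalence is 0.3, a common-trait figure (medication use, a prevalent
condition) consistent with traits that can pass a ≥ 10-affected-carriers
rule in modest cohorts.

Predictor scores are `|beta| + N(0, noise_sd²)`, negated for
low-is-damaging orientation, with a configurable fraction of variants
unscored; a spec can copy an earlier predictor's realized raw scores
(`copy_of`) to build exactly sign-flipped or down-sampled twins. With
zero missingness and increasing noise, the expected score-truth
correlation decreases strictly — the fidelity ordering the end-to-end
analysis is expected to recover.

Default cohort dimensions (2000 participants, 2 genes × 60 variants)
give each gene roughly 110 carriers, of whom about 1–2% carry multiple
variants in the gene — matching the sparsity regime the analysis assumes,
under which the additive model's behaviour is dominated by single-variant
carriers. Simulated QC fields (Poisson depth ~30, binomial allele
balance, site quality uniform on 30–60, missingness below 5%) mostly pass
the default filters; QC edge cases are exercised by dedicated toys rather
than by the cohort generator.

What passing tests on this simulator do *not* show: robustness to
linkage, relatedness, ancestry stratification, phenotype measurement
artifacts, or predictors whose errors correlate with allele frequency or
gene — all properties of real cohorts outside the generator's scope.

## Problem sizes and runtime choices

The test suite runs the full analysis at reduced but structurally
faithful sizes: the end-to-end recovery study uses 20 replicates of a
2000-participant cohort, 2 genes × 3 binary traits, five predictors
(noise 0.1 / 0.5 / 2.0, an exactly sign-flipped copy of the best, and a
60%-missing copy), at 1000 bootstrap iterations — sizes at which the
fidelity ordering is recoverable while a replicate completes in a couple
of seconds. The recovery cohort uses binary traits only because the
sign-flip condition is invisible to PCC² (squaring removes the sign, so a
flipped predictor exactly ties its parent on quantitative combinations);
AUBPRC, computed after orientation and normalization, is the metric that
exposes a wrong orientation flag. Production runs would use the 10000
iteration default and as many combinations as the cohort supports.

## Determinism

Every run draws from a single root seed; each combination derives its own
stream from `(seed, combo id)` by a fixed string hash, so results are
independent of evaluation order and identical configurations give
byte-identical result files. Result TSVs are written with fixed numeric
formatting; the JSON manifest records per-stage record counts and
wall-clock times (timings are run metadata, outside the determinism
contract).

## Known limitations

* Correlated gene–trait combinations (several traits of one gene share a
  score-noise realization) are counted as independent units in the
  best-or-tied tally, as in the source procedure; no gene- or
  trait-weighted ranking is attempted.
* The overall Wilcoxon matrix is granular at small combination counts
  (the minimal two-tailed exact p with n combinations is `2 / 2^n`), so
  overall significance needs a few dozen combinations to be informative.
* Coverage-excluded predictors make pairwise denominators uneven; the
  per-pair combination counts are reported rather than corrected for.
* The bootstrap resamples participants only; variant-level uncertainty
  (which variants happen to segregate in the cohort) is visible in the
  spread across genes, not within a combination.
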