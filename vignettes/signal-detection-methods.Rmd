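---
title: "Signal-detection analysis of truth judgments: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-detection analysis of truth judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truthsdt)
```

## The measurement model

A respondent judges each of a set of claims as *true* or *false*. Claims are
either actually true or actually false, and each carries a slant that is
either congruent or incongruent with the respondent's prior position
(congruence = the respondent's group matches the claim's slant). Four
outcomes result: hits (true claims judged true), false alarms (false claims
judged true), misses, and correct rejections. Acceptance of misinformation
is the false-alarm rate.

Under equal-variance Gaussian signal detection theory, per-participant
judgment behavior decomposes into three interpretable components:

* **Truth sensitivity** `d' = z(H) − z(FA)`: the ability to discriminate
  true from false claims.
* **Acceptance threshold** `c = −0.5 [z(H) + z(FA)]`: the general tendency
  to reject (high `c`) versus accept (low `c`) claims, regardless of
  veracity.
* **Myside bias** `m = c_incongruent − c_congruent`: the criterion gap
  between incongruent and congruent claims. Positive `m` means a lower
  threshold for accepting claims that agree with one's side.

`z(·)` is the probit (inverse standard-normal CDF). Hit and false-alarm
rates of exactly 0 or 1 are replaced by `1/(2n)` and `1 − 1/(2n)` before the
probit, with `n` the number of trials the rate was computed from — the
standard extreme-rate correction. `d'` and the overall `c` are computed from
all-items rates; the two congruence-specific criteria come from the
congruent and incongruent item subsets. For odd/even split-half scoring the
correction uses the split's own trial count, since that is the number of
trials actually behind the rate.

On the myside-bias sign: "difference between congruent and incongruent
criteria" read literally would give `c_cong − c_incong`, but the intended
interpretation — higher scores = lower threshold for accepting congruent
claims — forces `c_incong − c_cong`. The package implements the
interpretation-consistent sign throughout (generator, scoring, and
regressions agree).

## The generative model behind the synthetic cohort

The analysis pipeline is validated by parameter recovery, which requires a
generative model under which the scoring formulas are the exact estimators.
We use equal-variance Gaussian SDT in reverse: a participant with latent
sensitivity `d`, baseline criterion `c`, and myside shift `m` answers
"true" with probability `pnorm(d/2 − c*)` for true claims and
`pnorm(−d/2 − c*)` for false claims, where `c* = c − m/2` on congruent and
`c + m/2` on incongruent items. The symmetric `±m/2` split keeps the three
generative parameters orthogonal in meaning: the overall criterion equals
`c` and the incongruent−congruent gap equals `m` exactly.

Latent `(d, c, m)` are independent Gaussians. The default marginals —
`d ~ N(0.52, 0.49²)`, `c ~ N(0.38, 0.50²)`, `m ~ N(0.66, 0.70²)` — emulate
the published index means and SDs of a political-misinformation study of
274 partisans judging 80 headlines (20 per veracity × slant cell), and those
study dimensions (two balanced groups of 150, 20 items per cell, fixed
seeded presentation order) are the generator's defaults.

Each of the 15 individual-difference traits is generated as its
target-correlation combination of the three standardized SDT latents plus
independent uniqueness, so that `cor(trait, d)`, `cor(trait, c)`, and
`cor(trait, m)` hit their configured targets exactly in population, and
traits are conditionally independent given the SDT latents. This
construction is automatically positive semi-definite whenever each trait's
squared targets sum to at most 1, which is what `cohort_config()` validates.
The default targets are the published trait-by-index correlation screen of
the same study. Two caveats are deliberate:

* the published correlations involve *estimated* indices, so they are
  attenuated versions of latent correlations; using them as latent targets
  reproduces the published magnitudes only approximately, which is all the
  qualitative acceptance checks need;
* real trait-trait correlations have structure beyond what the three SDT
  latents induce (e.g., Big-5 inter-correlations); the generator does not
  model that, so passing tests say nothing about trait-covariance structure
  in real data.

Scale-item responses are emitted per trait with a configurable reliability
(defaults = the published Cronbach's alphas): Gaussian item noise sized so
the k-item mean attains the target reliability, then Likert rounding and
range clamping; 0/1 scales (cognitive reflection, narcissism) use Bernoulli
items; the likeminded-identification score uses paired rating vectors whose
item-wise difference tracks the latent. Rounding and clamping shave a little
reliability and compress extreme means — with `likert_items = FALSE` the
generator instead emits exact continuous trait scores, which the calibration
and power checks use to isolate screen behavior from discretization.

## Scoring the trait battery

Scales are scored per the cited instruments: reverse-keyed items recoded as
`min + max − r`, then the mean (most scales) or sum (the 7-item cognitive
reflection test and the 16-item narcissism inventory, both 0/1-coded);
identification with likeminded people is the mean item-wise difference
between "people who share my views" and "all humanity" ratings. Missing or
out-of-range responses are rejected, never imputed, because the analysis
operates on completers. The registry of scale specs ships as data and is
editable; the reverse-key sets are placeholders to be replaced with the
source instruments' keys when item-level fidelity matters.

Internal consistency is Cronbach's alpha. For the SDT indices, which have
no item-level scores, reliability is approximated by splitting each
veracity × congruence cell into `k` presentation-order parcels (default
`k = 4`, i.e. 5 items per cell per parcel at the default bank), scoring the
index within each parcel, and taking alpha across parcel scores. The method
behind the published index reliabilities is not stated; the parcel approach
is our stand-in and is labeled as such.

## Association analyses

Because the three indices are computed from the same responses as the
false-alarm outcome, regressions of acceptance on the indices use the
odd/even split-half design: predictors (`d'`, overall `c`, `m`) come from
one item half (by parity of the fixed presentation order), the corrected
congruence-specific false-alarm outcome from the other, in both directions.
This makes predictors and outcome mathematically independent — permuting
the outcome half's responses leaves the predictors untouched, which the
test suite checks literally. Under the generative model the expected sign
pattern is `(−, −, +)` for congruent and `(−, −, −)` for incongruent
false alarms: higher sensitivity and higher threshold always reduce false
alarms, while myside bias lowers the congruent criterion (`c − m/2`) and
raises the incongruent one (`c + m/2`).

The correlation screen crosses every trait with the overall false-alarm
rate and the three indices: Pearson correlations with t-based two-sided
p-values, first-order partial correlations controlling for a 0/1 group
dummy, and Holm step-down adjustment (Bonferroni available). Holm is
applied over the 3 × 15 index-by-trait family — the family the robustness
analyses correct — with the false-alarm column adjusted as its own 15-test
family. Calibration and power are assessed at the design's own scale
(N = 274, 20 items per cell): family-wise error of the Holm-adjusted screen
under a global-null generator, and detection of a configured
`cor(trait, d) = 0.3` at the unadjusted .05 level, which is the level of
the main (preregistered-style) screens; adjustment is the robustness
variant.

## The bifactor structural model

To ask whether trait–sensitivity associations are driven by a single
underlying disposition, the package fits a bifactor structural model: a
general reflective-open-mindedness factor (ROM) loading on all indicators,
orthogonal specific factors for cognitive reflection (CR), bullshit
receptivity (BS), conspiracy mentality (CM), and actively open-minded
thinking (AOT), and the odd- and even-half truth-sensitivity scores
regressed on all five factors. Because the factors are orthogonal with unit
variance, the structural paths enter the implied covariance exactly like
loadings, so the model reduces to one constrained pattern
`Sigma = Lambda Lambda' + Theta`, fitted by minimizing the normal-theory
discrepancy `F = log|Sigma| + tr(S Sigma⁻¹) − log|S| − p` with an analytic
gradient, log-parameterized residual variances (which precludes negative
estimates; near-zero ones are flagged as Heywood cases), 20 seeded random
starts, and a 1e−8 gradient-norm convergence tolerance. Standard errors are
`2/(n−1)` times the inverse Hessian at the solution; standardized estimates
divide by implied observed SDs (their SEs by the same factor, a first-order
approximation). Factor-sign indeterminacy is resolved by making each
factor's indicator-loading sum positive.

The exact published indicator sets live in unavailable supplemental
materials, so the default spec uses three presentation-order parcels per
construct — a configurable default, not a reproduction — and
`bifactor_spec()` accepts arbitrary bifactor structures, including `NA`
specific assignments (an all-`NA` map is a plain one-factor model, which
the tests exploit for a closed-form oracle).

## Numerical choices and known limitations

* **Aggregation bias of the overall indices.** When `m ≠ 0` the all-items
  hit/FA rates pool two criterion regimes, and the probit of a pooled rate
  is not the pooled probit: at `(d, c, m) = (1, 0.3, 0.6)` the overall `d'`
  estimator converges to ≈ 0.956, not 1.0. This is a property of the
  scoring procedure itself (sensitivity defined on all items), not a bug;
  the consistency checks bound it (±0.05 covers it) and congruence-specific
  round trips are exact to ten significant digits.
* **Extreme-rate correction** is applied per computed rate only at exactly
  0 or 1 (no log-linear alternative), and inside each split with the
  split's own trial count.
* **Degenerate inputs** fail loudly: probit outside (0,1), zero-variance
  reliability, collinear regression designs, non-PSD trait targets, and
  singular sample covariances are errors, not warnings.
* **Problem sizes in the checks** were chosen to make Monte-Carlo error
  small relative to the tolerances they guard: 100 replicate cohorts for
  the regression sign pattern, 200 each for screen calibration and power,
  60 participants × 5000 items/cell for estimator consistency, N = 5000
  for bifactor sample recovery. The whole suite runs in about a minute on
  one core.
* **What passing does not show.** The generator emulates the study design's
  statistical skeleton, not real headlines or respondents: no item
  difficulty heterogeneity, no trait-trait structure beyond the SDT
  latents, no content effects, no inattentive responding beyond a boolean
  flag. Recovery results validate the estimators and code, not substantive
  conclusions about any real population.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(
  mode = "simulate",
  cohort = cohort_config(n_per_group = 150, items_per_cell = 20, seed = 1),
  output_dir = "run1", seed = 1
)
res <- run_study(cfg)
res$exclusions          # staged exclusion counts
res$rates               # hit/FA/miss/CR means and SDs
res$regressions[["congruent.even_to_odd"]]
head(res$screen)        # trait x outcome correlations, raw/adjusted p
res$bifactor            # standardized bifactor solution
```

Every table lands in `output_dir` as a full-precision CSV plus a rounded
`*_display.csv`, with a `manifest.json` whose config hash and seed fully
determine all outputs.
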