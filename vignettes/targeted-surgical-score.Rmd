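---
title: "The targeted surgical score: model, validation statistics, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The targeted surgical score: model, validation statistics, and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssrisk)
```

## The score and what it measures

Mechanical complications after proximal femoral nailing of
intertrochanteric femur fractures — lag-screw cutout, screw migration,
implant failure — are strongly associated with modifiable surgical
factors: where the lag screw sits in the femoral head, how far its tip is
from the head apex, and how well the fracture is reduced. The targeted
surgical score (TSS) condenses six such criteria, all readable from
routine postoperative AP and lateral radiographs, into a 0–8 point total:

| Criterion | Points | Rule |
|---|---|---|
| Tip–apex distance (TAD) | 0–2 | `< 25` mm → 2; `[25, 30)` mm → 1; `>= 30` mm → 0 |
| Lag-screw quadrant | 0–2 | centre–centre or inferior–centre → 2; superior–anterior or superior–posterior → 0; others → 1 |
| AP alignment | 0–1 | collo-diaphyseal angle difference (fractured − intact) in `[0, 10)`° → 1 |
| Lateral alignment | 0–1 | lateral angulation `< 20`° → 1 |
| Medial cortical support (MCS) | 0–1 | neutral or positive → 1 |
| Anterior cortical support (ACS) | 0–1 | neutral or positive → 1 |

The TAD is magnification-corrected on each film by the ratio of the true
lag-screw diameter to its apparent diameter,
`TAD = x_ap · d_true/d_ap + x_lat · d_true/d_lat`, so it only depends on
ratios of image measurements and needs no pixel-spacing metadata. The
quadrant comes from dividing the femoral head into three equal parts
perpendicular to the neck axis on each plane (Cleveland–Bosworth
quadrants).

Totals map to clinical risk bands via the predicted complication
probability of the development cohort: 7–8 very low (< 5%), 5–6 low
(5–10%), 2–4 moderate (10–50%), 0–1 high (> 50%).

### Boundary conventions

The published band labels leave a few boundary points ambiguous; the
package resolves them once, as follows, and the tests pin them:

* TAD exactly 25 mm scores 1 and exactly 30 mm scores 0 (the classical
  thresholds are "risk decreased below 25", "risk increased at 30 and
  above").
* An AP difference of exactly 0° scores 1 (neutral is a stated target);
  exactly 10° scores 0 (strict `< 10`). Any varus difference scores 0 by
  default; `score_ap_alignment()` takes an optional `varus_tolerance`
  because whether a −1° difference was graded neutral by a human assessor
  is unknowable from the published material.
* Lateral angulation of exactly 20° scores 0 (strict `< 20`).
* In `assign_band()`, the normalised transverse position s ∈ [0, 1] maps
  to the outer bands on `s < 1/3` and `s > 2/3`; both boundary points go
  to the centre band, favouring the clinically modal category and keeping
  the partition exhaustive.
* `classify_cortical_support()` uses a ±1 mm neutrality band by default;
  the published grading was visual, so the category can always be
  supplied directly, as can the quadrant bands when landmark coordinates
  are unavailable.

## The complication model

`tss_fit()` fits the binary logistic model
`logit P(complication) = β0 + β1 · TSS` (or any other covariate set, e.g.
the six sub-scores for the multivariable analysis) by maximum likelihood
through iteratively reweighted least squares, with rank and separation
checks, Wald standard errors and confidence intervals, odds ratios by
exponentiation, and model/null log-likelihoods. Wald (symmetric) intervals
are used because that is what the development analysis reports.
Downstream diagnostics are deliberately plain:

* `roc_analysis()` builds the empirical ROC of the total score (lower
  score = higher risk; a positive call at threshold t is `score <= t`).
  The trapezoid AUC on this curve equals the tie-corrected Mann–Whitney
  concordance probability, which the tests verify against a brute-force
  pair count. Youden's J picks the operating cutoff; ties are broken
  towards the more sensitive (higher-score) cutoff so the result is
  deterministic on a 9-point score.
* `hosmer_lemeshow()` groups patients by predicted probability into
  deciles of risk; because a single-score model yields at most nine
  distinct probabilities, tied quantile breaks collapse and the grouping
  effectively becomes score levels, with `groups − 2` degrees of freedom.
* `fit_statistics()` reports McFadden's R² = 1 − ll/ll0 and the
  likelihood-ratio test.
* `vif()` uses the textbook definition 1/(1 − R²) from regressing each
  covariate on the others — the quantity quoted alongside the published
  multivariable fit — rather than a coefficient-covariance generalisation.
* `group_compare()`, `proportion_z_test()` and `spearman_correlation()`
  cover the published univariate comparisons (Mann–Whitney U with normal
  approximation and tie correction, Pearson chi-square, pooled two-sided
  two-proportion z, Spearman rank correlation with the asymptotic t
  approximation). All p-values are two-sided and unadjusted, matching the
  published analysis.

The published model reports only the slope (β1 = −0.597). The intercept
is recovered from the published probability anchor — the Youden threshold
0.248 attained at TSS 3 — as
`derive_model_intercept(0.248, 3, -0.597)` ≈ 0.682, and is flagged as
derived wherever it appears.

## The synthetic cohort generator

No patient-level data are deposited, so the generator reproduces the
development cohort's published statistical structure (n = 586, prevalence
48/586, and the per-group summary tables) rather than any real patients.
Three layers:

**Margins.** Each group's six sub-score distributions are pinned to the
published means/SDs: the two 3-level scores by `moment_match_trinary()`,
which solves the 2×2 linear moment system exactly on support {0, 1, 2};
the four binary scores by `bernoulli_margin()`, whose mean determines the
distribution (the implied SD √(p(1−p)) reproduces the published SDs to
rounding, which the tests check).

**Dependence.** The published tables give only marginal moments, and the
margins alone are demonstrably not enough: under independence the
complication group's total-score SD would be ≈ 1.52 against a published
2.22. The minimal structure that reproduces both the margins and the
total-score SDs is an equicorrelated Gaussian copula per group;
`calibrate_rho()` finds the correlation by bisection on large seeded
samples (10^5 draws per step, common random numbers, so the simulated SD
is monotone in ρ and the search is deterministic). With the default
margins the calibrated values are ρ ≈ 0.41 (complication) and ≈ 0.22
(non-complication). Positive correlation between surgical-quality
criteria is also clinically plausible: they share one surgeon and one
reduction.

**Back-fill.** Raw measurement columns are drawn from the group's
published summaries *conditioned on the generated sub-score*: TAD from
the group's normal truncated to the scored band, the CDA difference and
lateral angulation likewise (with two-sided complements handled as
truncated unions), the quadrant from the published frequency table
restricted to combinations with the scored point value (the four
published frequencies are used as-is; the remainder is spread uniformly
over the other five combinations), and cortical categories consistent
with their points (a sub-score of 1 splits 50/50 between neutral and
positive, since no finer split is published). Re-scoring the back-filled
measurements therefore reproduces the generated sub-scores exactly — a
round-trip the tests assert record by record.

Two generation modes: `distribution_matched` draws the outcome first at
the configured prevalence and then group-conditional sub-scores —
faithful to the published group tables and used for discrimination
checks; `model_based` draws the score mixture first and then the outcome
from the logistic model at the derived coefficients — used for parameter
recovery and calibration checks, where the generating truth must be the
model itself.

What the generator does *not* emulate: the joint distribution of the
non-modifiable covariates (they showed no group differences and carry no
signal), per-score-level complication counts (only graphical in the
source), within-patient measurement error, and any real-world departure
from the equicorrelation assumption. Passing tests therefore show that
the machinery recovers known structure, not that the score will
discriminate equally well in new clinical data.

One global seed drives generation: the config seed is set once and all
draws are vectorised, so identical config + seed gives byte-identical
cohorts (asserted in the tests). When ρ is left `NULL` it is calibrated
at generation time from seeds derived deterministically from the config
seed; passing a pre-calibrated ρ (as the test-suite helper does) skips
that cost.

## Numerical and design choices

* Degenerate inputs: zero-mass truncation bands fall back to the band
  edge; near-degenerate margins clamp their copula thresholds at ±qnorm
  of 10^-15; infeasible moment pairs and unreachable SD targets raise
  errors rather than silently clipping.
* Separation is declared when coefficients blow past |β| > 10 with the
  glm separation warning or an essentially zero deviance; rank deficiency
  is caught from the QR of the design matrix before fitting.
* Missing measurements leave the affected sub-scores `NA` and flag the
  row `incomplete`; nothing is imputed.
* Report serialisation rounds floats to 4 significant digits, giving
  deterministic, diffable output.

## Problem sizes used by the tests

The suite exercises moment fidelity and prevalence at n = 10^5 (one
cohort each), discrimination and cutoff stability over 100 cohorts of
n = 586, interval coverage and calibration over 100 replicates of
n = 5000, and the brute-force AUC oracle on cohorts up to n = 200 (where
the O(n²) pair count is cheap). The full suite runs in well under a
minute on one core.

## Worked example

```{r example}
margins <- tss_study_margins()
rho <- c(calibrate_rho(margins$complication, 2.22, seed = 101),
         calibrate_rho(margins$none, 1.56, seed = 202))
cohort <- simulate_cohort(tss_cohort_config(n = 586, rho = rho, seed = 1))
validation <- tss_validate(cohort)
validation
```

```{r calibration, fig.width = 6, fig.height = 4}
plot(validation)
```

## Limitations

The package validates the scoring system against its own published
summary statistics, not against independent patient data; the synthetic
cohorts inherit every simplification listed above. The score itself is
equally weighted by design — the published multivariable coefficients
differ by criterion, and a weighted refinement is explicitly left to
future work — so the package does not provide one.
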