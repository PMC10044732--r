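---
title: "Methods: comparing subjective and objective SES measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing subjective and objective SES measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sesagree)
```

This vignette documents the statistical procedures in `sesagree`, the
conventions chosen where the methodology leaves room, and what the
synthetic-cohort generator does and does not emulate.

## The two SES measures

**WAMI** is a composite objective index: improved **W**ater/sanitation,
**A**ssets, **M**aternal (or participant) education, and **I**ncome, each
scored 0–8 and summed to a 0–32 total.

*Water/sanitation* is deterministic: 4 points per improved service.

*Assets* uses principal component analysis on the correlation matrix of
15 binary ownership indicators. We interpret "the first component's
loading scores" as the per-participant component score: each indicator is
standardized (correlation-matrix PCA), weighted by its first-eigenvector
loading, and summed. A per-person quantity is required for scoring, and
the component-score reading is the standard asset-index construction in
this literature. The component's sign is fixed by requiring a
non-negative correlation between the score and the count of owned assets
(ties broken toward +1), so "more assets" can never lower the score.
Zero-variance indicators (near-universal items such as beds can be
constant in small samples) carry no correlation information and are
dropped with a warning rather than failing the fit. The score range
*observed in the fitting cohort* is stored in the model object, so a
frozen rubric scores new data identically; out-of-range component scores
on new data clamp to 0 or 8 with a warning.

*Education* takes the participant's own years of schooling from age 20
and the guardian's (equivalently, maternal) years below 20, even when own
years are recorded — respondents under 20 may not have finished school.
The 9 scoring intervals are laid over the range of these *effective*
years in the scorable cohort.

*Income* uses the participant's reported bracket (0–8) when present;
otherwise raw monthly USD income is assigned to brackets whose cutpoints
sit at the 12.5%-increment percentiles of a sample of precise incomes
(`build_income_brackets()`), or to the published cutpoints
($100/150/175/200/225/250/324/411, `study_income_brackets()`). A value
equal to a cutpoint falls in the *higher* bracket, matching the
"<\$100", "\$100–150" category labels. Incomes collected in Peruvian
soles convert at 1 sol = 0.25 USD on read.

All three interval-scored components share one convention
(`assign_interval_score()`): 9 equal-width intervals,
left-closed/right-open, the top interval closed, values outside the range
clamped with a warning. This makes scoring a total, reproducible function.

**The MacArthur ladder** is stored as an integer 1–10 (1 = bottom rung),
the conventional orientation of the instrument and the one consistent
with an observed median of 5.

Missing data are handled complete-case *per analysis*: each analysis
drops only the records missing its own inputs (`validate_cohort()`
reports the usable counts). No imputation is performed.

## Rescaling to common ordinal scales

Epidemiologic practice usually enters SES as a 3–5 category variable, and
the Bland–Altman comparison needs both scores on the same number of
categories, so both measures are mapped onto 10/5/4/3-category scales.
The default scheme places cutpoints at the i/k empirical quantiles of the
score's own distribution and then snaps each to the achievable score
boundary that best balances the category masses. The snapping rule
depends only on ranks, so quantile schemes are invariant under strictly
monotone transformations of the scores — categorizing and then comparing
cannot manufacture agreement. Explicit cutpoints
(`method = "user_cutpoints"`) let published conventional cutoffs be
replicated exactly; the pipeline log records the cutpoints actually used.
Category assignment is left-closed/right-open with the top category
closed.

## Agreement statistics

*Spearman's rho* is the Pearson correlation of mid-ranks (average ranks
for ties); it errors on constant input rather than returning `NA`.

*Fleiss–Cohen weighted kappa* uses quadratic disagreement weights
w(i,j) = (i − j)² over the *declared* category universe 1..k — not the
observed support — so empty categories are legal and the statistic is
invariant under common relabelings that preserve order and spacing. When
both ratings are constant and identical the chance-corrected denominator
is zero; 1 is returned by convention with a message. Landis–Koch labels
follow the conventional cutpoints (poor ≤ 0.20 < fair ≤ 0.40 < moderate
≤ 0.60 < substantial ≤ 0.80 < almost perfect), with boundaries belonging
to the lower label and the printed gaps (e.g. 0.40–0.41) assigned upward
so the map is total.

*Bland–Altman outliers*: with differences d = WAMI(10-pt) − ladder,
the default rule flags |d| strictly above the 95th empirical percentile
of |d| ("absolute" mode); a two-sided band (2.5th–97.5th percentiles of
signed d) is available by flag. The phrase "outside the 95th percentile"
admits both readings; absolute is the simpler one and both are offered.
Percentiles use linear interpolation between order statistics (R type 7).
On integer-valued differences the outlier count is sensitive to the
estimator, which is why it is fixed and logged. Under continuous
differences the flagged fraction converges to 5%; on integer differences
ties typically leave it between about 2% and 5%.

## Retest substitution

A seeded sample of Bland–Altman outliers and non-outlier controls (the
reference design used 14 and 22) has its initial ladder scores replaced
by retest scores; agreement and outlier counts are recomputed. The
outlier threshold is recomputed on the substituted cohort by default —
re-running the analysis as one would on the corrected data — with
`freeze_threshold = TRUE` to keep the original threshold instead. How the
original study picked which outliers to retest is not stated; we draw
uniformly at random under a seed. Controls are not analyzed separately.

## Outcome models

Asthma history is regressed on the k-category SES variable with age
(years, linear — no transformation is claimed for the reference analysis)
and a female indicator (female = 1). Fits use binomial IRLS (tolerance
1e-8 on the deviance scale, max 100 iterations) with Wald standard
errors; perfect separation is detected from diverging coefficients and
raised as an explicit error rather than reported as a fit.
"Linear-trend association" has no single formal definition in the source
methodology, so it is operationalized both ways and both are reported:
monotone non-decreasing OR point estimates across ordered categories, and
the Wald p-value of the numerically-coded per-category-step term.
Confidence intervals are Wald (symmetric on the log scale), consistent
with the published intervals; AIC is 2·(parameters) − 2·log-likelihood,
held as an exact identity. `compare_ses_models()` reports |ΔAIC| and the
maximum relative OR difference |OR₁ − OR₂|/OR₁ over non-reference
categories.

## The synthetic cohort generator

Real cohorts of this kind are not publicly deposited, so the generator
exists to make every stage exercisable and testable. One standard-normal
latent wealth trait Z per participant drives:

- **assets**: ownership j ~ Bernoulli(logit⁻¹(aⱼ + bⱼZ)) with unit
  loadings bⱼ; intercepts aⱼ are solved by root-finding on the
  logit-normal mean so marginal rates match the reference cohort (iron
  57%, bed 99%, ..., bank account 66%);
- **education**: 11 + 1.9·Z + N(0, 1.3) years, half-year resolution,
  clamped to 0–18 (median 11);
- **income**: exp(5.516 + 0.29·Z + N(0, 0.292)) USD/month, giving bracket
  shares of roughly 40/34/25% below \$224 / \$224–324 / above \$324;
- **ladder**: round(5.3 + 1.3·Z + N(0, 1.875)) clamped to 1–10
  (median 5).

Water and sanitation are independent Bernoulli(0.98) — in the reference
population these services are near-universal and nearly uncorrelated with
wealth. Age is log-normal (median 30, clamped to ≥ 14, the study's
enrollment floor) and the female share is 36.2%, the printed figure.
Asthma follows a logistic model on the *true* wealth tercile with ORs
(1, 1.4, 2.0), a small negative age effect and a positive female effect,
intercept −3.0 (marginal prevalence ≈ 7%).

Two subjective-reporting error channels, both described qualitatively in
the source setting, are on by default: **scale reversal** (the report
becomes 11 − ladder; probability 0.05) and **heaping** on the focal value
5 (probability 0.10). The reversal rate matches the level exercised by
the retest analysis; the heaping rate is our choice of a realistic
focal-value rate — neither is reported numerically anywhere, and they are
deliberately not refit to any test outcome. A third, optional channel —
frame-of-reference bias, implemented as shrinkage of the ladder's wealth
signal toward the middle rung proportional to |Z|
(`ladder_params$frame_bias`) — is off by default: it is kept separate
from reversal and heaping because it produces a *trend* in the
Bland–Altman differences (wealthier participants under-rate, poorer ones
over-rate) rather than isolated outliers. Retest scores are drawn for everyone with
fresh noise on the same Z and, by default, without the error channels
(`retest_error_free`), which encodes the working hypothesis that
discrepancies corrected months later were measurement error.

The ladder noise SD (1.875) is the one calibrated constant: it was tuned
once, by a 10⁶-draw Monte-Carlo evaluation of the generator's population
Spearman correlation between WAMI total and ladder, to hit ρ ≈ 0.40 with
the default error channels active, and then frozen. Each random channel
draws from its own sub-stream derived from the master seed, so toggling
one channel never perturbs another's draws.

**What the generator does not emulate.** A single latent factor cannot
reproduce multi-dimensional wealth structure (e.g. urban/rural asset
profiles); the asset items are conditionally independent given Z, so the
first principal component explains ~17% of indicator variance — a
one-factor lower bound, below values reported for real asset batteries
(~24%) where items cluster. Household structure, interviewer effects,
panel attrition and genuinely systematic frame-of-reference bias are out
of scope. One measured consequence: coarse 3/4-category rescaling
attenuates the synthetic cohort's Spearman correlation by ~0.05, slightly
more than the ≤0.04 spread reported for the real cohort. Passing tests
therefore demonstrate that the *pipeline* is correct and calibrated under
a known truth, not that any real cohort's numbers will recur.

## Problem sizes and tolerances in the test suite

The test suite verifies: kappa against an independent cell-loop oracle to
1e−12 (200 random tables); the logistic MLE against a Newton–Raphson
oracle to 1e−6 (20 datasets); null calibration of rho and kappa at
n = 20,000 (|·| < 0.02) and mean kappa over 1,000 null replicates of
n = 500 (±0.01); Bland–Altman flagging at n = 10⁵ (5.0% ± 0.5%); recovery
of the calibrated ρ ≈ 0.40 at n = 5,000 (±0.05 per seed, mean bias < 0.02
over 20 seeds); the retest direction (kappa up *and* outliers down) in
≥ 90% of 50 replicates at n = 595; Wald CI coverage of true ORs
(1, 1.4, 2.0) in ≥ 90/100 replicates at n = 5,000; and generator
marginals at n = 50,000 (±1.5 points per asset, ±1 point on the female
share, ladder median exactly 5). These sizes were chosen to hold
Monte-Carlo noise an order of magnitude below each tolerance while
keeping the default test run fast.

## Known limitations

- The PCA asset model assumes the Pearson correlation matrix of binary
  indicators; no tetrachoric/polychoric variant is provided.
- Quantile rescaling is a stand-in for any published "conventional
  cutoffs"; exact replication requires supplying those cutpoints.
- No confidence intervals accompany rho or kappa, and no test–retest
  reliability coefficient (ICC) is computed — the comparison framework
  this package implements reports none.
- Whether the original asset-variance figure was computed before or after
  dropping constant indicators is unknowable from the description; we
  compute it after.
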