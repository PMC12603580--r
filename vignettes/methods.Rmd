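---
title: "Methods: spline GEE models for pregnancy wearable trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spline GEE models for pregnancy wearable trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravida)
```

This vignette documents the statistical model implemented in `gravida`, the
numerical choices made in the from-scratch estimating-equation engine, the
design of the synthetic cohort generator, and the reasoning behind the
package's default parameters and conventions.

## 1. The data model

Each participant $i$ contributes daily records of up to eleven wearable
metrics (sleep duration and staging, nightly wake, distal skin temperature
deviation, resting heart rate, heart-rate variability, respiratory rate,
daily steps). Records are aligned to the inferred pregnancy start: day 0 is
the first day of gestation, negative days are prepregnancy, and the analysis
window runs from day $-56$ (8 weeks before conception-dating origin) to day
$391$ (16 weeks postpartum after a 40-week term).

**Pregnancy start.** When an expected due date is available the start is the
due date minus 280 days (the standard 40-week convention); otherwise the
reported last-menstrual-period date is used directly. Due-date dating takes
precedence because it typically reflects clinical (ultrasound-adjusted)
dating. `summarize_start_sources()` reports the share of each source.

**Trimesters.** Days 0–97 are T1, 98–195 are T2, and day 196 onward is T3.
These breaks are the conventional 14- and 28-week boundaries expressed in
days; the classifier is closed on the left so day 97 is still T1 and day 98
begins T2.

**Baselines and z-scores.** Each metric is individually normalized: the
baseline is the mean and SD of that participant's records over days
$-28\ldots-1$ (at least 7 observed days, SD floored at $10^{-6}$), and all
subsequent values are expressed as $(x - \mu_i)/\sigma_i$. This removes
stable between-person differences so the model targets the common
within-person trajectory. Native-unit effect sizes are recovered by
multiplying fitted z-values by the cohort-median baseline SD.

**Availability filter.** Participants must have data on at least 40% of days
in each trimester window they reached. Denominators are truncated at the
pregnancy end: a pregnancy ending on day 70 has a T1 denominator of 71 days,
and T2/T3 are simply not evaluated. This keeps early losses in the loss
analysis without demanding data from windows that never occurred.

**Weekly bins.** Gestational week $w$ covers days $7w \ldots 7w+6$; a weekly
value is the mean of available daily values in the bin. A bin labelled $w$
therefore represents mean gestational age $\approx w + 0.43$ weeks, which is
why landmark extrema are read off the fitted curve at integer weeks rather
than interpolated between bins.

## 2. The estimating-equation engine

### 2.1 Gaussian GEE with exchangeable working correlation

For participant $i$ with $n_i$ weekly observations, the model is
$y_{ij} = x_{ij}^\top \beta + \epsilon_{ij}$ with working covariance
$\phi V_i$, $V_i = (1-\alpha) I_{n_i} + \alpha \mathbf{1}\mathbf{1}^\top$.
The estimating equation $\sum_i X_i^\top V_i^{-1} (y_i - X_i\beta) = 0$ is
solved by iterating

1. $\beta \leftarrow (\sum_i X_i^\top V_i^{-1} X_i)^{-1}
   \sum_i X_i^\top V_i^{-1} y_i$,
2. moment updates
   $\hat\phi = \sum e_{ij}^2 / (N - p)$ and
   $\hat\alpha = \sum_i \sum_{j<k} e_{ij} e_{ik} \big/
   \hat\phi\,(\sum_i n_i(n_i-1)/2 - p)$,

until the relative change in $\beta$ falls below `tol` (default $10^{-10}$,
`maxit = 100`). $\beta$ starts at OLS and $\alpha$ is **seeded from the OLS
residual moments before the first weighted solve**; starting at $\alpha = 0$
would make the first iteration reproduce OLS exactly and terminate
spuriously. $\hat\alpha$ is clamped to the positive-definite range
$(-1/(\max_i n_i - 1),\, 1)$.

The exchangeable structure admits a closed-form inverse,
$$V_i^{-1} = \frac{1}{1-\alpha}\Big(I - \frac{\alpha}{1 + (n_i - 1)\alpha}
\mathbf{1}\mathbf{1}^\top\Big),$$
so $X_i^\top V_i^{-1} X_i$ reduces to per-observation products plus
cluster-sum outer products. The implementation computes all cluster sums at
once with `rowsum()`; no per-cluster loops or explicit $n_i \times n_i$
matrices are formed, and fits with thousands of clusters take milliseconds.

### 2.2 Covariances and tests

Two covariance estimates are kept: the model-based
$\hat\phi B^{-1}$ with $B = \sum_i X_i^\top V_i^{-1} X_i$, and the sandwich
$$\widehat{\mathrm{cov}}(\hat\beta) = B^{-1}
\Big(\sum_i X_i^\top V_i^{-1} e_i e_i^\top V_i^{-1} X_i\Big) B^{-1},$$
which is consistent even when the exchangeable working correlation is wrong.
All reported inference uses the sandwich. `joint_wald()` tests a coefficient
block $C\beta = 0$ via $\hat\beta_S^\top \Sigma_{SS}^{-1} \hat\beta_S \sim
\chi^2_{|S|}$, selecting $S$ by formula term label, coefficient name, or
index, and refusing singular sub-covariances rather than pseudo-inverting.

Correctness is pinned by tests: singleton clusters reproduce OLS to
$10^{-8}$; a fixed $\alpha$ reproduces explicit blockwise GLS; $\hat\alpha$
recovers the intraclass correlation of a random-intercept truth; Wald
p-values are uniform under the null (type-I error in $[0.03, 0.08]$ at
nominal 0.05); and an end-to-end cross-check against Python `statsmodels`
GEE (Gaussian, exchangeable) matches coefficients, robust SEs, $\hat\alpha$
and $\hat\phi$ to $10^{-4}$ relative.

### 2.3 B-splines

`bs_basis()` implements clamped (open uniform) B-splines by the Cox–de Boor
recursion. For `df` basis functions of degree $d$, `df` $- d$ interior knots
are placed at quantiles of the unique covariate values, with boundary knots
at the range and each boundary repeated $d + 1$ times. Evaluation clamps
query points to the boundary, and the recursion treats $0/0$ as $0$. The
basis satisfies partition of unity to $10^{-12}$ on dense grids, and with
shared knots matches `splines::bs` exactly; by default the first column is
dropped so the basis is identified alongside an intercept. The basis carries
its knots as attributes and registers `makepredictcall()`, so
`predict(fit, newdata)` re-evaluates the *training* basis at new points.
`tensor_product()` forms column-wise products of two bases for smoothly
varying covariate effects.

## 3. Analysis 1: gestational-age trajectories

`fit_ga_model()` regresses weekly z-scores on an 8-df cubic B-spline of
gestational week (plus intercept), clustered by participant. The fit
reports: the joint Wald test of the whole spline block; the fitted curve
with robust standard errors on a 0.25-week grid (plus native-unit columns
when a baseline SD is supplied); the extremum of the fitted curve over
integer gestational weeks 0–40; and trimester deltas (mean fitted z per
trimester minus the week-0 fit).

**Spline domain (default weeks 0–56).** The default drops prepregnancy
weeks before fitting. After baseline z-scoring, prepregnancy weeks are
mean-zero by construction and carry no trajectory information, but they
consume spline flexibility: with quantile knots, 8 weeks of flat
prepregnancy data pushes interior knots leftward and visibly attenuates the
sharp first-trimester features. The `week_range` argument restores the full
$-8\ldots56$ window when the prepregnancy segment is itself of interest (a
test verifies both settings fit cleanly).

`fit_covariate_model()` extends the design with 4-df splines in maternal age
and/or BMI and tensor-product interactions with the time spline, each an
addressable Wald block, to ask whether trajectory shape varies with the
covariate.

## 4. Analysis 2: pre-loss divergence

For each pregnancy ending in early loss, `extract_window()` takes the final
28 days of daily z-scores ($d = -27\ldots0$ relative to the end). Ends
before gestational day 28 are excluded (no full within-pregnancy window
exists). Each case is matched to a term control observed over the same
gestational days (`sample_controls()`: seeded, without reuse while the pool
lasts, then with replacement; it errors if no control has any coverage).

`fit_loss_model()` then fits, by GEE over the matched daily series,
$$z \sim \text{B-spline}_3(d) + \text{outcome} + \text{outcome} \times d,$$
i.e. a common 3-df day curve plus a loss-group level shift and a loss-group
linear trend in day. The outcome main effect and interaction form a 2-df
joint Wald test of divergence. Effect sizes are mean (term $-$ loss) fitted
differences over the full 28 days and the final 7 days. The **onset** is the
earliest day of the longest suffix over which the fitted loss$-$term
difference stays below $-q$ ($q = 0.25$ z by default) through day 0; a dip
not sustained to the end returns `NA`. Because cases and controls are
matched on gestational day, the common day curve cancels from the contrast —
a test verifies deltas and onset are invariant to adding an arbitrary shared
curve.

**Why a linear outcome contrast?** With 28 points per subject and modest
pair counts, a flexible interaction basis inflates the Wald degrees of
freedom and destabilizes the sandwich covariance. The level + trend contrast
is the minimal parameterization that distinguishes "shifted all along" from
"diverging at the end"; its least-squares projection of a 14-day unit hinge
crosses the $-0.25$ z threshold within a day of the true onset (verified
analytically and by simulation in the tests).

## 5. The synthetic cohort generator

`generate_cohort()` simulates per-day records as
$$x_{ijt} = \mu_{im} + b_{im} + \sigma_{B,m} f_m(t/7) + \epsilon_{ijt},$$
with participant baseline $\mu_{im}$ (population means: 7.2 h asleep, 0.8 h
awake, 20% deep, 25% REM, 36.5 °C reference temperature, 63 bpm HR, 45 ms
HRV, 14 rpm respiratory rate, 9000 steps), random intercept $b_{im}$,
residual noise $\epsilon$, and a template $f_m$ giving the trajectory in
baseline-SD units (temperature and HR templates are in native units;
$\sigma_B$ rescaling applies to the z-scale templates). Time in bed is
derived as asleep + awake and light sleep closes the stage percentages, so
accounting identities hold exactly in every record.

**Template anchors.** Templates are piecewise-linear in gestational week
through landmark anchors: temperature $+0.3$ °C at week 9 falling to
$-0.1$ °C by week 30; HR $+2/ +6.5/ +10$ bpm at weeks 13/27/32 with a
prelabor decline; HRV the mirrored dip to $-16.5$ ms at week 32; steps a
$-2000$ trough at week 8, recovery, then a decline to $-3200$ at week 40;
time in bed $+0.5$ h at week 9 then a decline to $-0.95$ h at 40; nightly
wake rising to $+1.5$ z by week 42. Anchor lists are densified through a
monotone Hermite interpolant at half-week spacing before use: an 8-df cubic
spline cannot represent a sharp piecewise-linear tent, and projecting the
raw tent attenuates peak heights by 20–35%. Densification makes the template
a smooth curve *through the same anchors* so the analysis model can resolve
what the generator encodes. Peak/trough anchor values are untouched.

**Outcomes and timing.** Outcome proportions, gestational end windows (loss
days 28–139, preterm 196–258, term 259–294), the 49.3% due-date-known
fraction, 20% missing-day rate, 2% nap rate, and 16 postpartum weeks are
generator *study conditions*; the variance components (random-intercept and
residual SDs per metric) are free parameters chosen to give realistic
intraclass correlations ($\approx 0.3$–$0.6$) and were fixed at design time.

**Pre-loss divergence.** In loss pregnancies each sleep metric's deviation
ramps linearly over the final 14 days toward a metric-specific end
deviation (time in bed: $-0.85$ h, i.e. shortening sleep), replacing the
template value during the ramp. The $-0.85$ h magnitude is an analytic
design choice: for the linear outcome contrast of Section 4, a unit hinge
of depth $D$ z yields a fitted crossing of the $-0.25$ z onset threshold at
day $\approx -14$ when $D \approx 1$, which $0.85\,\mathrm{h} /
\sigma_B$ delivers at the default variance components.

**Scope.** The generator is a structural emulator, not a physiological
model: noise is Gaussian and homoscedastic, missingness is completely at
random, naps are rare duplicates, and covariate effects on trajectory shape
are limited to optional age/BMI modifiers (active from week 0 onward, since
prepregnancy deviations are zero by construction). It exists to exercise the
estimators under a known truth.

## 6. Reproducibility conventions

Every stochastic entry point takes a `seed`; `substream_seeds()` derives
independent substreams so stages can be re-run in isolation.
`run_pipeline()` writes a manifest with MD5 hashes of all outputs, and
`scripts/acceptance.R` recomputes the landmark recovery targets from scratch
for any seed. The test suite (testthat, edition 3) contains no conditional
skips; the `statsmodels` cross-check invokes `python` directly and fails —
rather than skips — if the interpreter is unavailable, making the
environment requirement explicit.
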