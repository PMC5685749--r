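---
title: "Two-stage validation of disease-free survival as a surrogate for overall survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage validation of disease-free survival as a surrogate for overall survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfsurro)
```

## The problem

Overall survival (OS) is the gold-standard endpoint for trials of adjuvant
therapy after curative treatment of hepatocellular carcinoma, but it needs
large samples and long follow-up. Disease-free survival (DFS) — time from
randomization to the first of loco-regional recurrence, distant recurrence,
or death — is observed much earlier. `dfsurro` implements the standard
two-stage meta-analytic framework for asking whether DFS can stand in for
OS:

* **Individual level.** How strongly are a patient's DFS and OS times
  associated? Measured by a rank correlation $\rho$ derived from a copula
  model for the bivariate censored pair.
* **Trial level.** How well does a trial's treatment effect on DFS (log
  hazard ratio $\beta_{DFS}$) predict its effect on OS ($\beta_{OS}$)?
  Measured by the correlation $R$ of a weighted linear regression
  $\beta_{OS} = a + b\,\beta_{DFS} + \varepsilon$ across trials, together
  with the surrogate threshold effect (STE) and leave-one-out
  cross-validated prediction intervals.

Because the per-trial hazard ratios behind any particular published
meta-analysis live in external trial reports, the package is built around a
synthetic-data generator with known ground truth: every stage of the
pipeline can be checked against the truth that generated its input.

## What the generator emulates

`meta_truth()` fixes the study conditions; `simulate_meta_analysis()`
produces trial rosters and individual patient records.

* **Trial-level structure.** True per-trial effect pairs
  $(\beta_{DFS}, \beta_{OS})$ are bivariate normal with means $(-0.5,
  -0.35)$, standard deviations $(0.40, 0.30)$ and correlation $0.85$ by
  default: moderately protective adjuvant effects with strong but imperfect
  trial-level surrogacy, the regime in which a surrogate is worth
  validating and the grading question is non-trivial.
* **Patient-level structure.** Each patient has latent recurrence and death
  times with exponential margins (control-arm hazards $0.030$ and $0.015$
  per month, i.e. median time to recurrence around 23 months and median OS
  around 46 months after curative treatment) and Clayton dependence
  $\theta = 6$ (Kendall $\tau = \theta/(\theta+2) = 0.75$). Proportional
  hazards apply the trial's true effects to the two latent hazards. DFS is
  the minimum of recurrence and death, OS is death, so $OS \ge DFS$ holds
  by construction rather than by rejection sampling.
* **Censoring.** One follow-up clock per patient: a single uniform
  censoring time on 12–120 months truncates both endpoints, matching how
  administrative censoring operates in trials whose reported follow-up
  spans roughly 0–160 months.
* **Arm sizes.** Uniform on 30–150 per arm, the range seen in the packaged
  trial rosters.
* **Reproducibility.** One integer seed governs everything; each trial uses
  a substream derived deterministically from (seed, trial index), so
  adding a trial does not perturb the others.

The Clayton family was chosen for its closed-form Kendall identity and
trivial simulation; the family is recorded in the configuration and the
fitting code is written so alternatives could be added behind the same
interface. What the generator does **not** emulate: staggered accrual,
non-proportional hazards, informative censoring, and reporting artifacts
such as digitization error in curve coordinates. Passing tests therefore
demonstrate correctness of the estimators under clean proportional-hazards
data, not robustness to those real-data complications.

## Reconstructing treatment effects from published reports

Published trials rarely hand over $\beta$ and its variance directly, so
three routes are provided, each normalized to the convention *experimental
vs control, HR < 1 favours experimental*, with the route kept in a
provenance column:

1. **Direct CI** (`loghr_from_hr_ci`): $\beta = \log HR$, variance from the
   CI width on the log scale. The 97.5% normal quantile is taken as
   1.959964 rather than 1.96 throughout, so CI inversion round-trips to
   printed precision.
2. **P-value and event counts** (`loghr_from_pvalue`): the log-rank
   variance is approximated by $V = d\,n_1 n_2/(n_1+n_2)^2$, the
   observed-minus-expected statistic recovered from the normal quantile of
   the two-sided p-value, and $\beta = (O-E)/V$ signed by the reported
   direction. A p-value of exactly 1 yields the null effect; 0 is
   unextractable and rejected.
3. **Digitized curves** (`loghr_from_km`): for each grid interval, events
   per arm are back-calculated from the survival drop and the effective
   number at risk; per-interval log-rank contributions (hypergeometric
   expectation and variance) are pooled into $\beta = \sum(O-E)/\sum V$,
   $\mathrm{var} = 1/\sum V$. When the report prints no at-risk table, the
   effective risk set is the enrolled count scaled by survival and by a
   censoring fraction that grows linearly over the follow-up window — the
   constant-censoring assumption standard for this reconstruction.
   Zero-event intervals contribute nothing (no continuity correction);
   intervals where both arms have an empty risk set are dropped with a
   warning.

All three routes are antisymmetric under arm exchange, and the curve route
is validated against Cox partial-likelihood fits on the underlying records:
with at-risk tables and a 2-month grid, the mean absolute deviation from
the Cox estimate across 200 simulated trials of 150 patients per arm is
well under 0.08 on the log-HR scale, and the reconstructed variance stays
within a factor of two of the Cox variance.

## Individual-level association

`fit_copula()` uses two-stage pseudo-likelihood: product-limit margins are
estimated *per treatment arm* (treatment shifts the margins, not the
dependence) and plugged into the Clayton censored-data likelihood, which
has four contribution types by the censoring pattern of the pair — the
copula density when both endpoints are events, a partial derivative when
exactly one is, and the joint survival function when neither is. The
dependence parameter is maximized over $(0, 50]$; estimates at the
boundary raise a warning and are flagged in the diagnostics. Pseudo
survival probabilities are clamped to $[10^{-6}, 1-10^{-6}]$ and the
likelihood is evaluated in logs with a log-sum-exp form, so extreme
dependence and deep tails do not overflow.

Conversions to the reported scales use the Kendall identity
$\tau = \theta/(\theta+2)$ and Spearman's
$\rho = 12\int\!\!\int C_\theta(u,v)\,du\,dv - 3$ by numerical quadrature
(relative tolerance $10^{-10}$, checked against a frozen Monte-Carlo rank
correlation of $10^6$ copula draws). The 95% CI for $\rho$ is a percentile
bootstrap over patients (at least 200 resamples, seeded); percentile rather
than BCa because at the sample sizes involved the added complexity buys
nothing visible.

One modelling caveat is intrinsic to the endpoints: since DFS is the time
to the *first* event, a death without prior recurrence makes DFS equal OS
exactly, so the observed pair carries probability mass on the diagonal and
is more dependent than the latent recurrence–death pair. The package fits
the copula to the observed pair as the analysis defines it and reports the
count of such boundary ties in the diagnostics (`n_tied`) instead of
fitting a semi-competing-risks likelihood; parameter-recovery checks
therefore generate data from the bivariate model itself. Rank-based
margins make the estimate invariant under strictly monotone time
transformations, and duplication of the data set leaves it unchanged.

## Trial-level regression, STE and validation

`fit_trial_regression()` runs weighted least squares of $\beta_{OS}$ on
$\beta_{DFS}$ with weights proportional to total patients per trial
(inverse-variance and equal weights are available), normalized to mean 1 so
the residual scale is interpretable for an average-sized trial. $R$ is the
weighted Pearson correlation; its default CI is the Fisher-z interval with
effective $n$ equal to the number of trials. With seven to ten trials that
interval is honest but wide, and published CIs for such $R$ values are
generally not reproducible from the trial count alone; a
bootstrap-over-trials CI (`bootstrap_r_ci`) is provided as the alternative.
The regression is deliberately unadjusted for measurement error in the
per-trial estimates — matching common practice for this analysis — which
attenuates the slope when surrogate effects are noisy; the package leaves
the attenuation visible rather than correcting it.

Prediction for a new trial uses the estimation-error-adjusted interval:
residual variance scaled by the new trial's relative size plus the
covariance of the fitted line at the new point, with a $t_{J-2}$ quantile.
The **surrogate threshold effect** is the pair of HR values where those
limits cross no-effect: the upper limit's largest negative root on the
log-HR axis (beneficial side, HR $\le 1$) and the lower limit's smallest
positive root (harmful side, HR $\ge 1$). The upper limit is a convex
function (linear plus a square root of a positive quadratic) and the lower
limit concave, so each side has at most two roots and the one nearest zero
is found by bracketing between the limit's extremum and zero
(`uniroot`, tolerance $10^{-9}$, search bracket $\pm 5$ — far beyond any
plausible trial effect). Degenerate zero-variance fits collapse both
thresholds to HR = 1. Thresholds are reported at full precision and
rounded to two decimals.

`loocv()` refits the regression once per held-out trial and asks whether
the observed OS effect lands in the held-out 95% prediction interval,
evaluated at the held-out trial's own size. Intervals are closed, with a
$10^{-9}$ relative epsilon so exactly-degenerate fits are handled, and
boundary hits are logged. Calibration was checked over 200 synthetic
meta-analyses of 10 trials at 150 patients per arm with trial-level
correlation 0.85 — the generator's default strong-surrogacy regime — where
the mean empirical coverage of the nominal 95% intervals sits near 0.95.

## Problem sizes and numerical choices at a glance

* Monte-Carlo suite sizes: 200 trials for the extraction oracle, 100
  replicates per $\theta \in \{1, 2, 6\}$ at $n = 2000$ for copula
  recovery, 200 meta-analyses for LOOCV calibration, 500 draws for
  regression calibration; chosen to pin each statistic well inside its
  tolerance while keeping the suite quick on a laptop.
* Normal quantile 1.959964; copula search interval $(0, 50]$;
  pseudo-observation clamp $10^{-6}$; quadrature relative tolerance
  $10^{-10}$; root tolerance $10^{-9}$; per-trial substream seeds derived
  as a fixed linear congruence of (seed, index) below $2^{31}$.
* Ties and degenerate inputs: zero-variance predictors and sub-minimum
  trial counts are hard errors; non-concordant (negative-slope) fits yield
  undefined STE with a warning rather than a misleading number.

## Limitations

* No semi-competing-risks or illness–death likelihood for the individual
  level; the diagonal mass is diagnosed, not modelled.
* No bivariate random-effects meta-analytic model of both endpoint effects;
  the trial level is plain weighted regression by design.
* The Fisher-z CI for $R$ assumes bivariate normality of the effect pairs
  and ignores their estimation error; treat it as indicative with few
  trials.
* Curve-based extraction inherits the constant-censoring assumption when
  at-risk tables are missing; heavily non-uniform censoring will bias the
  effective risk sets.
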