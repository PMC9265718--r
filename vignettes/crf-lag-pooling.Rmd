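---
title: "Pooled concentration-response functions over exposure lags"
author: "crflag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled concentration-response functions over exposure lags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crflag)
```

## The problem

Short-term air-pollution epidemiology relates daily event counts (here:
respiratory emergency-department-style visits) to daily pollutant
concentrations (here: ozone 8-h daily maximum, in ppb), usually lag by
lag: the count on day $t$ against the concentration on day $t-L$ for
$L = 0, 1, \dots, 9$. Two chronic difficulties motivate this package.
First, each lag produces its own exposure–response curve and the
literature typically reports only the "best" lag; a defensible single
summary over lags is rarely produced. Second, the two standard curve
forms both fail at the low end: the log-linear form
$RR(Z) = e^{\beta Z}$ cannot express a threshold, and spline-based
curves often bend downwards at high concentrations where data are
sparse, producing the implausible message that more pollution lowers
risk.

`crflag` implements a parametric alternative: a sigmoid-weighted
transformation of the exposure inside an otherwise standard
case-crossover analysis, followed by least-squares pooling of the
per-lag curves into one monotone parametric curve with boundary curves
and a detectable threshold.

## Design and estimation

**Time-stratified case-crossover.** Each day belongs to the stratum
`year:month:day-of-week` (`build_strata()`); every stratum in a complete
month has 4 or 5 days, an invariant the tests check exhaustively over
1990–2005. Conditioning on the stratum totals removes everything that
varies between months or slower (season, trend, population), leaving
within-month weekday-matched contrasts.

**Conditional Poisson regression.** With counts $y_i$, covariates
$x_i$ and strata $s$, the conditional log-likelihood is
$$\ell(\beta) = \sum_s \Big[ \sum_{i \in s} y_i x_i^\top \beta
  - Y_s \log \sum_{i \in s} e^{x_i^\top \beta} \Big],$$
the multinomial likelihood obtained from a Poisson model after
conditioning each stratum on its total $Y_s$. `fit_conditional_poisson()`
maximises it by Newton–Raphson with the analytic gradient and Hessian,
step-halving, tolerance $|\Delta\ell| < 10^{-10}$, at most 100
iterations, and a BFGS fallback if the Hessian becomes numerically
singular. Standard errors come from the observed information. The
estimates are identical to a Poisson GLM with one intercept dummy per
stratum — the package's test suite verifies agreement with `glm()` to
$10^{-6}$ on the coefficients across randomised instances — but the cost
scales with the number of regression coefficients (7: the transformed
exposure plus two 3-df spline blocks), not the number of strata (~420 in
a decade of data). Covariate columns constant within every stratum are
non-identifiable and are dropped with a warning. An overdispersion
option scales the standard errors by $\sqrt{\hat\phi}$, with $\hat\phi$
the Pearson statistic of the equivalent stratum-mean model over its
residual degrees of freedom; under this quasi-likelihood there is no
AIC and the package reports it as unavailable.

**Weather adjustment.** Temperature and relative humidity enter as
natural cubic splines with 3 degrees of freedom (`splines::ns`):
interior knots at the 33.3%/66.7% quantiles of the analysis sample,
boundary knots at the observed min/max, linear beyond the boundaries.
All three exposures (pollutant, temperature, humidity) are lagged by the
same $L$; rows with any missing value are dropped per lag (listwise),
and strata reduced below two rows or with zero events are dropped since
they carry no conditional information. The data-supplying analysis is
silent on how missing pollutant days should be treated; listwise
deletion per lag is the neutral default here.

## The exposure transformation

The exposure enters as $T(Z) = f(Z)\,\mathrm{LWF}(Z)$ with
$$\mathrm{LWF}(Z) = \frac{1}{1 + \exp\!\big((\mu - Z)/(r\,\tau)\big)},$$
where $\mu$ (ppb) is the half-weight location, $\tau > 0$ a
dimensionless steepness, and $r$ (ppb) the observed concentration range
of the analysis sample at that lag (max − min), fixed from the data and
never optimised. Three variants:

* **(a)** no transformation, $T(Z) = Z$: the classical analysis;
* **(b)** $f \in \{Z, \sqrt{Z}, \log(1+Z), Z^P\}$ with $(\mu, \tau)$
  from a tabulated grid: $\mu$ at the 0/25/50/75th percentiles of $Z$,
  $\tau \in \{0.1, 0.2\}$, one conditional fit per cell, AIC-minimal
  cell wins (ties break to smaller $\mu$, then smaller $\tau$, then the
  family order as listed), then $\mu$ is refined in 5-percentile steps
  (five above, five below; from the 0th percentile the search continues
  below the observed minimum in increments of the 5th-percentile-minus-
  minimum difference while the log-likelihood improves);
* **(c)** the flexible form $f(Z) = \log(1 + Z/A)$ with $(A, \mu, \tau)$
  chosen by iterative AIC minimisation (`optimize_spec()`).

The one-unit shift in the log family ($\log(1+Z)$ rather than $\log Z$)
keeps near-zero concentration days valid — ozone series contain them —
and is configurable by using the power or scaled-log families instead.

**Numerical strategy for (c).** Nelder–Mead on the unconstrained scale
$(\log A,\ \mathrm{logit}((\mu - \min Z)/r),\ \log\tau)$, which enforces
$A, \tau > 0$ and keeps $\mu$ inside the observed range; eight
deterministic starts ($\mu$ at the 25th/50th percentiles,
$\tau \in \{0.01, 0.1\}$, $A \in \{\mathrm{med}(Z), 10\,\mathrm{med}(Z)\}$),
relative objective tolerance $10^{-10}$ (about $10^{-5}$ on the AIC at
the likelihood magnitudes of a decade-long series), up to 500
evaluations per start, plus up to three restarts from the incumbent —
a collapsed simplex re-expands and often gains a little along the flat
direction. Every objective evaluation refits the conditional model,
warm-started from the previous coefficients. The search is fully
deterministic given the data.

**The $A$–$\beta$ ridge.** For $A \gg \max Z$,
$\log(1 + Z/A) \approx Z/A$, so $(\beta, A)$ are only jointly identified
up to near-proportionality, and for small $\tau$ the weight becomes a
step whose location trades off against $A$. Fitted parameter *values*
can therefore be extreme (enormous $A$ with correspondingly enormous
slope) while the fitted *curve* $\beta\,T(Z)$ over the observed range is
stable. The package reports the profile as found and does not
regularise it; consumers should interpret curves, not raw parameters.
AIC counts only the coefficients maximised in the likelihood (7); a
sensitivity option (`k_correction`) adds 2 per searched transformation
parameter.

## Pooling over lags

Lags with $\hat\beta \le 0$ are excluded (`select_lags()`); if none
remains, pooling is refused with a distinct error. For the retained
lags, the per-lag log-RR curves $\hat\beta_L T_L(Z)$ are evaluated on a
common grid of 200 equally spaced points from 0 to the observed maximum
concentration, and the pooled form
$$\beta(Z) = \theta \log(1 + Z/A)\,\mathrm{LWF}(Z;\mu,\tau)$$
is fitted by unweighted least squares over all lags and grid points — no
variance weighting and no cross-lag correlation enter, which keeps the
summary transparent but means the boundary curves are descriptive, not
formal confidence bands. The same form is fitted, independently, to the
set of per-lag lower envelopes ($\hat\beta_L - 1.96\,SE_L$ through
$T_L$) and upper envelopes. Given $(A, \mu, \tau)$ the criterion is
linear in $\theta$, so $\theta$ is profiled out exactly and Nelder–Mead
searches only three parameters, with the same reparameterisation as
variant (c), an extra flat-weight start ($\tau = 1$) whose basin holds
(log-)linear input curves, tolerance $10^{-12}$, and incumbent restarts.
Pooling a single curve that is itself of pooled form is an exact fixed
point (residual sum of squares at machine zero), which the tests assert;
for straight-line inputs the least-squares optimum is the line with the
mean slope, an independently computable oracle the tests also assert.

The range $r$ entering the pooled LWF is the mean of the per-lag ranges
(they differ only through per-lag missingness). Desk evaluations of
published parameter sets use a representative $r = 50$ ppb; at 30 ppb
the weight is within $10^{-4}$ of 1 for any plausible range, so those
reproductions are insensitive to this convention.

**Threshold.** `detect_threshold()` reports the largest grid
concentration $Z^\*$ (0.5-ppb steps by default) such that
$RR(Z) - 1 < \varepsilon$ for every grid point below it. For the pooled
sigmoidal family with $\theta > 0$ this is finite and meaningful; for
the log-linear variant-(a) curve any $\varepsilon \to 0^+$ drives the
threshold to zero — that family cannot express one.

## The simulator

`simulate_daily_series()` generates the structure the method assumes:
ten years (3652 days) of daily counts with a marginal mean of 80/day
(~292,000 events), weekday effects, a winter-peaking seasonal count
cycle (log-amplitude 0.1), a summer-peaking ozone-like exposure
(seasonal mean 25 ppb, amplitude 10 ppb, AR(1) day-to-day coefficient
0.7 with innovation SD 6 ppb, truncated at zero, overall SD ≈ 11 ppb), a
cold-continental temperature cycle sharing the exposure's seasonal
phase (the confounding channel), humidity, a mild U-shaped
temperature-to-count effect, and a known true C-RF
$\theta \log(1+Z/A)\mathrm{LWF}(Z)$ acting on lagged exposure through
per-lag multipliers (defaults: full effect at lags 0–8, none at lag 9).
All log-scale components are centred in-sample so that `baseline` is the
marginal mean count under any setting; within-stratum contrasts, which
drive estimation, are unaffected. Everything is reproducible from one
integer seed, and the truth travels with the series as a JSON-able
attribute.

What the simulator does *not* emulate: measurement error in the
exposure, multi-station spatial averaging, holiday effects, long-term
trends, and influenza epidemics. Passing tests therefore demonstrate
the estimator's behaviour under the assumed data-generating structure,
not robustness to everything real series contain.

One deliberate realism matters for interpretation: the winter count
cycle is not fully absorbed by year-month-weekday strata (a sinusoid
still varies within a month), and its within-stratum remainder is
anti-phased with ozone. Temperature splines absorb most but not all of
it (temperature carries independent noise), leaving a small residual
confounding bias of roughly $-0.4$ standard errors on the slope in a
decade-long series — real, by design, and invisible at shorter series
lengths where the standard error dominates. The calibration tests
isolate estimator correctness by switching the count seasonality off;
the null-coverage acceptance check keeps confounding on at $n = 1000$
days, where nominal 95% coverage holds.

## Validation studies and their sizes

The test suite runs, per session: exhaustive calendar checks
(1990–2005); 50 randomised oracle comparisons against the stratum-dummy
GLM; 300 null replicates at $n = 1000$ days for confidence-interval
calibration under confounding; 40 replicates at $n = 3652$ for coverage
of a log-linear truth; and 25 replicates of the full flexible pipeline
at $n = 3652$, 80 events/day, truth $\theta = 0.05$, $A = 20$ ppb,
$\mu = 12$ ppb, $\tau = 0.02$, effect at lag 0, for recovery of the
pooled $RR(30)$.

The recovery study places the full true effect at a single lag and runs
the pipeline at that lag (pooling's exact fixed-point case). The reason
is structural: the pooled curve estimates the *common marginal* per-lag
association. With serially correlated exposure, a distributed-lag truth
makes each marginal per-lag curve a leakage-weighted mixture of
neighbouring days' effects (weights $\approx \rho^{|\Delta L|}$), so the
pooled curve then differs from the generating curve by design — with
uniform shares over lags 0–8 and $\rho = 0.7$ the pooled slope is
roughly $0.45\theta$, and with the full effect at every lag it is
roughly $3\theta$ — and a comparison against the generating curve would
measure that design property, not estimation error. At a single lag the
comparison is clean. Even so, the ±0.01 recovery tolerance on $RR(30)$
sits at the edge of the information content of a decade-long series:
the sampling standard deviation of $\widehat{\beta(30)}$ alone is about
0.008–0.013 on the RR scale at these conditions (the corresponding
published per-lag standard errors imply the same order), so the
realised recovery rate hovers around the target rather than safely
above it; the acceptance test reports whatever the fixed seeds produce.

## Known limitations

* The pooled boundary curves are least-squares fits to the envelope
  curves, not confidence bands; no bootstrap or ensemble weighting is
  provided.
* The $A$–$\theta$ ridge means pooled parameter values (and their
  printed magnitudes) are not individually interpretable; only curves
  are.
* Counts only: individual-level case-crossover records are out of
  scope.
* The threshold is a grid statement at resolution $\varepsilon$, not a
  changepoint estimate with uncertainty.
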