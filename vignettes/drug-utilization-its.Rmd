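---
title: "Interrupted time series analysis of drug dispensing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrupted time series analysis of drug dispensing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxits)
```

## The analytical problem

Monthly pharmacy dispensing registries record, per region and demographic
stratum, the total dispensed volume of a drug class (in WHO defined daily
doses, DDD) and counts of incident recipients. When a population-level
disruption occurs — here, the COVID-19 pandemic beginning March 2020 — the
analytical questions are: did dispensing shift abruptly around onset, did
the long-run trend change, and how much of what was eventually observed can
be attributed to the disruption rather than to pre-existing dynamics?

`rxits` answers these with an interrupted time series (ITS) design on a
fixed 60-month window, January 2018 – December 2022, split into a
pre-pandemic period (26 months, through February 2020) and a pandemic
period (34 months, from March 2020). The window is deliberately hard-coded:
every regressor shape, accumulation total and period definition depends on
these anchors (March 2020 = month 27, June 2020 = 30, December 2021 = 48,
December 2022 = 60), and a configurable window would silently invalidate
them.

## Outcomes

**DDD/TID.** The volume outcome is dispensed DDDs per 1000 inhabitants per
day, $v_p = \sum_m u_{m,p} / (d_p n_p) \cdot 1000$. For multi-month periods
the package uses the exact sum of calendar days for $d_p$ and the mean of
the monthly populations for $n_p$; this reduces to the single-population
formula whenever population is constant within the period, which is how
registry extracts typically report it. Population is stored per month and
never interpolated by the package — mid-year population revisions are the
data producer's responsibility.

**Incidence.** Incident recipients per 100,000,
$\sum k_p / \sum n_p \cdot 100{,}000$, where a person is incident in month
$m$ if they have a dispensing of the class in $m$ and none in the 12
preceding *calendar months*. The washout operates at month resolution
because incident counts are delivered monthly; a day-level washout is not
reconstructible from the monthly schema, and the choice is surfaced here
rather than hidden. A person dispensing several times within their incident
month counts once.

**Relative change.** Quarterly metrics are compared against the same
quarter of 2019, the last complete pre-pandemic year:
$\Delta_{q,y} = (v_{q,y}/v_{q,2019} - 1)\cdot 100$. Every quarter of 2019
maps to exactly 0 by construction; a zero base quarter is an error, not a
silent `Inf`.

## Intervention regressors

Two regressor families encode the pandemic, as pure functions of the
calendar:

* **Volume pulse** (March–May 2020): the dispensing surge at onset followed
  by a compensating dip. The default shape $(+1, -\tfrac12, -\tfrac12)$
  sums to zero, so the fitted coefficient reads as "DDD/TID shifted into
  March from April–May" — stockpiling, not net change. The magnitudes
  $(a, b)$ are configurable because published analyses do not always pin
  down the exact encoding; the sign pattern and timing are the fixed part.
  A `"slovenia"` variant mirrors the pattern ($-b, -b, +a$) for registries
  where dispensing instead dipped in March–April and rebounded in May 2020.
* **Volume ramp**: 0 through May 2020, then $1, 2, \ldots, 31$ to December
  2022. Its coefficient is a change in slope (units/month); the cumulative
  effect at month $t$ is the coefficient times the ramp value, hence
  $\times 31$ at the end of the window.
* **Incidence regressors**: an indicator pulse over March–May 2020 (a level
  shift during the first lockdowns, expected negative — unlike the volume
  pulse there is no compensating rebound to encode), a ramp from June 2020
  that freezes at 19 after December 2021 (trend growth that moderates once
  restrictions ease), and a separate 2022 ramp ($1..12$) for any remaining
  trend. Over the whole window the plateau and 2022 ramps sum to the plain
  ramp — the two parameterisations decompose the same post-onset trend — so
  the two families are never mixed in one design matrix.

Accumulated totals over the pandemic window, used by the attribution
arithmetic, follow from the shapes alone: pulse 3, ramp–plateau
$\sum_{1}^{19} + 19\cdot12 = 418$, 2022 ramp $\sum_{1}^{12} = 78$, and the
volume ramp reaches 31.

## The ITS model

`fit_its()` estimates a regression with seasonal ARIMA errors: the
regression part always carries an intercept and a deterministic linear
trend in the month index alongside the intervention columns, so a ramp
coefficient is a *change* in slope relative to the established trend, not
the post-period slope itself. Estimation is maximum likelihood through
`stats::arima` (exact ML; a failed fit is retried with a conditional
sum-of-squares start); when all ARMA orders and differencing are zero the
model *is* ordinary least squares on $[1, t, X]$ and is fitted as such,
which keeps noiseless oracle inputs exact instead of degenerate. With
ordinary differencing the intercept drops and the trend column acts as
drift, the standard convention.

Significance uses the z-test (estimate over its information-matrix SE
against a standard normal) and 95% CIs are estimate $\pm 1.96 \cdot$ SE,
both at the 0.05 level. These are the analysis's published conventions and
are kept even where a $t$ or profile interval might behave better at
$n = 60$ (see Limitations).

### Order selection

`select_orders()` fixes the differencing first: ordinary $d$ by sequential
KPSS testing (trend-stationarity of the level series, since the model
carries a deterministic trend; then level-stationarity of the differenced
series; at most 2), seasonal $D \in \{0, 1\}$ by an STL seasonal-strength
heuristic with the customary 0.64 threshold. It then fits the
regression-only ARMA(0,0) error model and **keeps it whenever its residuals
pass the Ljung–Box criterion (maximum lag 12) at 0.05** — the same adequacy
test applied to final fits. Only when that gate fails does a greedy
stepwise AICc search run, from four standard starting models, moving one
order at a time within $p, q \le 3$, $P, Q \le 2$, period 12. The gate is a
deliberate parsimony device: an unguarded AICc stepwise at $n = 60$ retains
a true white-noise specification only about half the time (each of several
candidate moves has a roughly 1-in-8 chance of a spurious AICc gain),
whereas "add ARMA structure only when residual autocorrelation is
detectable" matches how ITS analysts actually build these models and keeps
the false-structure rate at the Ljung–Box test's size. AICc uses the
effective sample size after differencing, with the innovation variance
counted as a parameter.

### Diagnostics

`diagnose()` reports the Ljung–Box statistic at lags 1..12 — by default
*without* subtracting fitted ARMA degrees of freedom, because the stated
contract is simply "maximum lag 12"; `fitdf` is an explicit toggle for the
adjusted variant — and the KPSS statistic under both the level- and
trend-stationarity nulls. KPSS p-values are linearly interpolated from the
standard critical-value table (0.347/0.463/0.574/0.739 level,
0.119/0.146/0.176/0.216 trend, at 10/5/2.5/1%); statistics outside the
table are clamped to [0.01, 0.10] and flagged `p_clamped`, so a reported
0.10 means "at least 0.10". The Bartlett long-run-variance truncation lag
is $\lfloor 4 (n/100)^{1/4} \rfloor$ (3 at $n = 60$); the statistic was
verified against an independent reference implementation to 10 decimal
places. All pass flags are $p \ge 0.05$.

## Attribution

`volume_attribution()` multiplies a *significant* ($p < 0.05$, strictly)
ramp coefficient and its CI bounds by 31; `incidence_attribution()` sums,
over the significant subset of the three incidence coefficients, estimate
$\times$ accumulated total (3/418/78), and likewise for the CI bounds.
Summing per-coefficient bounds ignores the coefficients' covariance, so the
low–high range is conservative and may straddle zero; this is the published
convention for these tables and is therefore the default. Non-significant
coefficients contribute nothing — with none significant the estimate is
reported as "not computed" (dashes in CSV output), never as a hard zero.
Shares are middle/observed $\times 100$, requiring a positive observed
value. Display rounding is 3 decimals for DDD/TID quantities, 1 for
incidence and shares; internally nothing is rounded.

## The synthetic-data generator

The generator emulates the *statistical structure* the analysis assumes:
linear trend, a single annual sinusoid (registries show a seasonal
dispensing rhythm but its harmonic content is not characterised, so one
configurable harmonic is the default), Gaussian ARMA noise for volumes
(continuous DDD totals), Poisson counts around the expected incidence, and
the injected pulse/ramp effects themselves. Volume outcomes are generated
on the DDD/TID scale and converted to dispensed DDD totals by inverting the
metric with the stratum population and exact calendar days, so
`compute_dddtid()` recovers the clean signal identically when noise and
effects are off. Negative outcomes are truncated at zero and counted.
Default region baselines span 27–210 DDD/TID, the range observed across
European antidepressant registries, so tests exercise low- and high-volume
regimes.

The person-level generator draws Poisson numbers of new starters per month
(with at least 12 months of pre-2018 burn-in) who refill in consecutive
months with a configurable persistence probability and then stop for good.
Because stopped users never return, the generator's logged starter counts
are *exactly* the incident recipients under the 12-month washout — a
bookkeeping oracle the tests exploit. What the generator does **not**
emulate: country-specific policy timelines, reimbursement differences,
within-month dispensing dates, restarting users, or non-stationary
populations. Passing tests therefore demonstrate the pipeline's
correctness and calibration under its stated assumptions, not fidelity to
any real registry.

Simulation studies in the test suite use 60-month series with AR(1) noise
($\phi = 0.5$, innovation SD 1.5 on a baseline of 50 DDD/TID), 200
replicates for recovery/coverage, 100 randomized tables for the washout
oracle, and 500 replicates for diagnostics calibration — sizes chosen to
give binomial standard errors of 1–2 percentage points on the rates being
checked.

## Numerical choices and degenerate inputs

* Differencing drops the corresponding leading residuals, so residual
  vectors have $60 - d - 12D$ values; diagnostics refuse vectors no longer
  than the Ljung–Box lag.
* Rank deficiency of $[1, t, X]$ is detected before fitting and reported
  with the offending column names (the volume ramp together with both
  incidence ramps is the canonical trap).
* A zero innovation variance (noiseless input) is handled by the OLS path;
  a zero SE yields $z = \pm\infty$ and $p = 0$ rather than `NaN`.
* Zero population, negative DDD, calendar gaps and unknown stratum labels
  are hard errors at construction; a stored February with 29 days in a
  non-leap year only warns, because days are data, not derived.
* Stepwise search ties break toward the incumbent (an improvement must
  exceed `1e-8` in AICc).

## Known limitations

* **Finite-sample calibration of the z-test.** With an estimated AR
  parameter at $n = 60$, ML underestimates $\phi$ on average, which shrinks
  the reported SE of trend-like regressors; the acceptance script measures
  empirical CI coverage and null significance rates for the ramp
  coefficient under the generator's AR(1) conditions, and these fall
  somewhat short of nominal (coverage below 0.95, type-I above 0.05). A
  GLS oracle with the true $\phi$ is well calibrated on the same data, so
  this is a property of the method's small-sample behaviour, shared by
  standard ARIMA implementations, not of this implementation. Interpret
  borderline p-values near 0.05 accordingly.
* The attribution interval propagates per-coefficient CI bounds, not the
  joint covariance; it is honest about this by construction (see above)
  and a covariance-aware interval is a possible extension.
* KPSS p-values are table-interpolated and clamped; they are decision
  tools at the 0.05 level, not continuous evidence measures.
* The pipeline is monthly throughout; nothing below month resolution
  (dispensing dates, day-level washout) is represented.
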