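# rxits

Interrupted time series (ITS) analysis of monthly drug dispensing data, for
pharmacoepidemiologists studying how a disruption — here, the COVID-19
pandemic — changed the volume and incident use of a drug class across
regions and demographic strata.

The package covers the full analysis pipeline on a fixed 60-month study
window (January 2018 – December 2022, pandemic onset March 2020):

1. **Utilization metrics.** Dispensed volume per period as DDD/TID
   (defined daily doses per 1000 inhabitants per day),

   $$v_p = \frac{\sum_{m=1}^{k} u_{m,p}}{d_p\,n_p}\cdot 1000,$$

   where $u_{m,p}$ is the dispensed DDD total of month $m$, $d_p$ the days
   and $n_p$ the population of period $p$; treatment incidence per 100,000
   as $\sum k_p / \sum n_p \cdot 100{,}000$, with incident recipients
   defined by a 12-month washout (no dispensing of the drug class, ATC
   `N06A`, in the preceding 12 calendar months); and relative change of any
   quarterly metric versus the pre-pandemic base year 2019,
   $\Delta_{q,y} = (v_{q,y}/v_{q,2019}-1)\cdot 100$.

2. **Intervention regressors.** A zero-sum stockpiling pulse over
   March–May 2020 (shape $(+1,-\tfrac12,-\tfrac12)$, with a mirrored
   "decrease-then-rebound" variant), a ramp from June 2020 rising to 31 at
   December 2022 (volume analysis), and for the incidence analysis a
   March–May 2020 indicator pulse, a June 2020 – December 2021 ramp held at
   its final value (19) through 2022, and a separate 2022 ramp.

3. **Seasonal ARIMA ITS fits.** Regression with seasonal ARIMA errors
   (intercept, deterministic linear trend, intervention columns), orders
   chosen by a bounded stepwise AICc search with KPSS-based differencing,
   coefficients tested by z-test with 95% CIs $\hat\beta \pm 1.96\,SE$;
   residual diagnostics via the Ljung–Box test (maximum lag 12) and KPSS
   level- and trend-stationarity tests at the 0.05 level.

4. **Pandemic attribution.** A significant ramp coefficient $\hat\beta$
   (DDD/TID per month) implies an end-of-window change of
   $\hat\beta \times 31$ DDD/TID (middle estimate; CI bounds give low/high),
   reported together with its share of the observed December 2022 value.
   For incidence, the cumulative change over 3/2020–12/2022 sums each
   significant coefficient times its accumulated regressor value
   ($3$, $418$, $78$ for pulse, ramp–plateau, 2022 ramp).

5. **Synthetic cohorts.** A stratified generator (trend + annual
   seasonality + ARMA noise + injected pulse/ramp effects; Poisson incident
   counts; person-level dispensing histories with a burn-in so the washout
   is exercisable) makes every stage testable without registry access.

## Worked example

Simulate one region with a known post-June-2020 slope change of
0.25 DDD/TID per month, fit the ITS model, and attribute the change:

```r
library(rxits)

cfg <- simulation_config(
  regions = "utopia", region_baselines = c(utopia = 70),
  trend_slope = 0.15, seasonal_amplitude = 2, ar = 0.4,
  innovation_sd = 1, pulse_effect = 6, ramp_slope = 0.25, seed = 2024
)
series <- simulate_volume_series(cfg)[["utopia|all|all"]]
y <- vapply(1:60, function(m) compute_dddtid(series, m)$v, numeric(1))
X <- cbind(volume_pulse = build_volume_pulse(),
           volume_ramp  = build_volume_ramp())

fit <- fit_its(y, xreg = X)   # orders chosen by select_orders()
fit
#> Interrupted time series fit (volume outcome), ARIMA (0,0,0)(0,1,0)[12], n = 60
#> log-likelihood -84.10, AICc 177.13
#>   term         estimate     se     z  p_value ci_low ci_high significant
#> 1 trend           0.196 0.0258  7.61 2.66e-14  0.146   0.247 TRUE
#> 2 volume_pulse    5.55  0.806   6.89 5.56e-12  3.97    7.13  TRUE
#> 3 volume_ramp     0.233 0.0368  6.34 2.34e-10  0.161   0.306 TRUE

diagnose(fit)
#>   test       statistic p_value pass
#> 1 ljung_box    19.9     0.0684 TRUE
#> 2 kpss_level    0.0805  0.1    TRUE
#> 3 kpss_trend    0.0796  0.1    TRUE

volume_attribution(fit, observed_dec2022 = y[60])
#> <attribution_estimate> (volume)
#>   middle 7.238 [low 4.999, high 9.476], observed 86.76751, share 8.3%
```

The fitted monthly rate (0.233, true value 0.25) accumulates over the 31
ramp months to a middle estimate of 7.24 DDD/TID attributable to the
disruption — 8.3% of the observed December 2022 level — and the 95% range
[5.00, 9.48] covers the injected cumulative effect of
$0.25 \times 31 = 7.75$. The stockpiling pulse (true 6, fitted 5.55) and
the pre-existing trend are recovered alongside, and the residual
diagnostics raise no autocorrelation or stationarity flags.

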