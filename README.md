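# overwintr

Projecting estuarine overwintering conditions for blue crab (*Callinectes
sapidus*) from long daily temperature records.

Blue crab growth stops below a critical temperature of about 9 °C; the crabs
bury in sediment and become dormant ("overwintering"), and the length and
severity of that dormancy drive winter mortality. In mid-latitude estuaries
such as Chesapeake Bay, a warming climate shortens the overwintering period
and raises overwinter survival, with direct consequences for population
productivity and fishery management. `overwintr` implements the full
inference chain from daily air/water temperature observations to projected
overwinter duration and survival through 2100:

1. **Record assembly** — merge multiple observation sources in priority
   order, fill interior gaps by linear interpolation, and characterise the
   raw record (gap statistics, autocorrelation decorrelation scale).
2. **Harmonic model and transfer function** — fit
   `T(tᵢ) = B₀ + B₁tᵢ + Σₘ [Cₘ cos(m w tᵢ) + Sₘ sin(m w tᵢ)]`, with
   `w = 2π/365.25`, to air and water temperature by OLS; form the
   air→water transfer function from per-harmonic coefficient ratios
   `crₘ = CWₘ/CAₘ`, `srₘ = SWₘ/SAₘ`, after a random 30 %/70 %
   calibration/validation split and a final refit on all days:
   `WT(tᵢ) = B₀ + B₁tᵢ + Σₘ [crₘ CAₘ cos(m w tᵢ) + srₘ SAₘ sin(m w tᵢ)]`.
3. **Projection to 2100** — an extended-trend scenario (the transfer
   function's point estimates continued forward, with uncertainty from
   resampling every coefficient from N(estimate, SE)), and a
   downscaled-GCM-style scenario (per-member harmonic refits of an
   ensemble of daily air-temperature members, transfer ratios applied,
   mean ± SD across members).
4. **Winter metrics and survival** — per winter year (July–June, labelled
   by the starting year), the number of days strictly below 9 °C (winter
   length) and their mean temperature (severity), fed into a Weibull
   accelerated-failure-time survival model
   `S(t) = exp(−t^λ · e^(−λ(3.59 + 0.10·Temp + 0.02·Sal + 0.03·Size)))`.
5. **Trend statistics** — OLS trends in winter length/survival, Welch
   t-tests contrasting scenarios in four future intervals, and a
   latitude-equivalence regression (where on the coast today's climate
   matches the projected future).

A synthetic-data module (`climate_sim_config()`, `generate_pair()`,
`generate_member_ensemble()`) produces records with known ground truth —
trend + annual harmonic + AR(1) noise, realistic weekend/holiday gap
patterns, GCM-like member ensembles — so the whole chain is testable
without any external download.

## Worked example

```r
library(overwintr)

# a synthetic 1938-2016 pier-style record with known truth
sim   <- generate_pair(climate_sim_config(seed = 1))
air   <- interpolate_gaps(sim$air)
water <- interpolate_gaps(sim$water)

gap_statistics(sim$air)
#> # A tibble: 1 × 4
#>   n_gaps mean_gap_length max_gap_length filled_fraction
#>    <int>           <dbl>          <int>           <dbl>
#> 1   4358            2.04             27           0.309

proto <- fit_transfer_protocol(air, water, seed = 2,
                               time_origin = as.Date("1938-01-01"))
proto$transfer
#> <transfer_function> M = 1, stage = final
#>   cr: 0.9511  sr: 0.9429
#>   trend ratio: 0.9701

ext <- extend_trend(proto$transfer, as.Date("2100-12-31"))
mean(ext$value[ext$date >= as.Date("2070-01-01") &
               ext$date <= as.Date("2099-12-31")])
#> [1] 17.67466   # degC, up from the 15.17 1961-1990 mean

winters <- winter_metrics(water, threshold = 9)
linear_trend(winters)
#> # A tibble: 1 × 5
#>    slope intercept r_squared     p_value     n
#>   -0.239      593.     0.280 0.000000641    78

surv <- winter_survival_series(winters,
                               survival_params(lambda = 1, sal = 12, size = 40))
autoplot(surv)
```

The fitted ratios recover the generator's design (cr = sr = 0.95), winters
shorten by ~0.24 days/yr over the record, and the extended trend warms the
2070–2099 window by ~2.5 °C over the reference period — shrinking the
end-of-century overwintering period to ~87 days. The survival shape `λ` and
ambient salinity are study-specific calibration constants with no package
default; `λ = 1` (exponential) and mid-estuary salinity 12 are illustrative.

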