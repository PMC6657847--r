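---
title: "From daily temperature records to overwinter survival: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From daily temperature records to overwinter survival: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overwintr)
```

# The problem

Blue crab (*Callinectes sapidus*) stop growing below roughly 9 °C; they bury
and enter dormancy, and both the duration of that overwintering period and
the temperature during it determine winter mortality. Long pier records of
daily air and water temperature in mid-latitude estuaries let us ask how a
warming climate changes those two quantities — and hence overwinter
survival — through the end of the century. `overwintr` implements that
inference chain as composable, tested pieces: record assembly, a harmonic
air→water transfer function, two projection scenarios with uncertainty,
threshold-based winter metrics, a parametric survival model, and the
summary statistics that compare scenarios.

# Record assembly

Daily series are plain tibbles (`date`, `value`, `provenance`, `variable`),
so every stage composes with dplyr verbs. `merge_sources()` implements the
first-non-missing priority scan used to build a "combined" record from a
primary station and ordered fallbacks, keeping per-day provenance.
`interpolate_gaps()` fills interior missing runs with the straight line
between flanking observations, evaluated at integer day offsets — justified
for water by its thermal inertia: day-to-day changes are small relative to
the seasonal cycle. Leading and trailing missing runs are trimmed, never
extrapolated: extrapolation beyond the first or last observation has no
support in the data. `max_gap` defaults to unlimited (blanket
interpolation); it is exposed because reusers with sparser records may
prefer to leave long runs missing.

`decorrelation_scale()` reports the smallest lag at which the sample
autocorrelation first falls below 1/e. On a raw daily record the annual
cycle dominates the variance, so this scale mostly reflects seasonal
persistence; for an annual cosine alone the 1/e lag is
`acos(1/e)/w ≈ 69` days, and AR(1) weather noise shifts it only modestly.
Published decorrelation scales are sensitive to the criterion used (1/e,
first zero crossing, integral timescale), which is why the criterion here
is explicit and the harmonic pre-detrending variant (`detrend = TRUE`) is
provided: on residuals the scale instead measures weather-band persistence,
`-1/log(φ)` for AR(1) noise.

# The harmonic model and transfer function

Both temperatures are modelled as

$$T(t_i) = B_0 + B_1 t_i + \sum_{m=1}^{M}\left[C_m \cos(m w t_i) + S_m \sin(m w t_i)\right],
\qquad w = \frac{2\pi}{365.25},$$

fitted by ordinary least squares (`stats::lm`), with coefficient standard
errors from the OLS covariance. Two choices deserve comment.

**The time coordinate.** A day-of-year coordinate cannot carry a
multi-decadal trend, so by default $t_i$ is continuous days since a declared
`time_origin` (default 1938-01-01): $B_1 t_i$ is then the long-term warming
trend, and because $w$ is exactly the annual angular frequency the harmonic
terms keep correct phase on a continuous axis. A `day_of_year` mode exists
for pure seasonal climatology, where the trend term is meaningless.

**The harmonic count.** $M = 1$ (annual cycle only) is the default;
estuarine records are strongly annual, and higher harmonics mostly fit
asymmetries that the transfer ratios then amplify noisily. $M > 1$ is a
plain argument.

The protocol (`fit_transfer_protocol()`) draws a random 30 % of days as
the calibration set, fits air and water models on it, and forms the
transfer function from per-harmonic coefficient ratios
$cr_m = CW_m/CA_m$, $sr_m = SW_m/SA_m$. The validation RMSE is computed on
the held-out 70 %. The *final* model refits both series on all days and
rebuilds the ratios — more data cannot hurt a correctly specified model,
and the final/validation RMSE comparison makes that checkable. Ratios are
refused when an air coefficient is within 1e-6 °C of zero (the ratio would
explode); the guard tolerance is an argument for synthetic edge cases.

**Intercept and trend when predicting.** Driving the transfer function with
its own air fit (historical window, extended trend) uses the water-side
$B_0, B_1$ — the literal transfer equation. Driving it with an
*independently fitted* air series (a climate-model member) instead takes
$B_1 = \text{trend ratio} \times B_1^{air}$, with $B_0$ offset so the trend
line is continuous with the observed water record at its last day. The
rationale: a projection driven by a high-emissions scenario must inherit
that scenario's warming, which a frozen historical water trend cannot
express; and anchoring at the end of observations removes any absolute
bias in the member's mean level (only its harmonic shape and trend enter).
The literal mode remains available via `predict_water(..., intercept = "water")`.

# Projection scenarios and uncertainty

`extend_trend()` evaluates the final model's point estimates on every day
from the end of observations to 2100 — a conservative scenario in which the
future continues the observed trend. Its uncertainty comes from
`resample_projections()`: every coefficient of the air and water fits is
drawn independently from Normal(estimate, SE), the ratios are rebuilt per
draw, and the per-day mean and SD across (by default 50) draws summarise
parameter uncertainty. Drawing coefficients independently ignores their
covariance and therefore understates joint uncertainty; it is the stated
propagation rule here, kept deliberately simple.

`read_member_ensemble()` converts downscaled-GCM-style output — per-member,
per-grid-cell daily minimum and maximum temperature — into one air series
per member (midpoint (min+max)/2, unweighted mean over cells), dropping
physically inconsistent days (min > max) with a warning and rejecting
members with more than 5 % missing days. `project_ensemble()` refits the
air harmonic model per member over the member's full span and applies the
transfer ratios with the continuity rule. Whole-span fitting linearises any
curvature in the member's warming; a trailing-window mode
(`refit_window = "sliding"`) exists for scenarios where that curvature
matters. Days overlapping the observational record inform the member fits
but are excluded from the reported projection.

# Winter metrics and survival

Winters bridge calendar years, so each winter is labelled by its starting
year and anchored to a July 1 – June 30 window, keeping it contiguous.
`winter_metrics()` counts days with temperature *strictly* below the
threshold (default 9 °C) and defines severity as the mean over those
sub-threshold days; averaging the whole window instead is switchable
(`severity = "window"`), since either convention is defensible. Only fully
covered winters are emitted. Leap-year winters have one extra day available
below threshold — a real calendar artifact that propagates into a visible
±1-day oscillation in projected winter length, deliberately not patched.

Overwinter survival is the Weibull accelerated-failure-time model

$$S(t) = \exp\!\left(-t^{\lambda} e^{-\lambda\,lp}\right),\qquad
lp = 3.59 + 0.10\,\mathrm{Temp} + 0.02\,\mathrm{Sal} + 0.03\,\mathrm{Size},$$

equivalently $S(t) = \exp(-(t/\eta)^\lambda)$ with time scale
$\eta = e^{lp}$: $S(0) = 1$ exactly, strictly decreasing in duration,
increasing in temperature, salinity and size. The slope coefficients come
from a field-calibrated juvenile blue crab model; the shape $\lambda$ and
ambient salinity are external calibration constants and have **no
defaults** — silent defaults would make survival numbers look portable when
they are conditional on those constants. Winters with zero sub-threshold
days impose no overwinter exposure and get survival 1: in a warm enough
year the crabs simply do not overwinter.

# Trend statistics

`linear_trend()` is OLS of a yearly quantity on year with a two-sided slope
test. `scenario_contrast()` compares two scenarios' per-winter values in
year intervals with Welch's t-test by default — the two scenarios have no
reason to share a variance — with the pooled-variance Student variant and a
Bonferroni flag available; raw p-values are the default, matching common
practice of reporting per-interval tests at α = 0.05.
`latitude_equivalent()` regresses observed days-below-threshold on latitude
across coastal anchor sites and inverts the fit, refusing to extrapolate
beyond the anchor range plus 10 % and warning when the slope is not
significantly positive.

# The synthetic generator: what it does and does not emulate

`generate_pair()` simulates air as trend + annual harmonic + AR(1) noise
and water as the ratio-transformed deterministic curve plus AR(1) noise
with correlated innovations, then injects weekend gaps, scattered missing
days and Poisson-placed long runs with geometric lengths — the gap anatomy
of a manually read pier record. The defaults were set once to emulate a
1938–2016 Chesapeake-tributary regime and are not tuned thereafter:

* water 1961–1990 mean ≈ 15.2 °C (air intercept 13.5 °C + 0.88 °C offset
  and the trend's accumulation to the window midpoint);
* seasonal amplitude ≈ 12.2 °C for water (air 12.8 °C × ratios 0.95),
  back-computed so a ~17.6 °C end-of-century mean yields a ~90-day winter;
* warming 6.0e-5 °C/day (≈ 2.2 °C/century), the observed-trend scale;
* AR(1) noise φ = 0.8, innovation SD 1.2 °C (stationary SD 2 °C),
  air–water innovation correlation 0.7 — enough weather-band variability
  to spread winter lengths over roughly 95–145 days.

`generate_member_ensemble()` adds member-specific warming rates drawn
around a configured mean (an RCP8.5-like 4.6 °C/century in the shipped
analysis script, spread 1 °C/century across members) and emits the min/max
per-cell layout the ensemble reader consumes.

What the generator does **not** emulate: instrument changes (thermometer
vs sonde), source-dependent bias between merged stations, skewed or
heteroscedastic noise, curvature in the warming trend, and
higher-harmonic seasonal asymmetry. Passing tests therefore demonstrate
that the chain recovers known structure of this idealised form — linear
trend, single harmonic, AR(1) noise — not that the models are adequate for
any particular real record.

# Numerical choices and test design

* Exact annual frequency `w = 2π/365.25` throughout; leap days are real
  calendar days, so the leap artifact emerges naturally.
* OLS everywhere (no robust or GLS variants): the reference methodology is
  least squares, and coefficient SEs feed the resampling propagation.
  Under autocorrelated noise OLS standard errors are optimistic by
  ≈ √((1+φ)/(1−φ)); tests that check coefficient recovery under AR(1)
  noise inflate the reported SEs by that analytic factor, and the
  ratio-SE coverage check uses independent noise, where OLS SEs are exact.
  Stochastic coverage assertions use binomial Monte-Carlo tolerances
  rather than knife-edge cuts.
* The test suite and the analysis script keep problem sizes modest by
  choice: a 79-year daily record (~29k days), 50 resampled projections,
  a 41-member ensemble at 150 years × 3 cells in the script (12 members in
  the test suite), 100-replicate coverage loops on 6-year records. The
  full script runs in about two minutes on one CPU.
* Scenario contrasts in the acceptance checks pool per-winter records
  across ensemble members (and across resampled projections) in each arm,
  so each arm's sampling spread enters the t-test rather than collapsing
  to a single near-deterministic series per scenario.

# Known limitations

* Coefficient resampling without covariance understates joint parameter
  uncertainty; interannual variability in any real record exceeds these
  parameter-uncertainty bands.
* A single harmonic cannot represent asymmetric seasons; transfer ratios
  then absorb some asymmetry as bias.
* The survival level is conditional on λ and salinity supplied by the
  user; the package deliberately refuses to default them.
* The decorrelation scale depends on the chosen criterion; cross-study
  comparisons require matching definitions.
* No bias correction or downscaling is performed here — ensemble inputs
  are assumed already downscaled to the site.
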