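---
title: "Methods: multi-pathway THM risk with successive-shower accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-pathway THM risk with successive-shower accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thmrisk)
```

## Model and assumptions

`thmrisk` propagates uncertainty in a chain of closed-form exposure
equations by plain Monte Carlo. Per iteration and gender, one draw of the
exposure-factor vector and one draw of the four-species water
concentration vector feed all three routes — the routes describe the same
person, so sharing draws preserves realistic covariation between, e.g.,
dermal and inhalation risk, while leaving every route mean unchanged.

Assumptions worth keeping in mind:

* **Linear, no-threshold dose response.** Risks are `CDI × CSF` (oral) and
  `EC × IUR` (inhalation); totals are plain sums over species and routes,
  i.e. no interaction between the four THM.
* **Well-mixed stall air.** The shower stall is one compartment,
  `dC/dt = a − bC`, with volatilization source `a` and a loss `b`
  combining re-dissolution (limited by Henry partitioning) and ventilation.
  No spatial gradients, droplets, or air-temperature dynamics.
* **Successive showers average, not re-integrate.** For back-to-back
  events the exposure concentration follows the recursion
  `Cair(n) = (Cair(n−1) + Ct)/2` with closed form `(2^n − 1)/2^n · Ct`.
  This is a modelling rule, not the literal ODE restart; the physically
  literal alternative (re-solving the mass balance from the carried-over
  concentration) is available as `event_series(..., mode = "ode")` for
  comparison, and gives slightly different saturation. All headline
  results use the averaging rule.
* **No inter-event gap.** Events are strictly back-to-back. An inter-event
  ventilation decay would multiply the carried-over concentration by
  `exp(−(Qg/Vs)·gap)`; it is deliberately not applied by default because
  the communal-stall scenario of interest is rush-hour usage.
* **Heated water.** Dermal and inhalation use
  `Chw = Cw·e^((kh−kc)t)`, `k(T) = 0.0011·e^0.0407T`; ingestion uses the
  cold tap `Cw`. The source model for heating involves a hot/cold mixing
  fraction that is not pinned down anywhere we could find; we apply the
  formation-rate formula directly with the sampled hot and cold
  temperatures, which treats shower water as fully heated and is the only
  fully printed form. Henry's constants stay at their 40 °C values
  regardless of the sampled temperature.
* **Genders.** The pipeline runs female and male parameter sets with equal
  iteration counts and pools them; pooled means equal the equal-weight
  gender average.

## Parameters that matter

All uncertain factors are triangular `T(min, mode, max)`, the standard
screening-level choice when only a range and a most-likely value are
defensible. Defaults (see `default_parameters()`) describe an adult
residential campus population in West Bengal, India: ingestion rate
T(1, 2, 3) L/day; shower duration T(5, 10, 15) min; stall volume
T(2000, 3500, 5000) L; water flow T(3, 4, 5) L/min; baseline ventilation
T(40, 50, 60) L/min; showering frequency T(0.72, 0.74, 0.76) events/day;
route-specific exposure frequencies near 330–350 days/yr; gender-specific
exposure duration (~70 yr), body weight (55/65 kg) and averaging time
(~26 000 days); cold water T(10, 15, 20) °C, hot water T(35, 40, 45) °C.
Species constants (`default_species_constants()`): dimensionless Henry's
constants 0.25/0.124/0.0526/0.0501, mass-transfer coefficients KoLA
7.4/5.9/4.6/3.7 L/min, oral slope factors 0.0061/0.062/0.084/0.0079
(mg/kg/day)⁻¹ and inhalation unit risks 2.3e-5/3.7e-5/2.4e-5/1.1e-6
(µg/m³)⁻¹ for TCM/BDCM/DBCM/TBM.

Two structural choices were genuinely open:

* **Averaging time.** The source tabulates AT as its own triangular
  distribution while noting it is "calculated as per exposure duration".
  We sample AT from its own spec (the tabulated distribution is the
  stated world); `draw_parameters(..., couple_at_to_ed = TRUE)` instead
  computes `AT = ED × 365` per draw for users who prefer the coupling.
  The means differ by well under 1%.
* **Breathing rate.** Carried in the parameter table but unused: the
  exposure-concentration method works in air concentration, not inhaled
  volume. It is exposed for users implementing the older intake-based
  inhalation formula, which this package does not.

## What the synthetic water generator emulates — and what it does not

The generator stands in for a 26-site tap-water survey that was published
only as per-species min–max ranges plus a total-THM mean ± sd
(30.22 ± 14.45 µg/L). Reported distributional structure: TCM follows a
three-parameter Weibull, the brominated species normals. That leaves
every family parameter free, so we calibrate:

1. The mean ingestion multiplier `M = E[IR·EF·ED·0.001/(BW·AT)]` is
   estimated by Monte Carlo (1e6 draws; `calibrate_default_means()`
   re-derives it at any n).
2. Because ingestion risk is linear in concentration, each species' mean
   concentration backs out of its published mean ingestion risk:
   `m_i = CR_i/(CSF_i·M)`, giving 4.90, 8.61, 11.05, 3.34 µg/L
   (total 27.9 µg/L, 7.7% under the published total mean — the published
   risks and total mean are not perfectly mutually consistent, and we
   privilege the risks, which downstream tests check).
3. Family parameters are solved so each *truncated* distribution has mean
   `m_i`: TCM Weibull location 1.7 (the observed minimum), shape 1.8,
   scale numerically fitted; normal means numerically fitted with
   sd = range-width/4.

Truncation to the observed ranges is exact inverse-CDF conditioning
(a uniform variate on `[F(lo), F(hi)]` through the quantile function) —
identical in law to rejection sampling, deterministic in cost, and unlike
clamping it does not pile mass on the boundaries.

Limitations a green test does **not** establish:

* Species are sampled independently. The survey's maximum total
  (70.65 µg/L) is essentially the sum of the per-species maxima, which
  real co-formed THM would only reach if strongly correlated; under
  independence with truncation the total-THM sd is mathematically capped
  near 9.3 µg/L, below the published 14.45. The shipped sds sit near that
  cap. A Gaussian-copula hook (`config$copula`) lets users impose a
  correlation matrix for sensitivity work, but no default correlation is
  asserted.
* Per-species means are calibration outputs, not measurements.
* The optional free-chlorine covariate reproduces a squared correlation
  with total THM (default 0.63) and the observed 0–0.6 mg/L range;
  it feeds nothing downstream.

## Numerical choices

* Triangular and truncated-family sampling use inverse-CDF transforms of
  `runif` streams: bit-reproducible for a fixed seed across platforms.
* `(1 − e^(−bt))·a/b` is computed with `expm1` to avoid cancellation as
  `b → 0`; the `b = 0` limit returns `a·t` explicitly.
* Stall air is computed in µg/L (the natural unit of the mass balance,
  with volumes in litres) and converted ×1000 to µg/m³ in exactly one
  place, at the exposure-concentration boundary.
* Summaries report mean, sd, min, p10, median, p90, max; percentiles use
  linear interpolation between order statistics (`quantile` type 7 — for
  draws 1..100 the 10th percentile is 10.9).
* Trend fits are least squares on the linearized form (`ln y ~ x`
  exponential; `y ~ ln x` logarithmic) with R² on the linearized scale;
  a constant response yields the exact degenerate fit with R² = 1.
* Scans reuse the same seed at every grid point, so grid settings differ
  only through the pinned parameter and monotonicity holds per iteration,
  not just in the mean.

## Known limitations

* **Absolute inhalation levels are convention-dependent.** With the
  package's explicit unit chain (Cair µg/L → ×1000 µg/m³;
  ET = t·F/60 h/day; AT in hours) the mean S1 inhalation risk is
  ~1.4e-5, an order of magnitude above the published 1.11e-6 for the
  emulated study, whose air-unit conversion point and exposure-time
  construction are not stated. Every accumulation *ratio*, both scan
  *trend coefficients* (duration growth 0.148 vs published 0.142;
  ventilation decay −0.065 vs −0.064) and all oral-route absolutes agree,
  so comparisons across events, durations and ventilation rates — the
  package's purpose — are unaffected. Treat absolute inhalation CR with
  the same caution you would any Part-F-style screening number.
* **Duration trend is only approximately exponential.** Inhalation risk
  scales as `t·(1 − e^(−bt))·e^((kh−kc)t)`: linear-times-saturating, which
  on a log scale is concave. On the 5–25 min grid the exponential fit
  yields R² ≈ 0.942 — a good, but not excellent, summary (the package's
  acceptance suite intentionally records this as a failure against the
  stricter 0.95 expectation carried over from the emulated study's
  reported 0.98). The fitted growth *rate* is nevertheless stable and
  identical across event indices, because the accumulation factor cancels
  in ratios.
* No age-dependent adjustment factors (adult population), no non-cancer
  hazard quotients, no THM-formation modelling in the distribution
  network, and no spatial air modelling.
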