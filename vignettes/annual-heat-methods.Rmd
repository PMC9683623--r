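---
title: "Annual heat exposure indices and HSI rate models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annual heat exposure indices and HSI rate models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatrisk)
```

## The problem

Heat stress illnesses (HSI) — heat stroke, heat exhaustion, and related
diagnoses — are a preventable hazard for physically active outdoor
populations such as military trainees. Most exposure–response work on heat
operates at daily scale; `heatrisk` addresses the complementary
annual-scale question: how do *annual* summaries of outdoor heat relate to
*annual* HSI morbidity at a panel of installations, and what burden would a
sustained warming imply? The package implements the full chain: hourly
thermal indices from basic meteorology, a catalogue of annual exposure
indices, negative-binomial rate models with installation effects, and
block-bootstrap uncertainty, plus a synthetic-data module because the real
inputs (military health surveillance extracts, bulk gridded meteorology)
are restricted or too large to ship.

## Hourly thermal indices

The meteorological inputs per location-hour are: air temperature at 2 m,
specific humidity, surface pressure, wind speed, and downward shortwave
irradiance. From them the package derives:

**Relative humidity.** Vapour pressure from specific humidity via the
mixing-ratio identity $e = q\,p / (\epsilon + (1-\epsilon)q)$ with
$\epsilon = 0.622$, divided by a Magnus-form saturation pressure over
liquid water, $e_s = 610.94 \exp(17.625\,T/(243.04+T))$ Pa
(Alduchov–Eskridge coefficients). One saturation formula is used
everywhere in the package — relative humidity, wick evaporation, sky
emissivity — so moisture conversions invert each other exactly. Values are
clipped to $[0, 100]$ %.

**NWS heat index.** The operational National Weather Service procedure:
the simple Steadman-average formula is evaluated first and, when it
reaches 80 °F, replaced by the Rothfusz multiple regression with the
published low-humidity (RH < 13 %, 80–112 °F) and high-humidity
(RH > 85 %, 80–87 °F) adjustments. The 80 °F switchover on the simple
formula's value gives a continuous hand-off between branches.

**Outdoor WBGT (Liljegren energy balance).** The wet-bulb globe
temperature is the fixed combination
$\mathrm{WBGT} = 0.7\,T_{nwb} + 0.2\,T_g + 0.1\,T_{air}$. The globe
temperature $T_g$ solves the steady-state balance of a 0.05 m black globe
(emissivity 0.95, albedo 0.05): absorbed direct/diffuse shortwave plus sky
and ground thermal radiation against convective loss (Ranz–Marshall sphere
correlation) and longwave emission. The natural wet-bulb temperature
$T_{nwb}$ solves the wick balance (Bedingfield–Drew cylinder correlation,
wick diameter 7 mm, length 25.4 mm, albedo 0.4) in which evaporative
cooling offsets convective and radiative gains. Sky emissivity is
$0.575\,e^{0.143}$ (vapour pressure in hPa), ground emissivity 0.999,
surface albedo 0.45. Direct and diffuse irradiance are partitioned by the
clearness-index relation $f_{dir}=\exp(3-1.34 s^*-1.65/s^*)$ with
$s^* = S/(S_0\cos z)$ capped at 0.85, driven by a simple declination/
hour-angle solar position model; when site coordinates are absent all
solar is treated as diffuse and a warning is issued.

*Numerical choices.* Both balances are solved by a vectorised,
step-clamped Newton iteration on the (monotone) balance residual rather
than plain fixed-point substitution: the convective term makes the naive
fixed-point map unstable at high wind, while the Newton step converges in
a handful of iterations everywhere in the physical range. Tolerance
(default 1e-3 °C) and iteration cap (default 100) are exposed;
non-convergence is an error carrying the residual. Wind speeds below
0.1 m/s are floored there to keep the convective correlations defined.
Solvers are deterministic: identical inputs give bit-identical outputs.
In the no-sun, ventilated limit the natural wet bulb reproduces the
psychrometric wet bulb to well under 1 °C, which the test suite checks
against an independent psychrometric-equation oracle.

## Annual exposure indices

Hourly values are aggregated in °F (the conventional base unit of U.S.
heat-category guidance) into one row per location-day and index type
(temperature, heat index, WBGT): mean and maximum over the 24 hourly
values. The 24-hour mean (rather than, say, daytime-only means) is used so
that overnight values, which matter for recovery from heat exposure, enter
the exposure measure. Days with fewer than 90 % of hours (i.e. fewer than
22) are flagged incomplete and excluded from degree-valued statistics;
threshold hour counts use all available hours, because counts are sums
rather than means. The day boundary is local standard time with no
daylight-saving shifts.

The catalogue comprises 30 annual indices per location: for each of the
three index types, means of daily means and of daily maxima over the full
year and over the heat season (01 May–30 September inclusive); full-year
counts of hours strictly above fixed thresholds (temperature 90/100 °F,
heat index 90/105 °F, WBGT 85/90 °F); and two relative measures for both
windows — the mean daily anomaly and the count of days strictly more than
one standard deviation above the day-of-year norm. Anomalies are taken
against per-location, per-calendar-day climatologies (mean and sample SD
of the *daily mean* across the 1990–2019 baseline). Decisions in corner
cases: all threshold comparisons are strict (ties do not count); a
constant baseline (SD 0) reduces the exceedance rule to "strictly above
the mean"; February 29 forms its own climatology key populated only by
leap years; no smoothing is applied across adjacent calendar days — the
climatology is the raw day-of-year statistic.

## The rate model

Installation-year counts $y_{it}$ of one outcome type (ambulatory,
hospitalization, or reportable events; valid spans 1998–2018, 1991–2018,
1995–2018 respectively) are modelled as NB2 negative binomial
(variance $\mu + \alpha\mu^2$) with log link:

$$\log \mathbb{E}[y_{it}] = \log \mathrm{pop}_{it} + \beta_0 +
\beta_1 x_{it} + \gamma_i,$$

where $x_{it}$ is one annual index, $\gamma_i$ are installation fixed
effects with the reference installation (by convention the lowest-count
site) pinned at 0, and the log population offset converts the model to
rates. The rate ratio per increment $\Delta$ (1 °F for degree indices,
1 hour or 1 day for count indices) is $e^{\beta_1 \Delta}$.

The fitter alternates a fixed-dispersion GLM (weighted least squares with
the `MASS::negative.binomial` family, called through `stats::glm.fit` to
avoid per-replicate formula overhead) with maximum-likelihood dispersion
updates via `MASS::theta.ml` — the same alternation `MASS::glm.nb`
performs, and the tests verify agreement with `glm.nb` on full panels.
Underdispersed data drives $\theta$ to a cap of $10^5$, reproducing the
Poisson fit. Inside the bootstrap a replicate that fails to converge is
flagged and dropped rather than raised.

## Block bootstrap and intervals

Calendar year is a confounder here: access to care, coding practice, and
reporting systems trend over the same decades as the exposure. Including a
year term would absorb part of the heat signal (bias toward the null, a
hypothesis the simulation suite confirms); ignoring serial structure
entirely would bias away from the null. The package therefore controls
long-term trend with a block bootstrap over years: blocks of $L$
consecutive years (default 2), uniform random start, drawn with
replacement — $\lceil T/L\rceil$ blocks, so an odd-length series overshoots
by up to $L-1$ years and is kept untrimmed. The same resampled year
sequence is applied to every installation, preserving the cross-sectional
design, because the trend being controlled is shared across sites. Blocks
may start at any year (the moving-block convention) rather than on a
fixed partition. Each replicate refits the full model, dispersion
included.

Intervals are formed on the $\beta$ scale and exponentiated:

* **basic (empirical):** $(2\hat\beta - Q_{1-\alpha/2},\,
  2\hat\beta - Q_{\alpha/2})$;
* **percentile:** $(Q_{\alpha/2}, Q_{1-\alpha/2})$;
* **BCa:** bias correction $z_0$ from the share of replicates below
  $\hat\beta$ (exact ties split evenly, so a symmetric replicate set gives
  $z_0 = 0$), acceleration from leave-one-year-block-out jackknife
  skewness over the non-overlapping block partition.

All quantiles use the type-7 (linear interpolation) rule, consistently
across interval types. Reproducibility: replicate $r$ draws under seed
$\texttt{seed} + r$, so results are independent of evaluation order. With
$L = T$ every replicate equals the observed fit and all intervals collapse
onto the point estimate; with $L = 1$ the procedure reproduces an ordinary
year-resampling bootstrap replicate-for-replicate, both verified in tests.
The `sensitivity_suite()` runs the five standard variants (plain fit,
year-adjusted fit, and $L \in \{1,2,3\}$ bootstraps) under a shared seed.

Projected burden under a sustained shift of $\Delta$ exposure units is
$\mathrm{round}(\mathrm{baseline} \times RR^\Delta)$; with a baseline of
3,612 encounters and RR 1.16/°F, one degree of warming projects 4,190
(+578).

## The synthetic world

The generator is the package's test bed, not a weather or health model.
Hourly temperature is an annual mean plus a seasonal harmonic (peak day
196), a diurnal harmonic (peak 15:00), a linear decadal trend, and AR(1)
noise (coefficient 0.95, innovation SD 1.2 °F); humidity is back-computed
from a noisy target RH; solar follows the zenith curve scaled by
stochastic cloudiness; wind is log-normal. The default ten sites span
annual means of 56–69 °F, heat-season means of roughly 73–84 °F, and
populations of 2,000–45,000, echoing the magnitudes reported for CONUS
Army installations. Outcome panels are drawn from the NB2 model above,
with site effects spanning rates of roughly 1.5–27 per 1,000 and an
all-cause denominator keeping HSI burden in the plausible 0.01–20 % range.

What it does **not** emulate: spatial correlation between sites, synoptic
heat-wave structure, demographic covariates, or reporting-system shifts.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and that the inference machinery is calibrated under the stated
generating model — not that the published effect estimates are recoverable
from real data, which remain restricted.

`recovery_experiment()` regenerates exposure at the *annual* scale
(`gen_annual_exposure`: the heat-season level implied by the site
configuration — annual mean plus 0.739 of the seasonal amplitude, the
harmonic's May–September average — plus trend and year noise of 1.5 °F,
matching the year-to-year SDs of published annual index summaries) rather
than re-running the hourly pipeline inside every simulation. Regression
inference conditions on the covariates, so recovery and coverage are
meaningfully assessed with exposure regenerated cheaply; the
hourly-to-annual path is exercised end-to-end by its own tests and by
`run_pipeline()`. Simulation $s$ uses seed stream
$\texttt{seed} + 100000\,s$ so bootstrap streams never collide across
simulations. At the default validation scale (10 sites, 28 years, 200
simulations, 500 replicates) the mean recovered $\beta_1$ sits within a
few percent of $\log 1.15$ and basic-interval coverage falls in the high
0.80s to mid 0.90s — the modest undercoverage expected when 14 resampled
blocks must stand in for the full sampling variation.

## Interfaces and scope

The package's interface is its functions (with `run_pipeline()` tying the
stages together over CSV inputs and a YAML-able configuration); it is an
analysis library rather than a shell tool, so no command-line binary is
shipped. Tabular schemas are documented on `read_hourly_csv()` and
`read_panel_csv()`; the run log records every design parameter actually
used (quantile rule, block length, tolerances, seed, configuration hash)
so runs are auditable and re-runs byte-identical.

Out of scope by design: indoor/shaded WBGT and other comfort indices
(UTCI); gridded-data retrieval and regridding; ICD code extraction;
installation-specific interaction rate ratios; lagged or nonlinear
daily-scale exposure models; multiple-testing adjustment across the 30
indices (none is applied, matching standard practice for this design).

## Known limitations

* The solar position model is a simple declination/hour-angle
  approximation (no equation of time, refraction, or ephemeris); adequate
  for beam/diffuse partitioning, not for precise sunrise timing.
* The Liljegren wick and globe constants are fixed at their reference
  values; instrument variations are not modelled.
* Annual counts cannot distinguish incident cases from follow-up
  encounters; rates are burden-oriented by construction.
* Block-bootstrap intervals mildly undercover with short panels (a
  14-block resample of 28 years); the BCa option corrects skewness, not
  this effective-sample limitation.
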