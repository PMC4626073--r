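---
title: "Modelling heat-attributable emergency department visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heat-attributable emergency department visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatav)
```

## The problem

During the warm season, days of intense heat are followed within hours to a
few days by measurable surges in emergency department (ED) activity. For a
surveillance system the questions are: above which apparent temperature does
the surge begin, how steep is it, who is affected (children, adults, the
elderly), and how many visits in a season can be attributed to heat. `heatav`
implements the complete chain from raw daily weather and visit counts to
those answers, with a synthetic-data generator that makes every stage
testable against known ground truth.

## Exposure

The exposure metric is the daily mean **apparent temperature** (AT), a
thermal-discomfort index combining air temperature $T$ and dew point $T_d$
(both °C):

$$AT = -2.653 + 0.994\,T + 0.0153\,T_d^2 .$$

The source analyses this package follows cite this index without printing a
formula; we adopt the dew-point form above, which is the standard choice in
the heat-epidemiology literature (the coefficients are exposed in
`at_coefficients()` so a variant — e.g. one including wind — can be swapped
in; thresholds in °C can shift slightly between variants).

Short-term heat effects are captured with lag-window means: lag 0 (the
current day), lag 0–3 (mean of the current and previous three days; the
primary definition, sensitive to short but possibly delayed effects) and lag
0–5. Three housekeeping rules matter:

* isolated missing AT days are filled with the mean of the adjacent days
  (`impute_adjacent_mean()`); consecutive or boundary gaps are an error, not
  silently patched;
* imputation happens **before** lagging, so lagged values never mix imputed
  and raw values inconsistently;
* lag windows never cross the winter gap between warm seasons — days whose
  window reaches before a season's start are dropped from fitting rather
  than back-filled.

PM10 is the arithmetic mean of the reporting monitoring stations, with a
single-station fallback and an error when no station reports.

## The heat-response model

Daily counts $Y_t$ (all visits or the high-priority "no-white-tag" subset,
pooled or by age class) are modelled as Poisson with log link:

$$\log E[Y_t] = \alpha + \beta_1 T_t + \beta_2 (T_t - h)_+ + \gamma\,
\mathrm{PM10}_t + \mathrm{dow}_t + \mathrm{month}_t ,$$

where $T_t$ is the lag-window mean AT. The hinge term $(T_t-h)_+$ makes the
two linear segments join continuously at the threshold $h$ (the "joined two
lines" form); the slope above the threshold is $b = \beta_1+\beta_2$,
reported as a percent change per 1 °C, $100(e^b-1)$. Exploration of the
shape uses a cubic regression spline with 4 df instead of the hinge
(`fit_spline_model()`; 3 and 5 df supported as a robustness check).

### Threshold estimation and its uncertainty

$h$ is estimated by profile maximum likelihood over a fixed grid: 0.05 °C
steps between the 5th and 95th percentiles of the exposure, each candidate
fitted by IRLS (relative log-likelihood tolerance $10^{-8}$, max 100
iterations, non-convergence an error), ties broken toward the lower
candidate. 0.05 °C resolution is needed because seasonal datasets of this
size can pin the threshold to about ±0.1 °C. The sweep stays cheap because
only the hinge column of the design matrix changes between candidates and
each fit warm-starts from the previous solution.

The 90% interval for $h$ is the set of candidates whose profile deviance is
within the $\chi^2_1$ quantile of the minimum, with each endpoint located
by linear interpolation of the profile between the last qualifying
candidate and its neighbour — the deviance crosses the cut strictly between
grid points, and clipping the interval to qualifying candidates makes it
systematically narrow (measured coverage dropped from ≈ 89% to ≈ 82% without
the interpolation, while the likelihood-ratio statistic at the true
threshold is, if anything, lighter-tailed than $\chi^2_1$ in this design). When that set touches the
grid boundary the threshold is considered unidentified: the fit carries a
`boundary` flag, a nearly-flat profile raises a warning, and the
normal-approximation SE (interval width divided by $2z_{0.95}$), which the
attribution sampler needs, is withheld as `NA` rather than fabricated.

### Age interaction

Whether the above-threshold slope differs by age is tested in a single
model over the three age classes with age-specific intercepts, shared
PM10/day-of-week/month effects and a shared below-threshold slope; only the
above-threshold slopes interact with age, and the threshold is fixed at the
pooled estimate. That structure gives exactly two extra parameters, hence a
2-df likelihood-ratio chi-squared test (Wald available via `test = "wald"`).
Stratified per-age fits are also supported; the interaction form is what the
reported per-age effects use.

## Attribution

Sampling variability of $(b, h)$ is propagated by Monte Carlo: `n = 10000`
pairs $(b_i, h_i)$ drawn from independent normals centred at the estimates
with their SEs as spreads. For each draw and day,

$$AV_{it} = Y_t - Y_t\exp[-b_i(T_t - h_i)] \ \text{if } T_t > h_i, \qquad
AV_{it} = 0 \ \text{if } T_t \le h_i .$$

Per-draw totals over a season (or the study period) give a distribution
summarised by its median and 10th/90th percentiles. Numerical choices:

* negative sampled slopes contribute negative $AV$ and are **kept** so the
  sampling distribution is not distorted (`truncate_negative = TRUE` exists
  for comparison);
* percentiles are empirical quantiles by linear interpolation of order
  statistics (R's type 7), stated here because conventions differ;
* rounding to report precision happens only at the report layer, never
  internally;
* age-specific attribution uses the age-specific interaction slopes with the
  common pooled high-priority threshold and its SE, matching the one-threshold
  reporting convention of the source analysis.

Derived burden measures: the **attributable community rate** (ACR),
$10000 \times \text{median total} / \text{inhabitants}$; the expected
attributable visits per day above the threshold (median seasonal total
divided by the number of days above; the variant that averages the per-day
medians over those days is also reported, because the two differ slightly
and published tables do not say which was used); and the maximum over days
of the per-day median $AV$.

## The synthetic world

`scenario_config()` states a two-season world calibrated to a mid-sized
Northern-Italian ED:

* **Weather.** AT follows a clipped half-sine: rising through late May and
  June, a plateau covering 45% of the season, falling through September,
  with amplitude 11 °C and AR(1) noise (SD 1.8 °C, lag-1 correlation 0.7)
  centred within each season so the season mean hits its target (24.7 °C in
  the mild year, 27.3 °C in the hot year) exactly. A plain sinusoid cannot
  reproduce a documented hot summer in which roughly half the days sit above
  a 28.8 °C threshold while the season mean is only 27.3 °C; the plateau
  does, yielding ≈ 13 mild-season and ≈ 58 hot-season days above threshold
  (the surveillance data this emulates recorded 17 and 57). PM10 is drawn
  with configurable mean (26.5 / 24.3 µg/m³) and correlation with the
  temperature anomaly (default 0.3, summer-typical).
* **Counts.** Poisson per day × age class, log-rate = baseline (140
  visits/day across ages, split 15% / 51% / 34%) + day-of-week + month
  effects + PM10 term + below-threshold slope (0.005/°C) + age-specific
  hinge slopes above $h^\* = 28.8$ °C (log(1.068), log(1.0574), log(1.037):
  the published per-age high-priority percent changes). The below-threshold
  term uses the same lag 0–3 exposure as the hinge, so the fitted model is
  correctly specified; the first three days of a season use the partial
  window for generation only. High-priority counts are binomial thinnings
  with white-tag fractions 0.50 / 0.19 / 0.09, independent of temperature by
  default (`differential_thinning` mimics a children's signal visible only
  in high-priority visits).
* **Truth.** Every dataset carries a hidden record of $\mu_{at}$ and the
  exact expected attributable visits, the oracle for round-trip tests.

What a green test does *not* establish: the generator has no residual
autocorrelation by default (counts are conditionally independent given
covariates, matching the GLM; an AR option exists), no heat-wave episode
effects, no reporting artefacts, and weather is a stylised shape — so green
recovery tests validate the estimation machinery under the model's own
assumptions, not robustness to their violation.

## Design choices where the design was open

* **Season length**: 15 May–15 September inclusive is 124 days; the
  two-season deposited layout (248 days, 3 rows per day) is reconstructed on
  that basis, day 1 = 15 May, with day-of-week taken from the true calendar.
* **No year indicator** by default (the source model never mentions one);
  available in the configuration.
* **No overdispersion correction**: plain Poisson is the stated model; GEE
  sensitivity refits are out of scope because no numbers exist to verify
  them against.
* **Interaction test**: "chi-square test" is implemented as the
  likelihood-ratio test, with Wald as an option.
* **Stata ingestion**: no Stata reader is available in the supported
  dependency set, so the deposited dialect is accepted as a CSV export with
  the canonical variable vocabulary (`visits`, `priority`, `tempapp`,
  `tempapp_l1..l3`, `tempapp_l03`, `PM10_mean`).

## Limitations

Thresholds are only identified when enough days lie on both sides; the
package flags, rather than hides, weak identification. The normal
approximation for the threshold's sampling distribution (used by the
Monte Carlo) is crude near identification boundaries. Attribution assumes
the fitted model is the data-generating process on the attribution days;
with an estimated threshold the Monte Carlo median is typically a few
percent above the deterministic plug-in total (threshold uncertainty enters
asymmetrically), which the recovery tests bound at 15% relative error. No
causal claims beyond the regression adjustment are made.
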