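# heatav

Heat-attributable emergency department (ED) visits from warm-season daily
counts.

## What problem this solves

Public-health surveillance teams need to know, from a couple of summers of
daily ED counts and weather, (i) the apparent-temperature threshold above
which visits start climbing, (ii) how steep the climb is — overall and by
age class — and (iii) how many visits a given summer's heat actually caused.
`heatav` implements that pipeline end to end for daily warm-season
(15 May – 15 September) surveillance data:

* **Exposure**: daily mean apparent temperature
  `AT = −2.653 + 0.994·T + 0.0153·Td²` from temperature and dew point,
  adjacent-day imputation of isolated gaps, station-averaged PM10, and
  lag-window means (lag 0, 0–3, 0–5) that never cross the winter gap.
* **Heat-response regression**: Poisson GLM
  `log E[Y_t] = α + β₁T_t + β₂(T_t − h)₊ + γ·PM10_t + dow_t + month_t`,
  with the threshold `h` estimated by profile maximum likelihood on a
  0.05 °C grid and the above-threshold slope `b = β₁ + β₂` reported as a
  percent change `100(e^b − 1)` per 1 °C. Exploratory cubic-spline fits
  (3–5 df) and a 2-df age-interaction likelihood-ratio test included.
* **Attribution**: Monte Carlo over 10000 independent normal draws
  `(b_i, h_i)`; per day,
  `AV_it = Y_t − Y_t·exp[−b_i(T_t − h_i)]` when `T_t > h_i`, else 0; totals
  summarised by median and 10th/90th percentiles, plus attributable
  community rates (per 10000 inhabitants), per-day burdens and maxima.
* **Synthetic data**: a calibrated generator for the same layout (two
  seasons × 124 days × 3 age classes, Poisson counts with seasonality, PM10
  and a hinge heat effect, priority counts by binomial thinning) with the
  exact expected attributable burden recorded as hidden truth.

See `vignettes/heat-attributable-visits.Rmd` for the model, the numerical
choices and the generator's assumptions.

## Worked example

```r
library(heatav)
ds  <- simulate_dataset(scenario_config(), seed = 2026)   # 744 rows, 248 days
fit <- fit_segmented(ds, outcome = "priority", age = "all")
fit
#> Segmented Poisson heat-response fit
#>   outcome: priority, age: all, lag: 0-3 (242 days)
#>   threshold: 28.77 degC  90% CI (28.12, 29.03)
#>   % change above threshold per 1 degC: 6.93 (5.64, 8.24)

rep <- run_pipeline(ds, analysis_config(n_draws = 10000, seed = 2026))
rep
#> Heat impact report (lag 0-3, 10000 draws, seed 2026)
#>   visits   threshold 28.42 degC, % change 6.43 (5.39, 7.47)
#>   priority threshold 28.77 degC, % change 6.93 (5.64, 8.24)
#>   attributable high-priority visits (overall):
#>     all       849 [612, 1142]
#>     0-14      104 [66, 150]
#>     15-64     438 [308, 602]
#>     65+       303 [207, 423]
```

Reading the output: the generator's true threshold is 28.8 °C and its true
high-priority percent changes are 6.8 / 5.74 / 3.7 by age; the fit localises
the threshold at 28.77 °C and attributes a median 849 high-priority visits
(10th–90th percentile 615–1138) to above-threshold heat over the two
seasons, concentrated in the hot second season (attributable community rate
24.3 per 10000 inhabitants vs 2.4 in the mild one; 65 vs 22 days above
threshold). `true_attributable(ds, "priority")` returns the generator's
exact expected burden for comparison.

A real dataset in the archived study's variable vocabulary (`visits`,
`priority`, `tempapp`, `tempapp_l1..l3`, `tempapp_l03`, `PM10_mean`; 3 rows
per day) is analysed the same way via
`read_dataset(path, dialect = "deposited")` or
`reproduce_study(path)`.

Command line:

```sh
Rscript -e 'heatav::heatav_cli()' simulate --seed 1 --out sim.csv
Rscript -e 'heatav::heatav_cli()' report --input sim.csv --draws 10000 --out out/
```

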