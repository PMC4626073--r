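#' Scenario configuration for the synthetic warm-season generator
#'
#' Describes a synthetic two-season ED surveillance world with the statistical
#' structure the analysis pipeline assumes: a warm-season apparent-temperature
#' trajectory (seasonal sinusoid plus AR(1) noise), PM10 with a configurable
#' correlation with temperature, and conditionally independent Poisson visit
#' counts per day and age class driven by a log-linear model with day-of-week
#' and month seasonality, a linear PM10 term and a piecewise-linear (hinge)
#' heat effect above a known threshold. High-priority ("no-white-tag") counts
#' are a binomial thinning of the visits.
#'
#' Defaults are calibrated to a mid-sized Northern-Italian ED: a mild first
#' season (mean apparent temperature 24.7 degC) and a hot second one
#' (27.3 degC), around 140 visits/day across ages split 15% / 51% / 34% over
#' 0-14 / 15-64 / 65+, a heat threshold of 28.8 degC with above-threshold
#' percent changes of 6.8 / 5.74 / 3.7 per degC by age, and white-tag
#' (lowest-priority) fractions of 0.50 / 0.19 / 0.09.
#'
#' @param n_seasons number of warm seasons (default 2).
#' @param days_per_season days per season; 124 covers 15 May - 15 September.
#' @param start_year first season's calendar year (seasons start 15 May).
#' @param season_mean_at per-season mean apparent temperature targets, degC.
#' @param at_amplitude seasonal shape amplitude, degC.
#' @param at_plateau_frac fraction of the season spent on the mid-summer
#'   plateau (the seasonal shape is a sinusoid clipped at its top, emulating
#'   the sustained July-August heat of a hot year; 0 = pure sinusoid).
#' @param at_noise_sd,at_ar AR(1) noise SD (degC) and lag-1 autocorrelation;
#'   the noise is centred within each season, so the season mean equals its
#'   target exactly.
#' @param pm10_mean per-season PM10 means, micrograms/m3.
#' @param pm10_sd PM10 day-to-day SD.
#' @param pm10_temp_cor correlation between PM10 and apparent temperature.
#' @param base_daily_visits expected all-ages visits/day at reference
#'   conditions (exposure at `ref_temp`, reference weekday/month, mean PM10).
#' @param age_share share of visits by age class (sums to 1).
#' @param threshold true heat threshold h*, degC.
#' @param slope_above true above-threshold extra log-slopes per age class
#'   (per degC; in addition to `slope_below`).
#' @param slope_below true below-threshold log-slope per degC.
#' @param ref_temp centring temperature for the below-threshold term, degC.
#' @param dow_effects log-scale day-of-week effects, Sunday first (length 7).
#' @param month_effects log-scale month effects, named by month number.
#' @param pm10_effect log-scale effect per microgram/m3 of PM10.
#' @param white_tag_frac fraction of visits with a white (lowest-priority)
#'   tag, per age class; priority counts are Binomial(visits, 1 - fraction).
#' @param ar_count_noise SD of an optional AR(1) log-rate noise shared within
#'   a day (0 = conditionally independent Poisson, the default).
#' @param differential_thinning additive change in the white-tag fraction per
#'   degC above threshold (0 by default: tag status independent of heat).
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_seasons = 2L,
                            days_per_season = 124L,
                            start_year = 2011L,
                            season_mean_at = c(24.7, 27.3),
                            at_amplitude = 11,
                            at_plateau_frac = 0.45,
                            at_noise_sd = 1.8,
                            at_ar = 0.7,
                            pm10_mean = c(26.5, 24.3),
                            pm10_sd = 8,
                            pm10_temp_cor = 0.3,
                            base_daily_visits = 140,
                            age_share = c(`0-14` = 0.15, `15-64` = 0.51,
                                          `65+` = 0.34),
                            threshold = 28.8,
                            slope_above = c(`0-14` = log(1.0680),
                                            `15-64` = log(1.0574),
                                            `65+` = log(1.0370)),
                            slope_below = 0.005,
                            ref_temp = 20,
                            dow_effects = c(0.06, 0, -0.02, -0.02, -0.01, 0, 0.04),
                            month_effects = c(`5` = 0, `6` = 0.02, `7` = 0.03,
                                              `8` = 0.01, `9` = -0.02),
                            pm10_effect = 5e-4,
                            white_tag_frac = c(`0-14` = 0.50, `15-64` = 0.19,
                                               `65+` = 0.09),
                            ar_count_noise = 0,
                            differential_thinning = 0) {
  stopifnot(n_seasons >= 1L, days_per_season >= 8L,
            all(age_share > 0), abs(sum(age_share) - 1) < 1e-8,
            all(white_tag_frac >= 0), all(white_tag_frac <= 1),
            base_daily_visits > 0, length(dow_effects) == 7L)
  season_mean_at <- rep_len(season_mean_at, n_seasons)
  pm10_mean <- rep_len(pm10_mean, n_seasons)
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate warm-season apparent temperature and PM10
#'
#' Apparent temperature follows a clipped half-sine seasonal profile (rising
#' through late May and June, a sustained mid-summer plateau covering
#' `at_plateau_frac` of the season, falling through September) plus AR(1)
#' noise centred within the season, so each season's mean equals its
#' configured target exactly. PM10 is generated with the configured mean and
#' a configured correlation with the temperature anomaly, floored at
#' 1 microgram/m3.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer seed.
#' @return data.frame with one row per day: `date`, `season` (year), `day`
#'   (1-based within season), `tempapp`, `pm10_mean`.
#' @export
simulate_weather <- function(config = scenario_config(), seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", config$n_seasons)
  nd <- config$days_per_season
  for (s in seq_len(config$n_seasons)) {
    year <- config$start_year + s - 1L
    dates <- as.Date(sprintf("%d-05-15", year)) + 0:(nd - 1L)
    shape <- sin(pi * (seq_len(nd) - 1) / (nd - 1))
    fp <- config$at_plateau_frac
    if (fp > 0) {
      top <- sin(pi * (1 - fp) / 2)  # clip level: plateau over fraction fp
      shape <- pmin(shape / top, 1)
    }
    # AR(1) noise, stationary start, centred within the season
    e <- numeric(nd)
    if (config$at_noise_sd > 0) {
      innov_sd <- config$at_noise_sd * sqrt(1 - config$at_ar^2)
      e[1L] <- rnorm(1L, 0, config$at_noise_sd)
      if (nd > 1L)
        for (t in 2:nd) e[t] <- config$at_ar * e[t - 1L] + rnorm(1L, 0, innov_sd)
      e <- e - mean(e)
    }
    level <- config$season_mean_at[s] - config$at_amplitude * mean(shape)
    at <- level + config$at_amplitude * shape + e
    z <- if (stats::sd(at) > 0) (at - mean(at)) / stats::sd(at) else rep(0, nd)
    rho <- config$pm10_temp_cor
    pm <- config$pm10_mean[s] + config$pm10_sd *
      (rho * z + sqrt(max(0, 1 - rho^2)) * rnorm(nd))
    pm <- pmax(pm, 1)
    out[[s]] <- data.frame(date = dates, season = year, day = seq_len(nd),
                           tempapp = at, pm10_mean = pm)
  }
  do.call(rbind, out)
}

# lag-window means where the first days of a season use the partial window
# (generation needs an exposure for every day; model fitting still drops the
# first days, whose full-window value is NA)
partial_window_mean <- function(x, maxlag) {
  n <- length(x)
  vapply(seq_len(n), function(t) mean(x[max(1L, t - maxlag):t]), numeric(1L))
}

#' Simulate daily visit counts from a weather series
#'
#' Per day t and age class a, visits are Poisson with
#' \deqn{\log \mu_{at} = \log(\mathrm{base}_a) + \mathrm{dow}_t +
#'   \mathrm{month}_t + \gamma (PM10_t - \bar{PM10}) +
#'   \beta_0 (T_t - T_{ref}) + b_a (T_t - h^*)_+,}
#' where T_t is the lag 0-3 mean apparent temperature (the model's exposure;
#' the first three days of a season use the partial window). High-priority
#' counts are a binomial thinning of visits with probability one minus the
#' age-specific white-tag fraction. The true per-day expected attributable
#' visits \eqn{\mu_{at}(1 - e^{-b_a (T_t - h^*)_+})} are recorded as a hidden
#' truth table for oracle checks.
#'
#' @param weather a [simulate_weather()] result.
#' @param config the same [scenario_config()].
#' @param seed optional integer seed (set it here when calling the two stages
#'   separately; [simulate_dataset()] seeds once for both).
#' @return long-format data.frame, 3 rows per day (one per age class), with
#'   the deposited-file vocabulary: `date`, `season`, `day`, `age_class`,
#'   `visits`, `priority`, `tempapp`, `tempapp_l1`..`tempapp_l3`,
#'   `tempapp_l03`, `tempapp_l05`, `pm10_mean`. The hidden truth (per-row
#'   `mu`, `expected_av`, `expected_av_priority` and the generating
#'   parameters) is in `attr(, "truth")`.
#' @export
simulate_counts <- function(weather, config = scenario_config(), seed = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            all(c("date", "season", "tempapp", "pm10_mean") %in% names(weather)))
  if (!is.null(seed)) set.seed(seed)
  ages <- names(config$age_share)
  rows <- vector("list", config$n_seasons)
  pm_center <- mean(weather$pm10_mean)
  truth_rows <- vector("list", config$n_seasons)

  for (s in seq_len(config$n_seasons)) {
    w <- weather[weather$season == sort(unique(weather$season))[s], ]
    nd <- nrow(w)
    at <- w$tempapp
    texp <- partial_window_mean(at, 3L)          # lag 0-3 exposure
    dow <- as.integer(format(w$date, "%w")) + 1L # Sunday = 1
    mon <- format(w$date, "%m")
    mkey <- as.character(as.integer(mon))
    meff <- config$month_effects[mkey]
    meff[is.na(meff)] <- 0
    day_noise <- numeric(nd)
    if (config$ar_count_noise > 0) {
      day_noise[1L] <- rnorm(1L, 0, config$ar_count_noise)
      if (nd > 1L)
        for (t in 2:nd)
          day_noise[t] <- 0.5 * day_noise[t - 1L] +
            rnorm(1L, 0, config$ar_count_noise * sqrt(0.75))
    }
    hinge <- pmax(texp - config$threshold, 0)

    per_age <- lapply(ages, function(a) {
      base <- config$base_daily_visits * config$age_share[[a]]
      log_mu <- log(base) + config$dow_effects[dow] + meff +
        config$pm10_effect * (w$pm10_mean - pm_center) +
        config$slope_below * (texp - config$ref_temp) +
        config$slope_above[[a]] * hinge + day_noise
      if (any(log_mu > 20)) stop("simulated Poisson rate overflow")
      mu <- exp(log_mu)
      visits <- rpois(nd, mu)
      wt <- config$white_tag_frac[[a]] -
        config$differential_thinning * hinge
      wt <- pmin(pmax(wt, 0), 1)
      priority <- rbinom(nd, visits, 1 - wt)
      av <- mu * (1 - exp(-config$slope_above[[a]] * hinge))
      list(
        data = data.frame(
          date = w$date, season = w$season, day = w$day, age_class = a,
          visits = visits, priority = priority,
          tempapp = at,
          tempapp_l1 = shift_lag(at, 1L),
          tempapp_l2 = shift_lag(at, 2L),
          tempapp_l3 = shift_lag(at, 3L),
          tempapp_l03 = lag_window_mean(at, 0:3),
          tempapp_l05 = lag_window_mean(at, 0:5),
          pm10_mean = w$pm10_mean),
        truth = data.frame(
          date = w$date, season = w$season, age_class = a,
          exposure = texp, mu = mu,
          expected_av = av,
          expected_av_priority = av * (1 - wt))
      )
    })
    rows[[s]] <- do.call(rbind, lapply(per_age, `[[`, "data"))
    truth_rows[[s]] <- do.call(rbind, lapply(per_age, `[[`, "truth"))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$date, factor(out$age_class, levels = ages)), ]
  rownames(out) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  attr(out, "truth") <- list(table = truth, config = config)
  out
}

#' Simulate a complete synthetic dataset (weather + counts)
#'
#' Convenience wrapper: seeds once, simulates the weather, then the counts,
#' so the same seed always yields a byte-identical dataset.
#'
#' @inheritParams simulate_counts
#' @return see [simulate_counts()].
#' @export
simulate_dataset <- function(config = scenario_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_counts(simulate_weather(config), config)
}

#' True expected attributable visits of a synthetic dataset
#'
#' Reads the hidden truth table of a [simulate_counts()] dataset and returns
#' the deterministic expected attributable visits
#' \eqn{E[AV] = \mu_t (1 - e^{-b (T_t - h^*)_+})}, per day or summed, for the
#' chosen outcome. This is the oracle the attribution machinery is checked
#' against.
#'
#' @param dataset a synthetic dataset carrying a `"truth"` attribute.
#' @param outcome `"visits"` or `"priority"`.
#' @param by `"day"` (per day and age row), `"season"`, `"age"` or `"total"`.
#' @return data.frame (for `"day"`, `"season"`, `"age"`) or single number.
#' @export
true_attributable <- function(dataset, outcome = c("visits", "priority"),
                              by = c("total", "season", "age", "day")) {
  outcome <- match.arg(outcome)
  by <- match.arg(by)
  tr <- attr(dataset, "truth")
  if (is.null(tr)) stop("dataset carries no hidden truth record")
  tab <- tr$table
  col <- if (outcome == "visits") "expected_av" else "expected_av_priority"
  switch(by,
    total = sum(tab[[col]]),
    day = tab[c("date", "season", "age_class", "exposure", col)],
    season = stats::aggregate(tab[[col]],
                              by = list(season = tab$season), sum),
    age = stats::aggregate(tab[[col]],
                           by = list(age_class = tab$age_class), sum))
}
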