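#' Resident population of the study area by age class
#'
#' Inhabitants of the Verona study area at the beginning of 2011, by age
#' class, used as denominators for attributable community rates.
#'
#' @return named integer vector (`0-14`, `15-64`, `65+`) with a `total`
#'   attribute of 317658.
#' @export
verona_population <- function() {
  p <- c(`0-14` = 42493L, `15-64` = 201624L, `65+` = 73541L)
  attr(p, "total") <- sum(p)
  p
}

#' Published reference values of the original Verona warm-season analysis
#'
#' Summary numbers printed by the original Verona ED heat-impact analysis
#' (2011-2012 warm seasons), kept here as inputs for worked-example
#' arithmetic and cross-checks: visit counts and percent changes by outcome
#' and age, Monte Carlo attributable-visit medians and percentile bands by
#' year and age, and community-rate / per-day burden summaries.
#'
#' @return a list of data.frames: `effects` (visit counts, percent changes and
#'   90% CIs at lag 0-3), `attributable` (medians and 10th/90th percentiles
#'   of attributable no-white-tag visits by year), `burden` (population, ACR,
#'   expected attributable visits per day above threshold, maximum daily),
#'   and scalars `threshold_all`, `threshold_priority`, `days_above`
#'   (per year), `season_mean_at` (per year).
#' @export
verona_published <- function() {
  list(
    effects = data.frame(
      outcome = rep(c("visits", "priority"), each = 4L),
      age = rep(c("all", "0-14", "15-64", "65+"), 2L),
      n_visits = c(37072, 5738, 18827, 12507, 29445, 2895, 15213, 11337),
      pct_change = c(3.75, 2.31, 4.53, 3.22, 5.06, 6.80, 5.74, 3.70),
      lower = c(3.01, 0.50, 3.60, 2.14, 4.19, 4.17, 4.641, 2.47),
      upper = c(4.49, 4.15, 5.46, 4.32, 5.95, 9.49, 6.84, 4.93)),
    interaction = data.frame(
      outcome = c("visits", "priority"),
      chi_square = c(5.95, 7.33), p_value = c(0.051, 0.026)),
    attributable = data.frame(
      age = c("all", "0-14", "15-64", "65+"),
      median_2011 = c(134, 11, 76, 46),
      p10_2011 = c(69, 5, 39, 23), p90_2011 = c(228, 21, 130, 80),
      median_2012 = c(1042, 143, 615, 280),
      p10_2012 = c(690, 89, 403, 168), p90_2012 = c(1426, 206, 844, 413),
      median_total = c(1177, 155, 692, 326),
      p10_total = c(759, 95, 442, 191), p90_total = c(1652, 227, 974, 493)),
    burden = data.frame(
      age = c("all", "0-14", "15-64", "65+"),
      population = c(317658, 42493, 201624, 73541),
      acr_2011 = c(4.2, 2.7, 3.8, 6.2),
      acr_2012 = c(32.8, 33.7, 30.5, 38.1),
      per_day_2011 = c(7.8, 0.6, 4.5, 2.7),
      per_day_2012 = c(18.2, 2.5, 10.8, 4.9),
      max_daily_2011 = c(19.8, 1.6, 12.3, 6.1),
      max_daily_2012 = c(39.9, 7.2, 25.2, 10.6)),
    threshold_all = 28.6,
    threshold_all_ci = c(28.5, 28.7),
    threshold_priority = 28.81,
    threshold_priority_ci = c(28.7, 28.9),
    days_above = c(`2011` = 17L, `2012` = 57L),
    season_mean_at = c(`2011` = 24.7, `2012` = 27.3),
    season_mean_pm10 = c(`2011` = 26.5, `2012` = 24.3)
  )
}

DEPOSITED_COLS <- c("visits", "priority", "tempapp", "tempapp_l1",
                    "tempapp_l2", "tempapp_l3", "tempapp_l03", "PM10_mean")

#' Read a daily ED visit dataset
#'
#' Two dialects are supported. The `"deposited"` dialect mirrors the archived
#' study file (a CSV export of it): 3 rows per day in age-class order 0-14,
#' 15-64, 65+, with variables `visits`, `priority`, `tempapp`,
#' `tempapp_l1`..`tempapp_l3`, `tempapp_l03`, `PM10_mean` and no explicit
#' dates; calendar dates are reconstructed assigning day 1 of each 124-day
#' season to 15 May (2011 for the first season, and so on), and day of week
#' comes from those dates — this reconstruction is noted in the reader log.
#' The `"tidy"` dialect is the package's own long format with explicit `date`
#' and `age_class` columns. Validation: counts are non-negative integers,
#' `priority <= visits` row by row, exactly 3 rows per day.
#'
#' @param path CSV file path.
#' @param dialect `"deposited"` or `"tidy"`.
#' @param start_year first season year for date reconstruction (deposited
#'   dialect).
#' @param days_per_season season length for date reconstruction (default 124,
#'   i.e. 15 May - 15 September inclusive).
#' @return validated long-format data.frame (columns as in
#'   [simulate_counts()]); the reader log is in `attr(, "log")`.
#' @export
read_dataset <- function(path, dialect = c("tidy", "deposited"),
                         start_year = 2011L, days_per_season = 124L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  log <- character(0)

  if (dialect == "deposited") {
    miss <- setdiff(DEPOSITED_COLS, names(d))
    if (length(miss)) stop("missing required columns: ",
                           paste(miss, collapse = ", "))
    if (nrow(d) %% 3L != 0L)
      stop("deposited dialect needs 3 rows per day; got ", nrow(d), " rows")
    n_days <- nrow(d) %/% 3L
    if (!"age_class" %in% names(d)) {
      d$age_class <- rep(AGE_LEVELS, times = n_days)
      log <- c(log, "age_class absent: assumed repeating order 0-14, 15-64, 65+")
    }
    day_idx <- rep(seq_len(n_days), each = 3L)
    same <- tapply(d$tempapp, day_idx, function(x) length(unique(x)) == 1L)
    if (!all(same))
      stop("rows within day ", which(!same)[1L],
           " disagree on tempapp: not 3 rows per day?")
    if (n_days %% days_per_season != 0L)
      stop("cannot split ", n_days, " days into seasons of ", days_per_season)
    n_seasons <- n_days %/% days_per_season
    season_of_day <- rep(seq_len(n_seasons), each = days_per_season)
    day_in_season <- ((seq_len(n_days) - 1L) %% days_per_season) + 1L
    dates_per_day <- as.Date(sprintf("%d-05-15",
                                     start_year + season_of_day - 1L)) +
      (day_in_season - 1L)
    d$date <- dates_per_day[day_idx]
    d$season <- as.integer(format(d$date, "%Y"))
    d$day <- day_in_season[day_idx]
    names(d)[names(d) == "PM10_mean"] <- "pm10_mean"
    log <- c(log, sprintf(
      "dates reconstructed: day 1 of each %d-day season = 15 May, seasons %s",
      days_per_season,
      paste(start_year:(start_year + n_seasons - 1L), collapse = ", ")))
  } else {
    need <- c("date", "age_class", "visits", "priority", "tempapp", "pm10_mean")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("missing required columns: ",
                           paste(miss, collapse = ", "))
    d$date <- as.Date(d$date)
    if (!"season" %in% names(d)) d$season <- as.integer(format(d$date, "%Y"))
  }

  for (col in c("visits", "priority")) {
    v <- d[[col]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) stop("column '", col,
                          "' is not a non-negative integer at row ", bad[1L])
  }
  bad <- which(d$priority > d$visits)
  if (length(bad))
    stop("priority exceeds visits at row ", bad[1L],
         " (", format(d$date[bad[1L]]), ", age ", d$age_class[bad[1L]], ")")
  tab <- table(d$date)
  if (any(tab != 3L))
    stop("expected 3 rows per day; day ", names(tab)[tab != 3L][1L],
         " has ", tab[tab != 3L][1L])

  if (!"tempapp_l03" %in% names(d)) {
    per_day <- d[!duplicated(d$date), c("date", "season", "tempapp")]
    per_day <- per_day[order(per_day$date), ]
    lagged <- do.call(rbind, lapply(split(per_day, per_day$season), function(s) {
      data.frame(date = s$date,
                 tempapp_l1 = shift_lag(s$tempapp, 1L),
                 tempapp_l2 = shift_lag(s$tempapp, 2L),
                 tempapp_l3 = shift_lag(s$tempapp, 3L),
                 tempapp_l03 = lag_window_mean(s$tempapp, 0:3),
                 tempapp_l05 = lag_window_mean(s$tempapp, 0:5))
    }))
    d <- merge(d, lagged, by = "date")
    log <- c(log, "lagged exposures recomputed from tempapp by season")
  }
  if (!"tempapp_l05" %in% names(d)) {
    per_day <- d[!duplicated(d$date), c("date", "season", "tempapp")]
    per_day <- per_day[order(per_day$date), ]
    l05 <- do.call(rbind, lapply(split(per_day, per_day$season), function(s)
      data.frame(date = s$date, tempapp_l05 = lag_window_mean(s$tempapp, 0:5))))
    d <- merge(d, l05, by = "date")
    log <- c(log, "lag 0-5 exposure computed from tempapp by season")
  }
  d <- d[order(d$date, factor(d$age_class, levels = AGE_LEVELS)), ]
  rownames(d) <- NULL
  log <- c(log, sprintf("read %d rows, %d days, %d season(s)", nrow(d),
                        length(unique(d$date)), length(unique(d$season))))
  attr(d, "log") <- log
  d
}

#' Write a dataset as a tidy CSV
#'
#' Inverse of [read_dataset()]'s tidy dialect; the round trip is lossless for
#' the analysis columns.
#'
#' @param data long-format analysis data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  cols <- intersect(c("date", "season", "day", "age_class", "visits",
                      "priority", "tempapp", "tempapp_l1", "tempapp_l2",
                      "tempapp_l3", "tempapp_l03", "tempapp_l05",
                      "pm10_mean"), names(data))
  utils::write.csv(data[cols], path, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the knobs of a full pipeline run: outcomes, exposure window,
#' threshold-grid settings, Monte Carlo size, seed, population denominators
#' and report precision.
#'
#' @param lag exposure window for the main analysis (default `"0-3"`).
#' @param grid_step,grid_quantiles threshold-grid resolution and bounds.
#' @param n_draws Monte Carlo draws (default 10000).
#' @param seed single top-level seed; every random step derives from it.
#' @param population named vector of inhabitants per age class.
#' @param level confidence level (default 0.90).
#' @param year_effect include a year indicator in the models (default off).
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(lag = "0-3", grid_step = 0.05,
                            grid_quantiles = c(0.05, 0.95),
                            n_draws = 10000L, seed = 1L,
                            population = verona_population(),
                            level = 0.90, year_effect = FALSE) {
  stopifnot(all(population > 0))
  structure(list(lag = lag, grid_step = grid_step,
                 grid_quantiles = grid_quantiles,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 population = population, level = level,
                 year_effect = year_effect),
            class = "analysis_config")
}

#' Run the full heat-impact pipeline
#'
#' Orchestrates the whole analysis on a validated long-format dataset:
#' segmented fits for all visits and high-priority visits (pooled over ages),
#' the age-interaction fits, Monte Carlo attribution of high-priority visits
#' (pooled and by age, all at the common high-priority threshold), and the
#' summary tables: effect estimates (percent changes and interaction tests),
#' attributable totals by year and age, community rates and per-day burdens,
#' plus the per-day attributable series for plotting.
#'
#' @param data long-format dataset (see [read_dataset()] / [simulate_dataset()]).
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, the report is written as
#'   JSON plus CSV companions, stamped with the seed and a config hash.
#' @return list of class `"heat_impact_report"` with elements `fits`
#'   (segmented + interaction fits), `effects` (data.frame of percent
#'   changes), `attributable` (totals by year and age), `burden` (ACR,
#'   per-day, maxima), `daily` (per-day attributable series), `config`.
#' @export
run_pipeline <- function(data, config = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  lag <- config$lag

  fits <- run_stage("segmented fits", {
    lapply(c(visits = "visits", priority = "priority"), function(oc)
      fit_segmented(data, outcome = oc, age = "all", lag = lag,
                    grid_step = config$grid_step,
                    grid_quantiles = config$grid_quantiles,
                    level = config$level, year_effect = config$year_effect))
  })
  inter <- run_stage("interaction fits", {
    lapply(c(visits = "visits", priority = "priority"), function(oc)
      fit_age_interaction(data, outcome = oc, lag = lag,
                          threshold = fits[[oc]]$threshold,
                          level = config$level,
                          year_effect = config$year_effect))
  })

  effects <- run_stage("effect table", {
    rows <- lapply(c("visits", "priority"), function(oc) {
      f <- fits[[oc]]
      it <- inter[[oc]]
      pooled <- percent_change(f$slope_above, f$slope_above_se, config$level)
      age_rows <- lapply(AGE_LEVELS, function(a) {
        pc <- percent_change(it$slopes[[a]], it$slopes_se[[a]], config$level)
        data.frame(outcome = oc, age = a, pct_change = pc[["estimate"]],
                   lower = pc[["lower"]], upper = pc[["upper"]],
                   chi_square = NA_real_, p_value = NA_real_)
      })
      rbind(data.frame(outcome = oc, age = "all",
                       pct_change = pooled[["estimate"]],
                       lower = pooled[["lower"]], upper = pooled[["upper"]],
                       chi_square = it$statistic, p_value = it$p_value),
            do.call(rbind, age_rows))
    })
    do.call(rbind, rows)
  })

  # attribution: high-priority outcome, common priority threshold + its SE
  f_pr <- fits$priority
  it_pr <- inter$priority
  h_se <- if (is.na(f_pr$threshold_se)) 0 else f_pr$threshold_se
  per_day <- data[!duplicated(data$date), ]
  per_day <- per_day[order(per_day$date), ]
  expo_col <- exposure_column(lag)
  keep <- !is.na(per_day[[expo_col]])
  per_day <- per_day[keep, ]
  Tt <- per_day[[expo_col]]
  seasons <- per_day$season

  agg_priority <- stats::aggregate(priority ~ date, data = data, sum)
  agg_priority <- agg_priority[match(per_day$date, agg_priority$date), ]

  scopes <- c("all", AGE_LEVELS)
  attribution <- run_stage("attribution", {
    res <- lapply(scopes, function(sc) {
      if (sc == "all") {
        b <- f_pr$slope_above; b_se <- f_pr$slope_above_se
        Y <- agg_priority$priority
      } else {
        b <- it_pr$slopes[[sc]]; b_se <- it_pr$slopes_se[[sc]]
        sub <- data[as.character(data$age_class) == sc, ]
        Y <- sub$priority[match(per_day$date, sub$date)]
      }
      draws <- sample_draws(n = config$n_draws,
                            seed = config$seed + match(sc, scopes),
                            b = b, b_se = b_se,
                            h = f_pr$threshold, h_se = h_se)
      ser <- attributable_series(draws, Y, Tt, dates = per_day$date,
                                 season = seasons)
      list(series = ser, summary = summarize_totals(ser))
    })
    names(res) <- scopes
    res
  })

  attributable <- do.call(rbind, lapply(scopes, function(sc) {
    tt <- attribution[[sc]]$summary$totals
    tt$age <- sc
    tt
  }))
  attributable <- attributable[c("age", "group", "p10", "median", "p90")]

  burden <- run_stage("burden table", {
    do.call(rbind, lapply(scopes, function(sc) {
      pop <- if (sc == "all") sum(config$population)
             else config$population[[sc]]
      per_season <- lapply(sort(unique(seasons)), function(yr) {
        bd <- per_day_burden(attribution[[sc]]$series, f_pr$threshold, yr)
        med <- attributable$median[attributable$age == sc &
                                     attributable$group == as.character(yr)]
        data.frame(age = sc, season = yr, population = pop,
                   attributable_median = med,
                   acr = attributable_community_rate(med, pop),
                   n_days_above = bd$n_days_above,
                   expected_per_day = bd$expected_per_day,
                   expected_per_day_daily_median = bd$expected_per_day_daily_median,
                   max_daily = bd$max_daily)
      })
      do.call(rbind, per_season)
    }))
  })

  daily <- attribution$all$summary$daily

  report <- structure(list(
    fits = fits, interaction = inter, effects = effects,
    attributable = attributable, burden = burden, daily = daily,
    config = config,
    seed = config$seed,
    config_hash = config_hash(config)
  ), class = "heat_impact_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# short stable hash of the configuration (no external digest dependency)
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (thresholds, slopes, percent changes, tests, totals)
#' plus CSV companions: `effects.csv`, `attributable.csv`, `burden.csv`,
#' `daily_attributable.csv` and per-outcome `profile_<outcome>.csv` traces.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits_json <- lapply(report$fits, function(f) list(
    outcome = f$outcome, lag = f$lag,
    threshold = f$threshold, threshold_se = f$threshold_se,
    threshold_ci = f$threshold_ci,
    slope_above = f$slope_above, slope_above_se = f$slope_above_se,
    pct_change = as.list(percent_change(f$slope_above, f$slope_above_se,
                                        report$config$level)),
    loglik = f$loglik, boundary = f$boundary))
  obj <- list(seed = report$seed, config_hash = report$config_hash,
              lag = report$config$lag, n_draws = report$config$n_draws,
              fits = fits_json,
              interaction = lapply(report$interaction, function(it) list(
                threshold = it$threshold, slopes = as.list(it$slopes),
                slopes_se = as.list(it$slopes_se),
                statistic = it$statistic, df = it$df, p_value = it$p_value)),
              effects = report$effects,
              attributable = report$attributable,
              burden = report$burden)
  jsonlite::write_json(obj, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$effects, file.path(out_dir, "effects.csv"),
                   row.names = FALSE)
  utils::write.csv(report$attributable, file.path(out_dir, "attributable.csv"),
                   row.names = FALSE)
  utils::write.csv(report$burden, file.path(out_dir, "burden.csv"),
                   row.names = FALSE)
  utils::write.csv(report$daily, file.path(out_dir, "daily_attributable.csv"),
                   row.names = FALSE)
  for (oc in names(report$fits))
    utils::write.csv(report$fits[[oc]]$profile,
                     file.path(out_dir, paste0("profile_", oc, ".csv")),
                     row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.heat_impact_report <- function(x, ...) {
  cat("Heat impact report (lag ", x$config$lag, ", ", x$config$n_draws,
      " draws, seed ", x$seed, ")\n", sep = "")
  for (oc in names(x$fits)) {
    f <- x$fits[[oc]]
    pc <- percent_change(f$slope_above, f$slope_above_se, x$config$level)
    cat(sprintf("  %-8s threshold %.2f degC, %% change %.2f (%.2f, %.2f)\n",
                oc, f$threshold, pc["estimate"], pc["lower"], pc["upper"]))
  }
  ov <- x$attributable[x$attributable$group == "overall", ]
  cat("  attributable high-priority visits (overall):\n")
  for (i in seq_len(nrow(ov)))
    cat(sprintf("    %-6s %6.0f [%.0f, %.0f]\n", ov$age[i], ov$median[i],
                ov$p10[i], ov$p90[i]))
  invisible(x)
}

#' Reproduce the original Verona analysis from a deposited-format file
#'
#' Runs the full pipeline with the study's settings (lag 0-3 exposure,
#' 10000 Monte Carlo draws, study-area population denominators) on a CSV in
#' the deposited dialect.
#'
#' @param path CSV path (deposited dialect, see [read_dataset()]).
#' @param n_draws Monte Carlo draws.
#' @param seed random seed.
#' @param out_dir optional report directory.
#' @return a [run_pipeline()] report.
#' @export
reproduce_study <- function(path, n_draws = 10000L, seed = 1L,
                            out_dir = NULL) {
  data <- read_dataset(path, dialect = "deposited")
  run_pipeline(data, analysis_config(n_draws = n_draws, seed = seed),
               out_dir = out_dir)
}
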