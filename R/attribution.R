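#' Monte Carlo draws of the heat slope and threshold
#'
#' Samples `n` independent pairs (b_i, h_i) from independent normal
#' distributions centred at the estimated above-threshold log-slope and
#' threshold, with their standard errors as spreads. A standard error of zero
#' collapses that margin to its point estimate (the degenerate, plug-in
#' case); negative standard errors are an error.
#'
#' @param fit either a [fit_segmented()] result, or `NULL` when `b`, `b_se`,
#'   `h`, `h_se` are supplied directly.
#' @param n number of draws (default 10000).
#' @param seed optional integer seed; recorded in the result.
#' @param b,b_se,h,h_se slope and threshold point estimates and standard
#'   errors, overriding those read from `fit`.
#' @return object of class `"draw_set"`: list with numeric vectors `b`, `h`
#'   (length `n`), the generating parameters and the seed.
#' @export
sample_draws <- function(fit = NULL, n = 10000L, seed = NULL,
                         b = NULL, b_se = NULL, h = NULL, h_se = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "segmented_fit"))
    if (is.null(b)) b <- fit$slope_above
    if (is.null(b_se)) b_se <- fit$slope_above_se
    if (is.null(h)) h <- fit$threshold
    if (is.null(h_se)) h_se <- fit$threshold_se
  }
  stopifnot(is.finite(b), is.finite(h), is.finite(b_se), is.finite(h_se))
  if (b_se < 0 || h_se < 0) stop("standard errors must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  bi <- if (b_se == 0) rep(b, n) else rnorm(n, b, b_se)
  hi <- if (h_se == 0) rep(h, n) else rnorm(n, h, h_se)
  structure(list(b = bi, h = hi, n = as.integer(n),
                 params = c(b = b, b_se = b_se, h = h, h_se = h_se),
                 seed = seed),
            class = "draw_set")
}

#' Daily attributable visits for every Monte Carlo draw
#'
#' Applies, for each sampled pair (b_i, h_i) and each day t, the attributable-
#' visit formula
#' \deqn{AV_{it} = Y_t - Y_t \exp[-b_i (T_t - h_i)] \quad \mathrm{if}\ T_t > h_i,
#'   \qquad AV_{it} = 0 \quad \mathrm{if}\ T_t \le h_i,}
#' where Y_t is the observed daily count and T_t the lag-window mean apparent
#' temperature. Draws with a negative sampled slope contribute negative
#' attributable visits; they are kept as-is by default so the Monte Carlo
#' distribution is not distorted (`truncate_negative = TRUE` clips them at 0
#' for comparison).
#'
#' @param draws a [sample_draws()] result.
#' @param Y non-negative daily counts.
#' @param Tt daily lag-window mean apparent temperature (same length as `Y`).
#' @param dates optional day identifiers carried into summaries.
#' @param season optional per-day season labels (e.g. year) for grouping.
#' @param truncate_negative clip negative per-day contributions at zero.
#' @return object of class `"attribution_series"`: list with `av`, an
#'   `n_draws` x `n_days` matrix, plus `Y`, `T`, `dates`, `season`.
#' @export
attributable_series <- function(draws, Y, Tt, dates = NULL, season = NULL,
                                truncate_negative = FALSE) {
  stopifnot(inherits(draws, "draw_set"), length(Y) == length(Tt),
            all(Y >= 0), !anyNA(Tt))
  n <- draws$n
  nd <- length(Y)
  av <- matrix(0, nrow = n, ncol = nd)
  for (i in seq_len(n)) {
    over <- Tt > draws$h[i]
    if (any(over))
      av[i, over] <- Y[over] * (1 - exp(-draws$b[i] * (Tt[over] - draws$h[i])))
  }
  if (truncate_negative) av[av < 0] <- 0
  structure(list(av = av, Y = Y, T = Tt,
                 dates = dates,
                 season = if (is.null(season)) rep(1L, nd) else season,
                 draws = draws),
            class = "attribution_series")
}

# empirical quantiles by linear interpolation of order statistics (type 7,
# the documented percentile rule of the package)
impact_quantiles <- function(x, probs = c(0.1, 0.5, 0.9)) {
  quantile(x, probs = probs, names = FALSE, type = 7)
}

#' Summarise the Monte Carlo attributable-visit distribution
#'
#' For each draw, sums the daily attributable visits over the requested
#' grouping (each season and overall), and summarises the resulting
#' distribution of totals by its median and 10th / 90th percentiles.
#' Also returns the per-day summary (median and the same percentile band of
#' AV_it across draws, day by day) used for daily-burden plots.
#'
#' @param series an [attributable_series()] result.
#' @param probs percentile levels; the middle entry is treated as the centre
#'   (default `c(0.1, 0.5, 0.9)`).
#' @return object of class `"impact_summary"`: list with `totals`, a
#'   data.frame (group, p10, median, p90), and `daily`, a data.frame with one
#'   row per day (date, season, T, Y, p10, median, p90).
#' @export
summarize_totals <- function(series, probs = c(0.1, 0.5, 0.9)) {
  stopifnot(inherits(series, "attribution_series"))
  av <- series$av
  groups <- unique(series$season)
  tot_rows <- lapply(groups, function(g) {
    tot <- rowSums(av[, series$season == g, drop = FALSE])
    q <- impact_quantiles(tot, probs)
    data.frame(group = as.character(g), p10 = q[1L], median = q[2L], p90 = q[3L])
  })
  overall <- impact_quantiles(rowSums(av), probs)
  totals <- rbind(do.call(rbind, tot_rows),
                  data.frame(group = "overall", p10 = overall[1L],
                             median = overall[2L], p90 = overall[3L]))
  rownames(totals) <- NULL

  dq <- apply(av, 2L, impact_quantiles, probs = probs)
  daily <- data.frame(
    date = if (is.null(series$dates)) seq_len(ncol(av)) else series$dates,
    season = series$season, T = series$T, Y = series$Y,
    p10 = dq[1L, ], median = dq[2L, ], p90 = dq[3L, ])
  structure(list(totals = totals, daily = daily, probs = probs),
            class = "impact_summary")
}

#' @export
print.impact_summary <- function(x, ...) {
  cat("Heat-attributable visits (median [p10, p90] of Monte Carlo totals)\n")
  for (i in seq_len(nrow(x$totals)))
    cat(sprintf("  %-8s %8.1f  [%.1f, %.1f]\n", x$totals$group[i],
                x$totals$median[i], x$totals$p10[i], x$totals$p90[i]))
  invisible(x)
}

#' Attributable community rate
#'
#' Number of heat-attributable events per 10000 inhabitants of the study
#' area: `10000 * total / population`.
#'
#' @param total attributable events (typically a median seasonal total).
#' @param population number of inhabitants (> 0).
#' @return rate per 10000 inhabitants (vectorised over `total`).
#' @export
#' @examples
#' attributable_community_rate(1042, 317658)  # 32.8
attributable_community_rate <- function(total, population) {
  if (!all(population > 0)) stop("population must be positive")
  10000 * total / population
}

#' Per-day heat burden above the threshold
#'
#' Counts the days with lag-window exposure above the fixed threshold, and
#' summarises the daily burden on those days two ways: the expected number of
#' attributable visits per day above the threshold (seasonal median total
#' divided by the day count; the variant that instead averages the per-day
#' medians over those days is also reported), and the maximum over days of
#' the per-day median attributable visits.
#'
#' @param series an [attributable_series()] result.
#' @param threshold fixed threshold in degC (a point estimate, not resampled).
#' @param season optional single season label to restrict to.
#' @return list with `n_days_above`, `expected_per_day` (median total /
#'   days above; `NA` when no day is above), `expected_per_day_daily_median`
#'   (mean of per-day medians over above-threshold days), `max_daily`
#'   (maximum per-day median attributable visits).
#' @export
per_day_burden <- function(series, threshold, season = NULL) {
  stopifnot(inherits(series, "attribution_series"))
  keep <- if (is.null(season)) rep(TRUE, length(series$T))
          else series$season == season
  av <- series$av[, keep, drop = FALSE]
  Tt <- series$T[keep]
  above <- Tt > threshold
  n_above <- sum(above)
  med_total <- impact_quantiles(rowSums(av), 0.5)[1L]
  daily_med <- apply(av, 2L, stats::median)
  list(
    n_days_above = n_above,
    expected_per_day = if (n_above == 0L) NA_real_ else med_total / n_above,
    expected_per_day_daily_median =
      if (n_above == 0L) NA_real_ else mean(daily_med[above]),
    max_daily = if (ncol(av) == 0L) 0 else max(daily_med)
  )
}

#' Deterministic plug-in attributable visits
#'
#' The attributable-visit formula applied at the point estimates (no Monte
#' Carlo): the day-by-day reference the sampler must reproduce when the
#' standard errors are zero.
#'
#' @param Y,Tt daily counts and exposures.
#' @param b,h slope and threshold point estimates.
#' @return numeric vector of per-day attributable visits.
#' @export
plug_in_attributable <- function(Y, Tt, b, h) {
  ifelse(Tt > h, Y * (1 - exp(-b * (Tt - h))), 0)
}
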