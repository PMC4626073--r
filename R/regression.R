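#' @importFrom stats glm glm.fit poisson quantile qnorm qchisq dpois logLik
#'   coef vcov predict anova pchisq rnorm rpois rbinom median sd setNames
#'   as.formula model.matrix
NULL

AGE_LEVELS <- c("0-14", "15-64", "65+")

# map a lag-window choice to the exposure column of the analysis frame
exposure_column <- function(lag = c("0-3", "0", "0-5")) {
  lag <- match.arg(as.character(lag), c("0-3", "0", "0-5"))
  switch(lag, "0" = "tempapp", "0-3" = "tempapp_l03", "0-5" = "tempapp_l05")
}

# Collapse the long (day x age) analysis frame to the day-level frame a single
# model is fitted on: outcome counts (summed over ages when pooling), the
# chosen lag-window exposure, PM10 and calendar covariates. Days with an
# undefined lag-window exposure (window reaching before the season start) are
# dropped. When age = "interaction" the frame keeps one row per day and age.
prepare_model_data <- function(data, outcome = c("visits", "priority"),
                               age = "all", lag = "0-3") {
  outcome <- match.arg(outcome)
  expo <- exposure_column(lag)
  need <- c("date", "age_class", outcome, expo, "pm10_mean")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns in analysis data: ",
                         paste(miss, collapse = ", "))
  y <- data[[outcome]]
  if (any(y < 0) || any(y != round(y)))
    stop("outcome '", outcome, "' must contain non-negative integer counts")

  if (identical(age, "all")) {
    agg <- stats::aggregate(data[[outcome]], by = list(date = data$date), sum)
    first <- data[!duplicated(data$date), c("date", expo, "pm10_mean")]
    d <- merge(agg, first, by = "date")
    names(d)[names(d) == "x"] <- "y"
  } else if (identical(age, "interaction")) {
    d <- data.frame(date = data$date, y = y,
                    age_class = factor(data$age_class, levels = AGE_LEVELS))
    d[[expo]] <- data[[expo]]
    d$pm10_mean <- data$pm10_mean
    counts <- table(d$date)
    if (any(counts != nlevels(d$age_class)))
      stop("interaction fit needs the same days observed for every age class")
  } else {
    if (!age %in% unique(as.character(data$age_class)))
      stop("unknown age class: ", age)
    d <- data[as.character(data$age_class) == age,
              c("date", outcome, expo, "pm10_mean")]
    names(d)[names(d) == outcome] <- "y"
  }
  d <- d[!is.na(d[[expo]]), , drop = FALSE]
  d <- d[order(d$date), , drop = FALSE]
  d$exposure <- d[[expo]]
  d$dow <- factor(format(d$date, "%w"), levels = as.character(0:6))
  d$month <- factor(format(d$date, "%m"))
  d$year <- factor(format(d$date, "%Y"))
  rownames(d) <- NULL
  d
}

# covariate part of the model formula (no heat terms)
covariate_terms <- function(d, year_effect = FALSE) {
  terms <- c("pm10_mean", "dow", "month")
  if (year_effect && nlevels(droplevels(d$year)) > 1L) terms <- c(terms, "year")
  terms
}

# Profile the Poisson log-likelihood over candidate thresholds. The design
# matrix is rebuilt once; only the hinge column changes along the grid, and
# each fit warm-starts from the previous solution, so the sweep stays cheap
# even at 0.05 degC resolution.
# Level set of the profile as an interval. The deviance crosses the cut
# somewhere between the last qualifying candidate and its non-qualifying
# neighbour; each endpoint is located by linear interpolation of the profile
# log-likelihood inside that bracket (clipping to qualifying grid points
# alone gives a systematically narrow, undercovering interval).
profile_interval <- function(grid, ll, cut) {
  inside <- (max(ll) - ll) <= cut
  target <- max(ll) - cut
  i_lo <- which(inside)[1L]
  i_hi <- which(inside)[sum(inside)]
  cross <- function(i_in, i_out) {
    if (abs(ll[i_in] - ll[i_out]) < 1e-12)
      return((grid[i_in] + grid[i_out]) / 2)
    stats::approx(ll[c(i_out, i_in)], grid[c(i_out, i_in)], xout = target)$y
  }
  lo <- if (i_lo > 1L) cross(i_lo, i_lo - 1L) else grid[1L]
  hi <- if (i_hi < length(grid)) cross(i_hi, i_hi + 1L) else grid[length(grid)]
  c(lo, hi)
}

profile_threshold <- function(y, exposure, X0, grid) {
  X <- cbind(X0, hinge = 0)
  p <- ncol(X)
  ll <- rep(NA_real_, length(grid))
  start <- NULL
  for (i in seq_along(grid)) {
    X[, p] <- pmax(exposure - grid[i], 0)
    fit <- suppressWarnings(
      glm.fit(X, y, family = poisson(),
              start = start,
              control = list(epsilon = 1e-8, maxit = 100))
    )
    if (!fit$converged)
      stop("IRLS did not converge at candidate threshold ", grid[i])
    start <- fit$coefficients
    # deviance differs from -2*loglik by a data-only constant: fine for
    # profiling, the true log-likelihood is recomputed at the optimum
    ll[i] <- -fit$deviance / 2
  }
  ll
}

#' Fit the segmented (joined two-line) Poisson heat-response model
#'
#' Fits, by profile maximum likelihood, the changepoint Poisson regression
#' \deqn{\log E[Y_t] = \alpha + \beta_1 T_t + \beta_2 (T_t - h)_+ +
#'   \gamma\,PM10_t + \mathrm{dow}_t + \mathrm{month}_t,}
#' where \eqn{T_t} is the lag-window mean apparent temperature. The hinge
#' parameterisation guarantees the two linear segments join continuously at
#' the threshold \eqn{h}; the slope above the threshold is
#' \eqn{b = \beta_1 + \beta_2}. The threshold is estimated by maximising the
#' log-likelihood over a fixed grid of candidates (default: 0.05 degC steps
#' between the 5th and 95th exposure percentiles, ties broken toward the
#' lower value), and its confidence interval is read off the profile
#' likelihood.
#'
#' @param data long-format analysis data.frame (one row per day and age class)
#'   with columns `date`, `age_class`, `visits`, `priority`, the exposure
#'   columns (`tempapp`, `tempapp_l03`, `tempapp_l05`) and `pm10_mean`.
#' @param outcome `"visits"` (all ED visits) or `"priority"` (no-white-tag,
#'   i.e. high-priority, visits).
#' @param age `"all"` (pooled over ages) or one of `"0-14"`, `"15-64"`,
#'   `"65+"`.
#' @param lag exposure window: `"0"`, `"0-3"` (default) or `"0-5"`.
#' @param grid optional explicit vector of candidate thresholds (degC).
#' @param grid_step grid resolution in degC when `grid` is not given.
#' @param grid_quantiles exposure quantiles bounding the default grid.
#' @param level confidence level for the threshold interval (default 0.90).
#' @param year_effect include a calendar-year indicator (off by default).
#' @return an object of class `"segmented_fit"`: a list with elements
#'   `threshold`, `threshold_se`, `threshold_ci`, `slope_above` (with
#'   `slope_above_se`), `slope_below` (with `slope_below_se`), `coefficients`,
#'   `vcov`, `loglik`, `profile` (data.frame of candidate/log-likelihood),
#'   `boundary` flag, the fitted `glm` object and the day-level model data.
#' @seealso [threshold_ci()], [percent_change()], [fit_age_interaction()]
#' @export
fit_segmented <- function(data, outcome = c("visits", "priority"),
                          age = "all", lag = "0-3",
                          grid = NULL, grid_step = 0.05,
                          grid_quantiles = c(0.05, 0.95),
                          level = 0.90, year_effect = FALSE) {
  outcome <- match.arg(outcome)
  d <- prepare_model_data(data, outcome, age, lag)
  if (is.null(grid)) {
    qs <- quantile(d$exposure, grid_quantiles, names = FALSE)
    grid <- seq(qs[1L], qs[2L], by = grid_step)
  }
  grid <- sort(unique(grid))
  if (length(grid) < 2L) stop("threshold grid needs at least two candidates")
  min_side <- 5L
  ok <- vapply(grid, function(h)
    sum(d$exposure > h) >= min_side && sum(d$exposure <= h) >= min_side,
    logical(1L))
  if (!any(ok)) stop("no candidate threshold leaves ", min_side,
                     " days on each side")
  grid <- grid[ok]

  covs <- covariate_terms(d, year_effect)
  f0 <- as.formula(paste("~ exposure +", paste(covs, collapse = " + ")))
  X0 <- model.matrix(f0, d)
  ll <- profile_threshold(d$y, d$exposure, X0, grid)

  i_best <- which.max(ll)  # first maximum: ties broken toward lower h
  h_hat <- grid[i_best]

  # profile-likelihood interval for the threshold
  cut <- qchisq(level, df = 1) / 2
  inside <- (max(ll) - ll) <= cut
  ci <- profile_interval(grid, ll, cut)
  boundary <- inside[1L] || inside[length(inside)]
  flat <- (max(ll) - min(ll)) <= cut
  if (flat)
    warning("profile log-likelihood is nearly flat: threshold not identified")
  h_se <- if (boundary) NA_real_ else
    (ci[2L] - ci[1L]) / (2 * qnorm((1 + level) / 2))

  # final refit at the selected threshold via glm() for SEs and diagnostics
  d$hinge <- pmax(d$exposure - h_hat, 0)
  ff <- as.formula(paste("y ~ exposure + hinge +", paste(covs, collapse = " + ")))
  fit <- glm(ff, family = poisson(), data = d,
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("final Poisson fit did not converge")
  cf <- coef(fit)
  V <- vcov(fit)
  b_above <- cf[["exposure"]] + cf[["hinge"]]
  b_above_se <- sqrt(V["exposure", "exposure"] + V["hinge", "hinge"] +
                       2 * V["exposure", "hinge"])

  structure(list(
    outcome = outcome, age = age, lag = lag,
    threshold = h_hat,
    threshold_se = h_se,
    threshold_ci = ci,
    level = level,
    slope_above = b_above,
    slope_above_se = b_above_se,
    slope_below = cf[["exposure"]],
    slope_below_se = sqrt(V["exposure", "exposure"]),
    coefficients = cf,
    vcov = V,
    loglik = as.numeric(logLik(fit)),
    profile = data.frame(threshold = grid, loglik = ll),
    boundary = boundary,
    flat = flat,
    glm = fit,
    model_data = d
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  pc <- percent_change(x$slope_above, x$slope_above_se, level = x$level)
  cat("Segmented Poisson heat-response fit\n")
  cat(sprintf("  outcome: %s, age: %s, lag: %s (%d days)\n",
              x$outcome, x$age, x$lag, nrow(x$model_data)))
  cat(sprintf("  threshold: %.2f degC  %d%% CI (%.2f, %.2f)%s\n",
              x$threshold, round(100 * x$level), x$threshold_ci[1L],
              x$threshold_ci[2L], if (x$boundary) " [boundary]" else ""))
  cat(sprintf("  %% change above threshold per 1 degC: %.2f (%.2f, %.2f)\n",
              pc["estimate"], pc["lower"], pc["upper"]))
  invisible(x)
}

#' Profile-likelihood confidence interval for the threshold
#'
#' Returns the set of candidate thresholds whose profile deviance lies within
#' the chi-squared(1) quantile of the minimum, as an interval, together with
#' the normal-approximation standard error (interval width divided by twice
#' the normal quantile) used by the Monte Carlo attribution sampler. An
#' interval touching the grid boundary is flagged: the threshold is then
#' weakly identified and the SE is `NA`.
#'
#' @param fit a [fit_segmented()] result.
#' @param level confidence level (default 0.90).
#' @return list with `interval` (numeric length 2), `se`, `boundary` flag.
#' @export
threshold_ci <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "segmented_fit"))
  pr <- fit$profile
  cut <- qchisq(level, df = 1) / 2
  inside <- (max(pr$loglik) - pr$loglik) <= cut
  ci <- profile_interval(pr$threshold, pr$loglik, cut)
  boundary <- inside[1L] || inside[nrow(pr)]
  se <- if (boundary) NA_real_ else (ci[2L] - ci[1L]) / (2 * qnorm((1 + level) / 2))
  list(interval = ci, se = se, boundary = boundary)
}

#' Percent change in visits per 1 degC above the threshold
#'
#' Transforms an above-threshold log-slope b (per degC) to the percent scale,
#' `100 * (exp(b) - 1)`; confidence-interval endpoints are transformed the
#' same way.
#'
#' @param log_slope log-linear slope per degC.
#' @param se optional standard error of the slope.
#' @param level confidence level when `se` is given (default 0.90).
#' @return if `se` is `NULL`, a numeric vector of percent changes; otherwise a
#'   named vector `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' percent_change(0)          # 0
#' percent_change(0.036814)   # 3.75
percent_change <- function(log_slope, se = NULL, level = 0.90) {
  est <- 100 * (exp(log_slope) - 1)
  if (is.null(se)) return(est)
  z <- qnorm((1 + level) / 2)
  c(estimate = est,
    lower = 100 * (exp(log_slope - z * se) - 1),
    upper = 100 * (exp(log_slope + z * se) - 1))
}

#' Exploratory spline Poisson heat-response fit
#'
#' Fits the Poisson regression with the heat-response modelled as a cubic
#' regression spline (default 4 degrees of freedom) instead of two joined
#' lines, adjusting for PM10, day of week and month as in [fit_segmented()].
#' Used to inspect the shape of the exposure-response before committing to the
#' changepoint form; refits with 3 or 5 df support the usual robustness check.
#'
#' @inheritParams fit_segmented
#' @param df spline degrees of freedom (3, 4 or 5 are the usual choices).
#' @param n_grid number of exposure grid points for the returned curve.
#' @return an object of class `"spline_fit"`: list with the fitted `glm`, and
#'   `curve`, a data.frame over the observed exposure range with the spline
#'   contribution to the log-rate (`log_rr`, centred at the curve mean) and a
#'   pointwise 90% band (`lower`, `upper`).
#' @export
fit_spline_model <- function(data, outcome = c("visits", "priority"),
                             age = "all", lag = "0-3", df = 4,
                             level = 0.90, year_effect = FALSE,
                             n_grid = 101L) {
  outcome <- match.arg(outcome)
  d <- prepare_model_data(data, outcome, age, lag)
  covs <- covariate_terms(d, year_effect)
  ff <- as.formula(paste("y ~ splines::bs(exposure, df =", df, ") +",
                         paste(covs, collapse = " + ")))
  fit <- glm(ff, family = poisson(), data = d,
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("spline Poisson fit did not converge")

  grid <- seq(min(d$exposure), max(d$exposure), length.out = n_grid)
  nd <- d[rep(1L, n_grid), , drop = FALSE]
  nd$exposure <- grid
  pr <- predict(fit, newdata = nd, type = "terms", se.fit = TRUE)
  term <- grep("exposure", colnames(pr$fit), value = TRUE)[1L]
  z <- qnorm((1 + level) / 2)
  eta <- pr$fit[, term] - mean(pr$fit[, term])
  se <- pr$se.fit[, term]
  structure(list(
    outcome = outcome, age = age, lag = lag, df = df, glm = fit,
    loglik = as.numeric(logLik(fit)),
    curve = data.frame(exposure = grid, log_rr = eta,
                       lower = eta - z * se, upper = eta + z * se),
    model_data = d
  ), class = "spline_fit")
}

#' Test whether the above-threshold heat slope differs by age class
#'
#' Fits a single Poisson model over all three age classes with age-specific
#' intercepts, shared PM10 / day-of-week / month effects, a shared
#' below-threshold slope, and age-specific slopes above a common, fixed
#' threshold (taken from the pooled fit). The null of equal above-threshold
#' slopes is tested with a 2-degree-of-freedom likelihood-ratio chi-squared
#' test (a Wald version is available).
#'
#' @inheritParams fit_segmented
#' @param threshold common threshold in degC; defaults to the pooled-data
#'   estimate obtained by running [fit_segmented()] on the same data.
#' @param test `"lrt"` (default) or `"wald"`.
#' @return object of class `"interaction_fit"`: list with `threshold`,
#'   `slopes` (named vector of age-specific above-threshold log-slopes),
#'   `slopes_se`, `statistic`, `df`, `p_value`, `test` and the fitted `glm`.
#' @export
fit_age_interaction <- function(data, outcome = c("visits", "priority"),
                                lag = "0-3", threshold = NULL,
                                level = 0.90, year_effect = FALSE,
                                test = c("lrt", "wald"), ...) {
  outcome <- match.arg(outcome)
  test <- match.arg(test)
  if (is.null(threshold)) {
    pooled <- fit_segmented(data, outcome = outcome, age = "all", lag = lag,
                            level = level, year_effect = year_effect, ...)
    threshold <- pooled$threshold
  }
  d <- prepare_model_data(data, outcome, age = "interaction", lag = lag)
  d$hinge <- pmax(d$exposure - threshold, 0)
  covs <- covariate_terms(d, year_effect)
  ff_full <- as.formula(paste(
    "y ~ age_class + exposure + hinge:age_class +",
    paste(covs, collapse = " + ")))
  ff_null <- as.formula(paste(
    "y ~ age_class + exposure + hinge +", paste(covs, collapse = " + ")))
  full <- glm(ff_full, family = poisson(), data = d,
              control = list(epsilon = 1e-8, maxit = 100))
  null <- glm(ff_null, family = poisson(), data = d,
              control = list(epsilon = 1e-8, maxit = 100))
  if (!full$converged || !null$converged)
    stop("interaction Poisson fit did not converge")

  cf <- coef(full)
  V <- vcov(full)
  hnames <- vapply(AGE_LEVELS, function(a)
    grep("hinge", grep(a, names(cf), fixed = TRUE, value = TRUE),
         fixed = TRUE, value = TRUE)[1L], character(1L))
  if (anyNA(hnames))
    stop("unexpected interaction coefficient names")
  slopes <- cf[["exposure"]] + cf[hnames]
  names(slopes) <- AGE_LEVELS
  slopes_se <- vapply(hnames, function(nm)
    sqrt(V["exposure", "exposure"] + V[nm, nm] + 2 * V["exposure", nm]),
    numeric(1L))
  names(slopes_se) <- AGE_LEVELS

  if (test == "lrt") {
    stat <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null)))
  } else {
    # Wald: 2 contrasts among the three hinge coefficients
    L <- matrix(0, nrow = 2L, ncol = length(cf),
                dimnames = list(NULL, names(cf)))
    L[1L, hnames[1L]] <- 1; L[1L, hnames[2L]] <- -1
    L[2L, hnames[2L]] <- 1; L[2L, hnames[3L]] <- -1
    delta <- L %*% cf
    stat <- drop(t(delta) %*% solve(L %*% V %*% t(L)) %*% delta)
  }
  structure(list(
    outcome = outcome, lag = lag, threshold = threshold,
    slopes = slopes, slopes_se = slopes_se,
    statistic = stat, df = 2L, p_value = pchisq(stat, df = 2L, lower.tail = FALSE),
    test = test, level = level, glm = full, glm_null = null,
    model_data = d
  ), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Age-interaction heat-response fit (common threshold ",
      sprintf("%.2f", x$threshold), " degC)\n", sep = "")
  for (a in names(x$slopes)) {
    pc <- percent_change(x$slopes[[a]], x$slopes_se[[a]], level = x$level)
    cat(sprintf("  %-6s %% change %.2f (%.2f, %.2f)\n",
                a, pc["estimate"], pc["lower"], pc["upper"]))
  }
  cat(sprintf("  %s chi-square (2 df) = %.2f, p = %.3f\n",
              toupper(x$test), x$statistic, x$p_value))
  invisible(x)
}
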