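test_that("percent change transforms the log slope and its CI", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(0.036814), 100 * (exp(0.036814) - 1))
  expect_equal(round(percent_change(0.036814), 2), 3.75)
  expect_equal(round(percent_change(0.049290), 2), 5.05)
  pc <- percent_change(0.05, se = 0.01, level = 0.90)
  z <- qnorm(0.95)
  expect_equal(unname(pc["lower"]), 100 * (exp(0.05 - z * 0.01) - 1))
  expect_equal(unname(pc["upper"]), 100 * (exp(0.05 + z * 0.01) - 1))
  # monotone, and asymmetric around zero (exp is convex)
  b <- seq(-0.2, 0.2, by = 0.01)
  expect_true(all(diff(percent_change(b)) > 0))
  expect_true(all(abs(percent_change(b[b > 0])) >
                    abs(percent_change(-b[b > 0]))))
})

test_that("grid-search segmented fit matches an exhaustive refit oracle", {
  d <- tiny_dataset(n_days = 20L)
  cand <- c(24, 27)
  # 2-candidate grid: the flat-profile warning is expected and irrelevant here
  fit <- suppressWarnings(
    fit_segmented(d, outcome = "visits", age = "all", lag = "0", grid = cand))

  # independent path: aggregate by hand, refit each candidate via the glm
  # formula interface, keep the higher log-likelihood
  agg <- aggregate(visits ~ date, d, sum)
  agg$T <- d$tempapp[match(agg$date, d$date)]
  agg$pm10 <- d$pm10_mean[match(agg$date, d$date)]
  agg$dow <- factor(format(agg$date, "%w"), levels = as.character(0:6))
  agg$month <- factor(format(agg$date, "%m"))
  oracle <- lapply(cand, function(h) {
    glm(visits ~ T + I(pmax(T - h, 0)) + pm10 + dow + month,
        family = poisson(), data = agg)
  })
  ll <- vapply(oracle, function(m) as.numeric(logLik(m)), numeric(1))
  best <- which.max(ll)
  expect_equal(fit$threshold, cand[best])
  expect_equal(fit$loglik, ll[best], tolerance = 1e-8)
  cf <- coef(oracle[[best]])
  expect_equal(unname(fit$slope_above), unname(cf[2] + cf[3]),
               tolerance = 1e-6)
  # profile trace is the likelihood of each candidate (up to a shared
  # saturated-model constant)
  expect_equal(diff(fit$profile$loglik), diff(ll), tolerance = 1e-6)
})

test_that("segmented fit recovers a known threshold and slope", {
  cfg <- scenario_config()
  ds <- paper_scale_dataset()
  fit <- fit_segmented(ds, outcome = "priority", age = "all")
  b_true <- true_pooled_slope(cfg, "priority")
  expect_lt(abs(fit$threshold - cfg$threshold), 1.0)
  expect_lt(abs(fit$slope_above - b_true), 0.02)
  expect_gt(fit$slope_above, fit$slope_below)

  # argmax property of the profile
  expect_equal(fit$profile$threshold[which.max(fit$profile$loglik)],
               fit$threshold)
  # the reported CI contains the estimate
  expect_gte(fit$threshold, fit$threshold_ci[1])
  expect_lte(fit$threshold, fit$threshold_ci[2])

  # better likelihood than the no-heat model on the same days
  d <- fit$model_data
  null <- glm(y ~ pm10_mean + dow + month, family = poisson(), data = d)
  expect_gt(fit$loglik, as.numeric(logLik(null)))

  # threshold_ci agrees with the stored interval and returns a usable SE
  ci <- threshold_ci(fit, level = 0.90)
  expect_equal(ci$interval, fit$threshold_ci)
  if (!ci$boundary) expect_gt(ci$se, 0)
})

test_that("an unidentifiable (linear) response is boundary-flagged", {
  # property-style: under a perfectly linear response the profile interval
  # should (usually) span the grid and carry the boundary flag; a single
  # noisy replicate can escape, so check the typical behaviour over 5 seeds
  cfg <- scenario_config(slope_above = c(`0-14` = 0, `15-64` = 0, `65+` = 0),
                         slope_below = 0.01)
  res <- vapply(1:5, function(s) {
    ds <- simulate_dataset(cfg, seed = s)
    fit <- suppressWarnings(fit_segmented(ds, outcome = "visits", age = "all"))
    ci <- threshold_ci(fit)
    gr <- range(fit$profile$threshold)
    c(boundary = ci$boundary, se_na = is.na(ci$se),
      width_frac = diff(ci$interval) / diff(gr))
  }, numeric(3))
  expect_gte(sum(res["boundary", ]), 3)
  # when boundary-flagged the normal-approximation SE is withheld
  expect_equal(res["se_na", ], res["boundary", ])
  expect_gt(median(res["width_frac", ]), 0.5)
})

test_that("input validation catches bad counts, ages and day sets", {
  d <- tiny_dataset()
  d_bad <- d; d_bad$visits[3] <- 2.5
  expect_error(fit_segmented(d_bad, "visits", lag = "0", grid = c(24, 27)),
               "non-negative integer")
  d_neg <- d; d_neg$priority[1] <- -1L
  expect_error(fit_segmented(d_neg, "priority", lag = "0", grid = c(24, 27)),
               "non-negative integer")
  expect_error(fit_segmented(d, "visits", age = "7-99", lag = "0",
                             grid = c(24, 27)), "age class")
  d_miss <- d[-4L, ]  # drop one age row on one day
  expect_error(fit_age_interaction(d_miss, "visits", lag = "0",
                                   threshold = 26),
               "same days")
})

test_that("spline fit is flat under a null and tracks a known kink", {
  cfg0 <- scenario_config(slope_above = c(`0-14` = 0, `15-64` = 0, `65+` = 0),
                          slope_below = 0)
  ds0 <- simulate_dataset(cfg0, seed = 31L)
  sp0 <- fit_spline_model(ds0, outcome = "visits", age = "all", df = 4)
  # null world: the 90% band contains the flat curve almost everywhere
  covered <- mean(sp0$curve$lower <= 0 & sp0$curve$upper >= 0)
  expect_gt(covered, 0.85)

  ds <- paper_scale_dataset()
  cfg <- scenario_config()
  sp <- fit_spline_model(ds, outcome = "priority", age = "all", df = 4)
  b_true <- true_pooled_slope(cfg, "priority")
  # true centred log-rate curve over the same grid
  g <- sp$curve$exposure
  truth <- cfg$slope_below * g +
    (b_true - cfg$slope_below) * pmax(g - cfg$threshold, 0)
  truth <- truth - mean(truth)
  expect_lt(mean(abs(sp$curve$log_rr - truth)), 0.05)
  # visibly steeper above the threshold than below
  below <- g < cfg$threshold - 1
  above <- g > cfg$threshold + 0.5
  slope_lo <- coef(lm(sp$curve$log_rr[below] ~ g[below]))[2]
  slope_hi <- coef(lm(sp$curve$log_rr[above] ~ g[above]))[2]
  expect_gt(slope_hi, slope_lo + 0.01)
  # 3 and 5 df refits keep the shape (correlated curves)
  for (dfree in c(3, 5)) {
    spk <- fit_spline_model(ds, outcome = "priority", age = "all", df = dfree)
    expect_gt(cor(spk$curve$log_rr, sp$curve$log_rr), 0.98)
  }
})

test_that("age interaction estimates per-age slopes and a 2-df test", {
  ds <- paper_scale_dataset()
  cfg <- scenario_config()
  pooled <- fit_segmented(ds, outcome = "priority", age = "all")
  it <- fit_age_interaction(ds, outcome = "priority",
                            threshold = pooled$threshold)
  expect_named(it$slopes, c("0-14", "15-64", "65+"))
  expect_equal(it$df, 2L)
  b_true <- cfg$slope_above + cfg$slope_below
  expect_lt(max(abs(it$slopes - b_true)), 0.03)
  # Wald and LRT agree to first order
  itw <- fit_age_interaction(ds, outcome = "priority",
                             threshold = pooled$threshold, test = "wald")
  expect_equal(itw$statistic, it$statistic, tolerance = 0.5)
  expect_identical(itw$slopes, it$slopes)
  # stratified per-age fits point the same way as the interaction slopes
  for (a in c("15-64", "65+")) {
    fa <- suppressWarnings(
      fit_segmented(ds, outcome = "priority", age = a,
                    grid = pooled$threshold + c(-0.5, 0, 0.5)))
    expect_lt(abs((fa$slope_above) - it$slopes[[a]]), 0.03)
  }
})

test_that("PM10 adjustment reduces confounding bias", {
  cfg <- scenario_config(pm10_temp_cor = 0.8, pm10_effect = 4e-3)
  b_true <- true_pooled_slope(cfg, "priority")
  bias_adj <- bias_raw <- numeric(12)
  for (r in seq_len(12)) {
    ds <- simulate_dataset(cfg, seed = 5000L + r)
    fit <- suppressWarnings(
      fit_segmented(ds, outcome = "priority", age = "all", grid_step = 0.1))
    ds_perm <- ds
    set.seed(6000L + r)  # permuted PM10: the model can no longer adjust
    per_day <- unique(ds$pm10_mean)
    ds_perm$pm10_mean <- sample(per_day)[match(ds$pm10_mean, per_day)]
    fit_raw <- suppressWarnings(
      fit_segmented(ds_perm, outcome = "priority", age = "all",
                    grid_step = 0.1))
    bias_adj[r] <- fit$slope_above - b_true
    bias_raw[r] <- fit_raw$slope_above - b_true
  }
  expect_lt(abs(median(bias_adj)), abs(median(bias_raw)))
})
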