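test_that("the attributable-visit formula is applied verbatim", {
  # Y = 100, b = 0.05, T - h = 1.2  ->  100 * (1 - exp(-0.06))
  expect_equal(plug_in_attributable(100, 29, 0.05, 27.8),
               100 * (1 - exp(-0.05 * 1.2)))
  expect_equal(round(plug_in_attributable(100, 29, 0.05, 27.8), 4), 5.8235)
  expect_equal(plug_in_attributable(100, 27.8, 0.05, 27.8), 0)  # T <= h
  expect_equal(plug_in_attributable(100, 25, 0.05, 27.8), 0)
  expect_equal(plug_in_attributable(100, 32, 0, 27.8), 0)       # b = 0

  draws <- sample_draws(n = 3L, b = 0.05, b_se = 0, h = 27.8, h_se = 0)
  ser <- attributable_series(draws, Y = c(100, 50, 80),
                             Tt = c(29, 27.8, 30))
  expect_equal(ser$av[1, ], plug_in_attributable(c(100, 50, 80),
                                                 c(29, 27.8, 30), 0.05, 27.8))
  expect_equal(ser$av[1, 2], 0)
})

test_that("draw sampling honours the moments, seeds and degenerate SEs", {
  d0 <- sample_draws(n = 100L, b = 0.05, b_se = 0, h = 28.8, h_se = 0)
  expect_true(all(d0$b == 0.05) && all(d0$h == 28.8))

  d <- sample_draws(n = 10000L, seed = 11L, b = 0.05, b_se = 0.01,
                    h = 28.8, h_se = 0.06)
  expect_lt(abs(mean(d$b) - 0.05), 3 * 0.01 / sqrt(10000))
  expect_lt(abs(mean(d$h) - 28.8), 3 * 0.06 / sqrt(10000))
  expect_lt(abs(sd(d$b) - 0.01) / 0.01, 0.05)
  expect_lt(abs(cor(d$b, d$h)), 0.03)  # independence of the two margins

  d2 <- sample_draws(n = 10000L, seed = 11L, b = 0.05, b_se = 0.01,
                     h = 28.8, h_se = 0.06)
  expect_identical(d$b, d2$b)  # same seed, same draws
  expect_error(sample_draws(n = 10L, b = 0.05, b_se = -0.01, h = 28, h_se = 0),
               "non-negative")
})

test_that("totals and percentiles match a brute-force oracle", {
  # hand-built 5-draw set over 4 days
  draws <- sample_draws(n = 5L, b = 0.04, b_se = 0, h = 28, h_se = 0)
  draws$b <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  draws$h <- c(27.5, 27.9, 28.0, 28.4, 29.0)
  Y <- c(120, 90, 110, 100)
  Tt <- c(27.0, 28.2, 29.4, 30.1)
  ser <- attributable_series(draws, Y, Tt,
                             season = c(2011L, 2011L, 2012L, 2012L))
  # brute force, day by day and draw by draw
  av_bf <- matrix(0, 5, 4)
  for (i in 1:5) for (t in 1:4)
    if (Tt[t] > draws$h[i])
      av_bf[i, t] <- Y[t] - Y[t] * exp(-draws$b[i] * (Tt[t] - draws$h[i]))
  expect_equal(ser$av, av_bf)

  s <- summarize_totals(ser)
  tot <- rowSums(av_bf)
  # interpolated order statistics, computed by hand
  srt <- sort(tot)
  expect_equal(s$totals$median[s$totals$group == "overall"], srt[3])
  # type-7 interpolation: index (n-1)p + 1 = 1.4 and 4.6 for p = .1, .9
  expect_equal(s$totals$p10[s$totals$group == "overall"],
               srt[1] + 0.4 * (srt[2] - srt[1]))
  expect_equal(s$totals$p90[s$totals$group == "overall"],
               srt[4] + 0.6 * (srt[5] - srt[4]))
  # season split adds up
  t11 <- rowSums(av_bf[, 1:2]); t12 <- rowSums(av_bf[, 3:4])
  expect_equal(s$totals$median[s$totals$group == "2011"], sort(t11)[3])
  expect_equal(s$totals$median[s$totals$group == "2012"], sort(t12)[3])
  expect_true(all(s$totals$p10 <= s$totals$median &
                    s$totals$median <= s$totals$p90))

  # identical draws collapse the distribution
  dd <- sample_draws(n = 50L, b = 0.05, b_se = 0, h = 28, h_se = 0)
  ss <- summarize_totals(attributable_series(dd, Y, Tt))
  expect_equal(ss$totals$p10, ss$totals$median)
  expect_equal(ss$totals$p90, ss$totals$median)
})

test_that("plug-in oracle equals the degenerate Monte Carlo exactly", {
  ds <- paper_scale_dataset()
  fit <- fit_segmented(ds, outcome = "priority", age = "all")
  d <- fit$model_data
  draws <- sample_draws(fit, n = 20L, b_se = 0, h_se = 0)
  ser <- attributable_series(draws, d$y, d$exposure, season = rep(1L, nrow(d)))
  s <- summarize_totals(ser)
  plug <- sum(plug_in_attributable(d$y, d$exposure, fit$slope_above,
                                   fit$threshold))
  expect_identical(s$totals$median[s$totals$group == "overall"], plug)
})

test_that("attribution respects monotonicity and the count bound", {
  Y <- c(80, 120, 100, 90, 110)
  Tt <- c(27, 29, 30, 31, 28.5)
  base <- sum(plug_in_attributable(Y, Tt, 0.05, 28))
  # nondecreasing in b
  bs <- seq(0.01, 0.1, by = 0.01)
  tots <- vapply(bs, function(b) sum(plug_in_attributable(Y, Tt, b, 28)),
                 numeric(1))
  expect_true(all(diff(tots) > 0))
  # nonincreasing in h
  hs <- seq(27, 31, by = 0.25)
  tots_h <- vapply(hs, function(h) sum(plug_in_attributable(Y, Tt, 0.05, h)),
                   numeric(1))
  expect_true(all(diff(tots_h) <= 0))
  # per-draw total bounded by observed visits on days above threshold
  draws <- sample_draws(n = 200L, seed = 3L, b = 0.05, b_se = 0.02,
                        h = 28, h_se = 0.3)
  ser <- attributable_series(draws, Y, Tt)
  for (i in c(1L, 57L, 200L)) {
    above <- Tt > draws$h[i]
    expect_lte(sum(ser$av[i, ]), sum(Y[above]))
  }
  # AV strictly below Y when b > 0 (exp(-x) > 0)
  pos <- draws$b > 0
  expect_true(all(ser$av[pos, ] < matrix(Y, sum(pos), 5, byrow = TRUE)))
})

test_that("negative sampled slopes pass through unless truncated", {
  draws <- sample_draws(n = 2L, b = -0.02, b_se = 0, h = 28, h_se = 0)
  ser <- attributable_series(draws, Y = c(100), Tt = c(30))
  expect_lt(ser$av[1, 1], 0)
  ser_t <- attributable_series(draws, Y = c(100), Tt = c(30),
                               truncate_negative = TRUE)
  expect_equal(ser_t$av[1, 1], 0)
})

test_that("community rate and per-day burden follow their definitions", {
  expect_equal(round(attributable_community_rate(1042, 317658), 1), 32.8)
  expect_equal(attributable_community_rate(0, 50000), 0)
  expect_equal(round(attributable_community_rate(280, 73541), 2), 38.07)
  expect_error(attributable_community_rate(10, 0), "positive")

  draws <- sample_draws(n = 100L, seed = 9L, b = 0.05, b_se = 0.005,
                        h = 28, h_se = 0.05)
  Y <- c(100, 90, 110, 95); Tt <- c(27, 29, 30, 26)
  ser <- attributable_series(draws, Y, Tt, season = rep(2012L, 4))
  bd <- per_day_burden(ser, threshold = 28, season = 2012L)
  expect_equal(bd$n_days_above, 2L)
  med_tot <- summarize_totals(ser)$totals
  expect_equal(bd$expected_per_day,
               med_tot$median[med_tot$group == "2012"] / 2)
  daily_med <- apply(ser$av, 2, median)
  expect_equal(bd$max_daily, max(daily_med))
  expect_equal(bd$expected_per_day_daily_median, mean(daily_med[Tt > 28]))

  # no day above threshold
  ser_cold <- attributable_series(draws, Y, Tt - 10, season = rep(2012L, 4))
  bd0 <- per_day_burden(ser_cold, threshold = 28)
  expect_equal(bd0$n_days_above, 0L)
  expect_true(is.na(bd0$expected_per_day))
})
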