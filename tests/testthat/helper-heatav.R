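# shared fixtures, all generated in code

# paper-scale synthetic dataset reused across tests (fixed seed)
paper_scale_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(scenario_config(), seed = 424L)
    cache
  }
})

# true pooled above-threshold slope implied by a scenario: age slopes weighted
# by each age's share of the outcome at the threshold
true_pooled_slope <- function(config, outcome = c("priority", "visits")) {
  outcome <- match.arg(outcome)
  w <- config$age_share
  if (outcome == "priority") w <- w * (1 - config$white_tag_frac)
  w <- w / sum(w)
  # the fitted above-threshold slope is below-slope + (mixture of) hinge slopes
  sum(w * config$slope_above) + config$slope_below
}

# tiny hand-rolled long-format frame (n_days days, 3 age classes)
tiny_dataset <- function(n_days = 20L, seed = 99L) {
  set.seed(seed)
  dates <- as.Date("2011-05-15") + 0:(n_days - 1L)
  at <- seq(20, 30, length.out = n_days) + rnorm(n_days, 0, 0.3)
  ages <- c("0-14", "15-64", "65+")
  d <- expand.grid(date = dates, age_class = ages,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[order(d$date), ]
  d$tempapp <- at[match(d$date, dates)]
  d$tempapp_l03 <- d$tempapp      # window {0} stand-in: keeps all days usable
  d$tempapp_l05 <- d$tempapp
  d$pm10_mean <- round(runif(n_days, 15, 40), 1)[match(d$date, dates)]
  mu <- ifelse(d$age_class == "0-14", 20, ifelse(d$age_class == "15-64", 70, 45))
  d$visits <- rpois(nrow(d), mu * exp(0.04 * pmax(d$tempapp - 26, 0)))
  d$priority <- rbinom(nrow(d), d$visits, 0.8)
  d$season <- 2011L
  rownames(d) <- NULL
  d
}
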