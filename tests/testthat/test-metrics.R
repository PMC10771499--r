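# A synthetic trajectory with a prescribed O.A staircase.
staircase_traj <- function(times, values, D_tot = 50) {
  states <- matrix(0, length(times), 18,
                   dimnames = list(NULL, state_names()))
  states[, "O.A"] <- values
  states[, "O.D"] <- D_tot - values
  structure(list(times = times, states = states, event_count = 0,
                 params = grn_params(D_tot = D_tot)),
            class = "grn_trajectory")
}

test_that("first passage finds the earliest sampled crossing", {
  tr <- staircase_traj(seq(0, 192, by = 9.6),
                       c(0, 0, 5, 10, 20, 30, 35, 38, 39, 39, 40, 45,
                         rep(50, 9)))
  expect_equal(first_passage(tr, 40, "up"), 96)   # day 10
  expect_equal(tau_to_days(first_passage(tr, 40, "up")), 10)
  # starting above the threshold: latency 0
  tr0 <- staircase_traj(c(0, 10), c(50, 50))
  expect_equal(first_passage(tr0, 40, "up"), 0)
  # never crossing: censored
  trc <- staircase_traj(c(0, 10), c(10, 20))
  expect_true(is.na(first_passage(trc, 40, "up")))
  # downward crossing
  trd <- staircase_traj(c(0, 5, 10), c(50, 20, 0))
  expect_equal(first_passage(trd, 0, "down"), 10)
  expect_error(first_passage(tr, 60, "up"), "threshold")
})

test_that("efficiency curve counts uncensored latencies cumulatively", {
  expect_equal(efficiency_curve(c(1, 2, NA, NA), c(1.5, 3)), c(25, 50))
  # all reach within horizon
  expect_equal(efficiency_curve(c(1, 2, 3), 5), 100)
  # all censored
  expect_equal(efficiency_curve(c(NA_real_, NA_real_), c(1, 10)), c(0, 0))
  # stepwise non-decreasing
  lat <- c(0.5, 4, 8, NA, 2, 2)
  curve <- efficiency_curve(lat, seq(0, 10, by = 0.5))
  expect_true(all(diff(curve) >= 0))
  expect_true(all(curve >= 0 & curve <= 100))
})

test_that("latency histogram is normalized by ensemble size with censored mass aside", {
  lat <- days_to_tau(c(3.2, 3.9, 5.1, 5.5))
  h <- latency_histogram(lat)
  expect_equal(h$f_L[4], 0.5)   # day bin [3,4)
  expect_equal(h$f_L[6], 0.5)   # day bin [5,6)
  expect_equal(sum(h$f_L), 1)
  # with censoring, histogram mass + censored mass = 1
  lat2 <- c(lat, NA, NA)
  h2 <- latency_histogram(lat2)
  expect_equal(sum(h2$f_L) + h2$censored_fraction, 1)
  expect_equal(h2$censored_fraction, 1 / 3)
  # all censored: flagged empty histogram
  expect_warning(h3 <- latency_histogram(c(NA_real_, NA_real_)), "censored")
  expect_true(h3$all_censored)
})

test_that("variability statistics match closed forms on realized latencies", {
  lat <- days_to_tau(c(3, 3, 5, 5))
  v <- latency_variability(lat)
  expect_equal(v$sd_days, sd(c(3, 3, 5, 5)))
  expect_equal(v$sd_days, 1.1547, tolerance = 1e-4)
  expect_equal(v$mean_days, 4)
  expect_equal(v$iqr_days, IQR(c(3, 3, 5, 5)))
  vc <- latency_variability(c(lat, NA))
  expect_equal(vc$n_censored, 1)
  expect_equal(vc$sd_days, v$sd_days)  # censored excluded from spread
})

test_that("ensemble summary ties efficiency to the censored fraction exactly", {
  lat <- c(days_to_tau(c(2, 4, 6)), NA, NA)
  res <- epigrn:::make_ensemble_result(lat, tau_end = 201.6, name = "toy")
  expect_equal(res$efficiency_final, 100 * (1 - 2 / 5))
  expect_true(all(diff(res$efficiency_curve$pct) >= 0))
  s <- summary(res)
  expect_equal(s$censored_n, 2)
  expect_equal(s$efficiency_final, 60)
  expect_equal(s$latency_mean_days, 4)
})
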