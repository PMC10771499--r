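test_that("an empty reaction system leaves the state constant", {
  p <- grn_params()
  sys <- build_reaction_system(p)
  sys <- subset_system(sys, "^$")  # no channels
  init <- initial_state(p, "active")
  tr <- simulate_grn(sys, init, sim_config(tau_end = 20, seed = 3))
  expect_equal(tr$event_count, 0)
  expect_equal(max(abs(sweep(tr$states, 2, init))), 0)
})

test_that("identical seeds give bit-identical trajectories, different seeds differ", {
  p <- grn_params()
  sys <- build_reaction_system(p, overexpression_schedule(O = 320))
  init <- initial_state(p, "repressed")
  cfg <- sim_config(tau_end = 30, seed = 5)
  t1 <- simulate_grn(sys, init, cfg, traj_index = 2)
  t2 <- simulate_grn(sys, init, cfg, traj_index = 2)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$event_count, t2$event_count)
  t3 <- simulate_grn(sys, init, cfg, traj_index = 3)
  expect_false(identical(t1$states, t3$states))
})

test_that("nucleosome conservation holds at every sample of a full run", {
  p <- grn_params()
  sys <- build_reaction_system(p, overexpression_schedule(O = 320, T = 160))
  tr <- simulate_grn(sys, initial_state(p, "repressed"),
                     sim_config(tau_end = 100, seed = 9))
  for (g in 0:2)
    expect_true(all(rowSums(tr$states[, 5 * g + 1:5]) == p$D_tot))
  expect_true(all(tr$states >= 0))
})

test_that("pure birth-death protein subsystem reaches its Poisson stationary mean", {
  p <- grn_params()
  bd <- birth_death_system(p, n_A = 10)   # birth p_bar*gamma*10, mean 50
  cfg <- sim_config(tau_end = 40, sample_grid = c(0, 40), seed = 100)
  n <- 2000
  xs <- vapply(seq_len(n), function(i)
    simulate_grn(bd$system, bd$init, cfg, i)$states[2, "X_O"], numeric(1))
  lambda <- p$p_bar_O * 10
  se <- sqrt(lambda / n)  # Poisson variance = mean
  expect_lt(abs(mean(xs) - lambda), 3 * se)
  expect_lt(abs(var(xs) / lambda - 1), 0.15)  # Fano factor near 1
})

test_that("piecewise-constant inputs switch production on and off exactly", {
  p <- grn_params()
  sched <- overexpression_schedule(
    O = data.frame(tau_start = 0, tau_end = 25, u = 400))
  sys <- build_reaction_system(p, sched)
  sys <- subset_system(sys, "^O\\.P[23]$")  # input + decay only
  init <- initial_state(p, "unmodified")
  cfg <- sim_config(tau_end = 80, sample_grid = c(0, 25, 80), seed = 11)
  xs <- t(vapply(1:300, function(i)
    simulate_grn(sys, init, cfg, i)$states[, "X_O"], numeric(3)))
  # by tau 25 (5 decay time constants) X ~ 400; 55 tau later it has decayed
  expect_lt(abs(mean(xs[, 2]) - 400), 3 * sqrt(400 / 300) + 1)
  expect_lt(mean(xs[, 3]), 5)
})

test_that("binomial division halves proteins on average", {
  p <- grn_params()
  sys <- build_reaction_system(p, division = TRUE)
  sys <- subset_system(sys, "^$")  # partitioning only, no reactions
  init <- initial_state(p, "unmodified")
  init["X_O"] <- 100
  cfg <- sim_config(tau_end = 1.1, sample_grid = c(0, 1.1), seed = 13,
                    division_mode = "binomial", division_period = 1)
  xs <- vapply(1:1000, function(i)
    simulate_grn(sys, init, cfg, i)$states[2, "X_O"], numeric(1))
  se <- sqrt(100 * 0.25 / 1000)
  expect_lt(abs(mean(xs) - 50), 3 * se)
})

test_that("division-mode CpG loss follows the eta/2 maintenance rule", {
  base <- initial_state(grn_params(), "unmodified")
  run_div <- function(eta) {
    p <- grn_params(eta = eta)
    sys <- subset_system(build_reaction_system(p, division = TRUE), "^$")
    init <- base
    init["O.D"] <- 0; init["O.R1"] <- p$D_tot
    cfg <- sim_config(tau_end = 1.1, sample_grid = c(0, 1.1), seed = 17,
                      division_mode = "binomial", division_period = 1)
    vapply(1:400, function(i)
      simulate_grn(sys, init, cfg, i)$states[2, "O.R1"], numeric(1))
  }
  expect_true(all(run_div(0) == 50))        # perfect maintenance
  r1 <- run_div(1)                          # no maintenance: Binomial(50, 1/2)
  expect_lt(abs(mean(r1) - 25), 3 * sqrt(50 * 0.25 / 400))
  r05 <- run_div(0.5)                       # lose each with prob 1/4
  expect_lt(abs(mean(r05) - 37.5), 3 * sqrt(50 * 0.25 * 0.75 / 400))
})

test_that("binomial partitioning reproduces the first-order dilution half-life", {
  p <- grn_params(eps_d = 0.2)
  sys <- subset_system(build_reaction_system(p, division = TRUE), "^$")
  init <- initial_state(p, "unmodified")
  init["X_O"] <- 400
  Tdiv <- log(2) / p$eps_d
  horizon <- 2 * Tdiv + 0.1
  cfg <- sim_config(tau_end = horizon, sample_grid = c(0, horizon), seed = 19,
                    division_mode = "binomial")
  xs <- vapply(1:500, function(i)
    simulate_grn(sys, init, cfg, i)$states[2, "X_O"], numeric(1))
  target <- 400 * exp(-p$eps_d * horizon)   # ~ 100
  expect_lt(abs(mean(xs) - target) / target, 0.10)
})

test_that("division mode conserves nucleosome totals through partitioning", {
  p <- grn_params()
  sys <- build_reaction_system(p, overexpression_schedule(O = 320),
                               division = TRUE)
  cfg <- sim_config(tau_end = 30, seed = 23, division_mode = "binomial")
  tr <- simulate_grn(sys, initial_state(p, "repressed"), cfg)
  for (g in 0:2)
    expect_true(all(rowSums(tr$states[, 5 * g + 1:5]) == p$D_tot))
})

test_that("trajectory export is tidy and round-trips through CSV", {
  p <- grn_params()
  sys <- build_reaction_system(p)
  tr <- simulate_grn(sys, initial_state(p, "active"),
                     sim_config(tau_end = 5, seed = 1))
  df <- as.data.frame(tr, replicate = 7)
  expect_equal(nrow(df), 3 * length(tr$times))
  expect_setequal(unique(df$gene), c("O", "T", "J"))
  expect_equal(df$day, df$tau / 9.6)
  tmp <- tempfile(fileext = ".csv")
  write_trajectory(tr, tmp, replicate = 7)
  back <- utils::read.csv(tmp)
  expect_equal(back$n_A, df$n_A)
  unlink(tmp)
})
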