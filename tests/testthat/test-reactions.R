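test_that("the full network has 30 channels per gene, 90 total", {
  sys <- build_reaction_system(grn_params())
  expect_equal(nrow(sys$channels), 90)
  expect_equal(unname(table(factor(sys$channels$gene, c("O", "T", "J")))),
               rep(30L, 3), ignore_attr = TRUE)
  # division-mode system drops A3, K4a/b, M3a/b, P2 per gene
  div <- build_reaction_system(grn_params(), division = TRUE)
  expect_equal(nrow(div$channels), 90 - 3 * 6)
  expect_false(any(grepl("A3|K4|M3|P2", div$channels$label)))
})

test_that("every chromatin update conserves the nucleosome total", {
  sys <- build_reaction_system(grn_params())
  for (g in 1:3) {
    rows <- 5 * (g - 1) + 1:5
    expect_true(all(colSums(sys$update[rows, , drop = FALSE]) == 0 |
                    grepl("P[13]$", colnames(sys$update))))
    # protein channels never touch nucleosome rows
    pcols <- grepl(paste0("^", c("O", "T", "J")[g], "\\.P"),
                   colnames(sys$update))
    expect_true(all(sys$update[1:15, pcols] == 0))
  }
})

test_that("propensities are non-negative on random reachable states", {
  p <- grn_params()
  sys <- build_reaction_system(p, overexpression_schedule(O = 100, T = 5))
  set.seed(42)
  for (k in 1:50) {
    st <- c(as.vector(vapply(1:3, function(g)
      as.numeric(stats::rmultinom(1, p$D_tot, runif(5))), numeric(5))),
      stats::rpois(3, 80))
    a <- propensities(sys, st, tau = runif(1, 0, 100))
    expect_true(all(a >= 0))
  }
})

test_that("boundary state: fully active gene with no modifiers leaves only
           A3, A4, P1, P2 active", {
  p <- grn_params()
  sys <- build_reaction_system(p)  # no overexpression
  st <- state_with_O(p, c(0, p$D_tot, 0, 0, 0), X = c(100, 0, 0))
  a <- propensities(sys, st, 0)
  aO <- a[grepl("^O\\.", names(a))]
  pos <- names(aO[aO > 0])
  expect_setequal(pos, c("O.A3", "O.A4", "O.P1", "O.P2"))
})

test_that("zero overexpression means zero input propensity everywhere", {
  sys <- build_reaction_system(grn_params())
  st <- initial_state(sys$params, "active")
  a <- propensities(sys, st, 10)
  expect_true(all(a[grepl("P3$", names(a))] == 0))
})

test_that("modifier counts scale exactly their own erasure families", {
  p <- grn_params()
  sys <- build_reaction_system(p)
  st <- state_with_O(p, c(10, 10, 10, 10, 10), X = c(50, 100, 100))
  st[6:10] <- c(10, 10, 10, 10, 10)   # T gene composition
  a0 <- propensities(sys, st, 0)
  up <- st; up[17] <- 200             # double TET1
  a1 <- propensities(sys, up, 0)
  tet <- grepl("M[45]", names(a0))
  expect_equal(a1[tet], 2 * a0[tet])
  expect_equal(a1[!tet & !grepl("P2$", names(a0))],
               a0[!tet & !grepl("P2$", names(a0))])
  upj <- st; upj[18] <- 300           # triple JMJD2
  a2 <- propensities(sys, upj, 0)
  jmj <- grepl("K[56]", names(a0))
  expect_equal(a2[jmj], 3 * a0[jmj])
})

test_that("channels built from (alpha, r) equal channels from alpha_prime", {
  s1 <- build_reaction_system(grn_params(alpha = 0.4, r = 5))
  s2 <- build_reaction_system(grn_params(alpha = 0.4, alpha_prime = 2.0))
  expect_equal(s1$channels$rate, s2$channels$rate)
})

test_that("compiled propensity evaluator matches the R reference", {
  p <- grn_params()
  sched <- overexpression_schedule(
    O = 320, T = data.frame(tau_start = 10, tau_end = 50, u = 80))
  sys <- build_reaction_system(p, sched)
  set.seed(7)
  for (tau in c(0, 9.9, 10.1, 49.9, 60)) {
    st <- c(as.vector(vapply(1:3, function(g)
      as.numeric(stats::rmultinom(1, p$D_tot, runif(5))), numeric(5))),
      stats::rpois(3, 150))
    aR <- propensities(sys, st, tau)
    aC <- epigrn:::ssa_props_cpp(
      sys$channels$rate, as.integer(sys$channels$s1),
      as.integer(sys$channels$s2), as.integer(sys$channels$mod),
      st, schedule_at(sched, tau), p$K_A, p$p_bar_T * p$D_tot,
      p$p_bar_J * p$D_tot)
    expect_equal(unname(aR), as.numeric(aC), tolerance = 1e-12)
  }
})

test_that("schedules validate and evaluate piecewise", {
  sch <- overexpression_schedule(
    O = 320, T = data.frame(tau_start = c(0, 50), tau_end = c(20, 80),
                            u = c(10, 30)))
  expect_equal(unname(schedule_at(sch, 0)), c(320, 10, 0))
  expect_equal(unname(schedule_at(sch, 30)), c(320, 0, 0))
  expect_equal(unname(schedule_at(sch, 79.9)), c(320, 30, 0))
  expect_error(overexpression_schedule(O = -1), "gene O")
  expect_error(overexpression_schedule(
    T = data.frame(tau_start = c(0, 5), tau_end = c(10, 15), u = c(1, 1))),
    "overlap")
})

test_that("sequential schedule covers its boundary cases", {
  s <- sequential_schedule(320, 100, 200, u_O = 160)
  expect_equal(unname(schedule_at(s, 50)), c(160, 320, 0))
  expect_equal(unname(schedule_at(s, 150)), c(160, 0, 320))
  # switch at the end: pure transient TET1
  s2 <- sequential_schedule(320, 200, 200)
  expect_equal(unname(schedule_at(s2, 100)), c(0, 320, 0))
  expect_equal(max(s2$J$u), 0)
  # switch at 0: pure JMJD2
  s3 <- sequential_schedule(320, 0, 200)
  expect_equal(max(s3$T$u), 0)
  expect_equal(unname(schedule_at(s3, 100)), c(0, 0, 320))
  expect_error(sequential_schedule(320, 300, 200), "switch_tau")
})
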