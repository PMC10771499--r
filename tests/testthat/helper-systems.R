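# Shared fixture builders (all fixtures are generated in code).

# Subset a system to the channels whose labels match `pattern`.
subset_system <- function(sys, pattern) {
  keep <- grepl(pattern, sys$channels$label)
  sys$channels <- sys$channels[keep, , drop = FALSE]
  sys$update <- sys$update[, keep, drop = FALSE]
  sys
}

# A pure protein birth-death system for gene O with the chromatin frozen at
# n_A active nucleosomes (only P1/P2 channels retained).
birth_death_system <- function(params, n_A) {
  sys <- build_reaction_system(params)
  sys <- subset_system(sys, "^O\\.P[12]$")
  init <- initial_state(params, "unmodified")
  init["O.D"] <- params$D_tot - n_A
  init["O.A"] <- n_A
  list(system = sys, init = init)
}

# State with given single-gene composition for gene O, frozen proteins.
state_with_O <- function(params, comp, X = c(0, 0, 0)) {
  s <- initial_state(params, "unmodified")
  s[1:5] <- comp
  s[16:18] <- X
  s
}

run_latencies <- function(params, sched, N, seed, init = "repressed",
                          dirn = "up", thr = 40, tau_end = 201.6,
                          division = FALSE) {
  sys <- build_reaction_system(params, sched, division = division)
  cfg <- sim_config(tau_end = tau_end, seed = seed, sample_dt = 0.96,
                    division_mode = if (division) "binomial" else "off")
  st <- initial_state(params, init)
  vapply(seq_len(N), function(i)
    first_passage(simulate_grn(sys, st, cfg, i), thr, dirn), numeric(1))
}
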