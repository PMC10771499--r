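#' Simulation configuration
#'
#' @param tau_end normalized horizon (default 201.6, i.e. 21 days).
#' @param sample_dt spacing of the recording grid in \eqn{\tau} units
#'   (default 0.96, i.e. 0.1 day); ignored if `sample_grid` is given.
#' @param sample_grid explicit sorted vector of record times in
#'   `[0, tau_end]`.
#' @param seed integer base seed of the per-trajectory RNG stream.
#' @param division_mode `"off"` for first-order dilution kinetics, or
#'   `"binomial"` for deterministic synchronous divisions with binomial
#'   partitioning of molecules and marks.
#' @param division_period time between divisions in the binomial mode;
#'   defaults to `log(2)/eps_d` of the system's parameters, matching the
#'   half-life of the first-order dilution it replaces.
#' @return An object of class `grn_config`.
#' @export
sim_config <- function(tau_end = 201.6, sample_dt = 0.96, sample_grid = NULL,
                       seed = 1L, division_mode = c("off", "binomial"),
                       division_period = NULL) {
  division_mode <- match.arg(division_mode)
  if (!is.numeric(tau_end) || length(tau_end) != 1 || tau_end < 0)
    stop("'tau_end' must be a single number >= 0")
  if (is.null(sample_grid)) {
    sample_grid <- if (tau_end > 0) seq(0, tau_end, by = sample_dt) else 0
    if (sample_grid[length(sample_grid)] < tau_end)
      sample_grid <- c(sample_grid, tau_end)
  } else {
    sample_grid <- sort(as.numeric(sample_grid))
    if (any(sample_grid < 0) || any(sample_grid > tau_end))
      stop("'sample_grid' must lie within [0, tau_end]")
  }
  if (!is.null(division_period) && division_period <= 0)
    stop("'division_period' must be > 0")
  structure(list(tau_end = tau_end, sample_grid = sample_grid,
                 seed = as.integer(seed), division_mode = division_mode,
                 division_period = division_period),
            class = "grn_config")
}

#' Canonical initial states
#'
#' @param params a [grn_params()] object.
#' @param type `"active"`: all nucleosomes of every gene carry activating
#'   marks and proteins sit at their stationary counts `p_bar * D_tot`
#'   (pluripotent-like state); `"repressed"`: all nucleosomes carry both
#'   repressive marks (CpGme + H3K9me3) and protein counts are 0
#'   (differentiated, DNA-methylated state — the conservative,
#'   slowest-reactivating composition); `"unmodified"`: all nucleosomes bare,
#'   proteins 0.
#' @return Named numeric vector of length 18.
#' @export
initial_state <- function(params, type = c("active", "repressed", "unmodified")) {
  type <- match.arg(type)
  s <- stats::setNames(numeric(18), state_names())
  Dt <- params$D_tot
  for (g in 1:3) {
    o <- 5 * (g - 1)
    s[o + switch(type, active = 2, repressed = 5, unmodified = 1)] <- Dt
  }
  if (type == "active")
    s[16:18] <- round(c(params$p_bar_O, params$p_bar_T, params$p_bar_J) * Dt)
  s
}

#' Simulate one trajectory of the reaction system
#'
#' Runs Gillespie's direct-method stochastic simulation algorithm on the
#' channel table of a [build_reaction_system()] system, recording the full
#' state on the configuration's sample grid. Piecewise-constant
#' overexpression inputs are handled exactly by capping proposed jumps at
#' schedule breakpoints and redrawing. In the binomial division mode
#' (`config$division_mode == "binomial"`, with a system built with
#' `division = TRUE`), first-order dilution channels are absent and at each
#' division time every protein molecule and activating/H3K9me3 mark is
#' retained with probability 1/2 while each CpGme mark is lost with
#' probability `eta/2` (the maintained fraction of the diluted half
#' survives).
#'
#' Identical `(system, init, config)` including the seed give bit-identical
#' trajectories; trajectory `traj_index` uses an RNG stream derived from
#' `(config$seed, traj_index)`, so ensembles and paired-seed arms are
#' reproducible element-wise.
#'
#' @param system a `grn_system`.
#' @param init numeric length-18 initial state (see [initial_state()]).
#' @param config a [sim_config()].
#' @param traj_index integer index of the trajectory within an ensemble.
#' @return A `grn_trajectory`: list with `times` (the sample grid), `states`
#'   (matrix, one row per sample, columns [state_names()]), `event_count`.
#' @examples
#' sys <- build_reaction_system(grn_params())
#' tr <- simulate_grn(sys, initial_state(sys$params, "active"),
#'                    sim_config(tau_end = 5, seed = 1))
#' @export
simulate_grn <- function(system, init, config, traj_index = 0L) {
  stopifnot(inherits(system, "grn_system"), inherits(config, "grn_config"))
  if (length(init) != 18 || any(init < 0))
    stop("'init' must be a non-negative state vector of length 18")
  p <- system$params
  Dt <- p$D_tot
  for (g in 1:3) {
    o <- 5 * (g - 1)
    if (abs(sum(init[o + 1:5]) - Dt) > 1e-9)
      stop("each gene's five nucleosome counts must sum to D_tot")
  }
  division <- config$division_mode == "binomial"
  if (division != isTRUE(system$division))
    stop("config division mode and system 'division' flag must agree")
  division_period <- config$division_period
  if (division && is.null(division_period)) division_period <- log(2) / p$eps_d
  if (!division) division_period <- 0

  st <- schedule_table(system$schedule, max(config$tau_end, 1e-12))
  ch <- system$channels
  res <- ssa_run_cpp(
    rate = ch$rate, s1 = as.integer(ch$s1), s2 = as.integer(ch$s2),
    mod = as.integer(ch$mod), update = system$update,
    sched_breaks = st$breaks, sched_levels = st$levels,
    init = as.numeric(init), grid = config$sample_grid,
    tau_end = config$tau_end,
    K_A = p$K_A, denomT = p$p_bar_T * Dt, denomJ = p$p_bar_J * Dt,
    base_seed = config$seed, traj_index = as.integer(traj_index),
    division = division, division_period = division_period, eta = p$eta,
    max_events = 5e8)
  states <- res$states
  colnames(states) <- state_names()
  structure(list(times = config$sample_grid, states = states,
                 event_count = res$event_count, params = p),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d samples on tau = [%g, %g] (%.1f days), %g reaction events\n",
    length(x$times), min(x$times), max(x$times), tau_to_days(max(x$times)),
    x$event_count))
  last <- x$states[nrow(x$states), ]
  cat(sprintf("  final n_A (O, T, J): %g, %g, %g of D_tot = %d\n",
              last["O.A"], last["T.A"], last["J.A"], as.integer(x$params$D_tot)))
  cat(sprintf("  final proteins (X_O, X_T, X_J): %g, %g, %g\n",
              last["X_O"], last["X_T"], last["X_J"]))
  invisible(x)
}

#' @export
as.data.frame.grn_trajectory <- function(x, ..., replicate = NA_integer_) {
  out <- do.call(rbind, lapply(1:3, function(g) {
    o <- 5 * (g - 1)
    data.frame(tau = x$times, day = tau_to_days(x$times), gene = GENES[g],
               n_D = x$states[, o + 1], n_A = x$states[, o + 2],
               n_R1 = x$states[, o + 3], n_R2 = x$states[, o + 4],
               n_R12 = x$states[, o + 5],
               X_O = x$states[, 16], X_T = x$states[, 17],
               X_J = x$states[, 18], replicate = replicate)
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.grn_trajectory <- function(x, ...) {
  day <- tau_to_days(x$times)
  graphics::matplot(day, x$states[, c("O.A", "T.A", "J.A")], type = "s",
                    lty = 1, col = c("black", "goldenrod3", "deeppink3"),
                    xlab = "time (days)", ylab = "active nucleosomes n_A",
                    ylim = c(0, x$params$D_tot), ...)
  graphics::legend("right", legend = c("OCT4", "TET1", "JMJD2"), lty = 1,
                   col = c("black", "goldenrod3", "deeppink3"), bty = "n")
  invisible(x)
}
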