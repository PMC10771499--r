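#' Specify a differentiation or reprogramming experiment
#'
#' Bundles parameters, initial condition, overexpression schedule, ensemble
#' size and thresholds for one in-silico study arm.
#'
#' @param name label for reports.
#' @param params a [grn_params()] object.
#' @param init `"active"`, `"repressed"`, or an explicit length-18 state.
#' @param schedule a [overexpression_schedule()]; `NULL` = no input.
#' @param N ensemble size (number of independent trajectories).
#' @param seed base seed; trajectory `i` uses the stream `(seed, i)`, so two
#'   arms sharing `seed` and `N` are paired replicate-by-replicate.
#' @param threshold_on OCT4 active-mark count defining reactivation
#'   (default 40 of `D_tot = 50`).
#' @param threshold_off OCT4 active-mark count defining silencing
#'   (default 0).
#' @param tau_end horizon (default 201.6, 21 days).
#' @param sample_dt recording grid spacing in \eqn{\tau} units.
#' @param division_mode `"off"` or `"binomial"` (see [simulate_grn()]).
#' @return An object of class `grn_experiment_spec`.
#' @export
experiment_spec <- function(name = "experiment", params = grn_params(),
                            init = c("repressed", "active"),
                            schedule = NULL, N = 100, seed = 1L,
                            threshold_on = 40, threshold_off = 0,
                            tau_end = 201.6, sample_dt = 0.96,
                            division_mode = c("off", "binomial")) {
  if (is.character(init)) init <- match.arg(init)
  division_mode <- match.arg(division_mode)
  stopifnot(inherits(params, "grn_params"))
  if (is.null(schedule)) schedule <- overexpression_schedule()
  if (!(threshold_off >= 0 && threshold_off < threshold_on &&
        threshold_on <= params$D_tot))
    stop("thresholds must satisfy 0 <= threshold_off < threshold_on <= D_tot")
  if (N < 1) stop("'N' must be >= 1")
  structure(list(name = name, params = params, init = init,
                 schedule = schedule, N = as.integer(N),
                 seed = as.integer(seed), threshold_on = threshold_on,
                 threshold_off = threshold_off, tau_end = tau_end,
                 sample_dt = sample_dt, division_mode = division_mode),
            class = "grn_experiment_spec")
}

resolve_init <- function(spec) {
  if (is.character(spec$init)) initial_state(spec$params, spec$init)
  else {
    init <- as.numeric(spec$init)
    if (length(init) != 18) stop("explicit 'init' must have length 18")
    init
  }
}

# Run the ensemble of a spec and extract first-passage latencies.
run_ensemble <- function(spec, threshold, direction,
                         keep_trajectories = FALSE) {
  division <- spec$division_mode == "binomial"
  sys <- build_reaction_system(spec$params, spec$schedule,
                               division = division)
  cfg <- sim_config(tau_end = spec$tau_end, sample_dt = spec$sample_dt,
                    seed = spec$seed, division_mode = spec$division_mode)
  init <- resolve_init(spec)
  lat <- numeric(spec$N)
  trajs <- if (keep_trajectories) vector("list", spec$N) else NULL
  for (i in seq_len(spec$N)) {
    tr <- simulate_grn(sys, init, cfg, traj_index = i)
    lat[i] <- first_passage(tr, threshold, direction)
    if (keep_trajectories) trajs[[i]] <- tr
  }
  res <- make_ensemble_result(lat, spec$tau_end, name = spec$name,
                              threshold = threshold, direction = direction)
  res$spec <- spec
  res$trajectories <- trajs
  res
}

#' Differentiation study: spontaneous OCT4 silencing
#'
#' Simulates an ensemble starting from the fully active (pluripotent-like)
#' state with no exogenous input and records, per trajectory, the first time
#' the OCT4 active-mark count falls to `threshold_off` (silencing latency;
#' censored at the horizon if never reached). The ensemble silencing
#' fraction over time is the resulting efficiency curve.
#'
#' @param spec an [experiment_spec()] with `init = "active"`; its schedule
#'   must be identically zero (differentiation is input-free).
#' @param keep_trajectories retain the per-trajectory state paths.
#' @return A `grn_ensemble` (direction `"down"`).
#' @export
run_differentiation <- function(spec, keep_trajectories = FALSE) {
  stopifnot(inherits(spec, "grn_experiment_spec"))
  if (is.character(spec$init) && spec$init != "active")
    spec$init <- "active"
  levels <- vapply(spec$schedule[c("O", "T", "J")],
                   function(seg) max(seg$u), numeric(1))
  if (any(levels > 0))
    stop("differentiation is input-free: all overexpression levels must be 0")
  run_ensemble(spec, spec$threshold_off, "down",
               keep_trajectories = keep_trajectories)
}

#' Reprogramming study: overexpression-driven OCT4 reactivation
#'
#' Simulates an ensemble starting from the fully repressed state (all
#' nucleosomes carrying both repressive marks, proteins at 0) under the
#' spec's overexpression schedule, and records per-trajectory reactivation
#' latency: the first time the OCT4 active-mark count reaches
#' `threshold_on`. Efficiency `%O^A` and the latency distribution follow
#' from the latencies.
#'
#' @param spec an [experiment_spec()]; at least one overexpression segment
#'   should be positive for reactivation to occur.
#' @param keep_trajectories retain the per-trajectory state paths.
#' @return A `grn_ensemble` (direction `"up"`).
#' @export
run_reprogramming <- function(spec, keep_trajectories = FALSE) {
  stopifnot(inherits(spec, "grn_experiment_spec"))
  if (is.character(spec$init) && spec$init != "repressed")
    spec$init <- "repressed"
  run_ensemble(spec, spec$threshold_on, "up",
               keep_trajectories = keep_trajectories)
}

#' Parameter-grid comparison of reprogramming arms
#'
#' Cross-product sweep over parameter and/or schedule settings, running
#' [run_reprogramming()] in each cell with shared base seeds across cells
#' (paired-seed variance reduction: cell `i`'s trajectory `j` uses the same
#' RNG stream in every cell).
#'
#' @param base_spec an [experiment_spec()] providing all settings not swept.
#' @param grid named list; each element is a vector of values for one
#'   [grn_params()] field, or (for schedules) a list of `grn_schedule`
#'   objects under the name `"schedule"`.
#' @return A `grn_grid` object: list with `results` (long-format data frame,
#'   one row per cell: swept values, `efficiency_final`, latency summaries,
#'   `censored_n`) and `ensembles` (the per-cell `grn_ensemble`s).
#' @examples \donttest{
#' base <- experiment_spec(N = 10, schedule = overexpression_schedule(O = 320))
#' g <- run_comparison_grid(base, list(eps_d = c(0.1, 0.3)))
#' g$results
#' }
#' @export
run_comparison_grid <- function(base_spec, grid) {
  stopifnot(inherits(base_spec, "grn_experiment_spec"))
  if (!is.list(grid) || length(grid) == 0 || is.null(names(grid)) ||
      any(!nzchar(names(grid))))
    stop("'grid' must be a non-empty named list")
  param_fields <- setdiff(names(grid), "schedule")
  bad <- setdiff(param_fields, names(base_spec$params))
  if (length(bad))
    stop("unknown grid parameter(s): ", paste(bad, collapse = ", "))

  cells <- expand.grid(lapply(grid, seq_along))
  ensembles <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    spec <- base_spec
    desc <- list()
    pars <- as.list(spec$params)
    for (f in param_fields) {
      v <- grid[[f]][[cells[k, f]]]
      pars[[f]] <- v
      desc[[f]] <- v
    }
    # re-derive the dependent member of the (r, alpha_prime) pair
    if ("alpha_prime" %in% param_fields) pars$r <- NULL
    else pars$alpha_prime <- NULL
    pars <- pars[!vapply(pars, is.null, logical(1))]
    spec$params <- do.call(grn_params, pars)
    if ("schedule" %in% names(grid)) {
      spec$schedule <- grid$schedule[[cells[k, "schedule"]]]
      desc$schedule <- names(grid$schedule)[cells[k, "schedule"]]
      if (is.null(desc$schedule)) desc$schedule <- as.character(cells[k, "schedule"])
    }
    spec$name <- paste(vapply(names(desc), function(nm)
      paste0(nm, "=", desc[[nm]]), character(1)), collapse = ", ")
    res <- run_reprogramming(spec)
    ensembles[[k]] <- res
    rows[[k]] <- cbind(as.data.frame(desc, stringsAsFactors = FALSE),
                       summary(res)[, -1])
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, ensembles = ensembles,
                 base_spec = base_spec, grid = grid), class = "grn_grid")
}

#' @export
print.grn_grid <- function(x, ...) {
  cat(sprintf("Comparison grid: %d cells, N = %d trajectories per cell\n",
              nrow(x$results), x$base_spec$N))
  print(x$results, digits = 3)
  invisible(x)
}
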