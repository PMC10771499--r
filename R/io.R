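#' Load an experiment specification from a YAML/JSON config file
#'
#' The config has top-level keys `experiment` (`"differentiate"`,
#' `"reprogram"` or `"compare"`), and optional blocks `name`, `model`
#' (any [grn_params()] field), `schedule` (per-gene `O`/`T`/`J` levels or
#' segment lists), `init`, `run` (`N`, `seed`, `tau_end`, `threshold_on`,
#' `threshold_off`, `sample_dt`, `division_mode`) and, for `compare`, a
#' `grid` block mapping parameter names to value vectors. Unknown keys are
#' rejected; omitted keys take the documented defaults (`D_tot = 50`,
#' `tau_end = 201.6`, `N = 100`, activation threshold 40).
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return An [experiment_spec()]; for `compare` configs the grid is
#'   attached as attribute `"grid"` and the experiment kind as attribute
#'   `"experiment"` in all cases.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  spec_from_config(cfg)
}

spec_from_config <- function(cfg) {
  known_top <- c("experiment", "name", "model", "schedule", "init", "run",
                 "grid")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  experiment <- cfg$experiment
  if (is.null(experiment) ||
      !experiment %in% c("differentiate", "reprogram", "compare"))
    stop("config key 'experiment' must be one of ",
         "'differentiate', 'reprogram', 'compare'")

  model <- cfg$model
  if (!is.null(model)) {
    unknown <- setdiff(names(model), names(formals(grn_params)))
    if (length(unknown))
      stop("unknown model parameter(s): ", paste(unknown, collapse = ", "))
  }
  params <- do.call(grn_params, as.list(model))

  schedule <- if (is.null(cfg$schedule)) overexpression_schedule() else {
    unknown <- setdiff(names(cfg$schedule), c("O", "T", "J"))
    if (length(unknown))
      stop("unknown schedule gene(s): ", paste(unknown, collapse = ", "))
    args <- lapply(cfg$schedule, function(x) {
      if (is.list(x) && !is.data.frame(x))
        do.call(rbind, lapply(x, as.data.frame))
      else x
    })
    do.call(overexpression_schedule, args)
  }

  run <- if (is.null(cfg$run)) list() else cfg$run
  # YAML 1.1 treats a bare `N` key (and an `off` value) as booleans; undo
  names(run)[names(run) %in% c("FALSE", "n")] <- "N"
  if (isFALSE(run$division_mode)) run$division_mode <- "off"
  known_run <- c("N", "seed", "tau_end", "threshold_on", "threshold_off",
                 "sample_dt", "division_mode")
  unknown <- setdiff(names(run), known_run)
  if (length(unknown))
    stop("unknown run key(s): ", paste(unknown, collapse = ", "))

  init <- cfg$init
  if (is.null(init))
    init <- if (experiment == "differentiate") "active" else "repressed"

  spec <- experiment_spec(
    name = if (is.null(cfg$name)) experiment else cfg$name,
    params = params, init = init, schedule = schedule,
    N = run$N %||% 100, seed = run$seed %||% 1L,
    threshold_on = run$threshold_on %||% 40,
    threshold_off = run$threshold_off %||% 0,
    tau_end = run$tau_end %||% 201.6,
    sample_dt = run$sample_dt %||% 0.96,
    division_mode = run$division_mode %||% "off")
  attr(spec, "experiment") <- experiment
  if (experiment == "compare") {
    if (is.null(cfg$grid) || length(cfg$grid) == 0)
      stop("'compare' configs require a non-empty 'grid' block")
    attr(spec, "grid") <- cfg$grid
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise an experiment specification to a config list or file
#'
#' `save_config(load_config(path))` round-trips: the written file reloads
#' to an identical spec.
#'
#' @param spec an [experiment_spec()].
#' @param path optional output path (`.yaml` or `.json`); if `NULL` the
#'   config list is returned invisibly without writing.
#' @return The config list, invisibly.
#' @export
save_config <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "grn_experiment_spec"))
  p <- unclass(spec$params)
  model <- p[!vapply(p, is.null, logical(1))]
  model$r <- NULL  # alpha_prime is the stored member of the pair
  sched <- lapply(spec$schedule[c("O", "T", "J")], function(seg) {
    if (nrow(seg) == 1 && seg$tau_start == 0 && is.infinite(seg$tau_end))
      seg$u
    else lapply(seq_len(nrow(seg)), function(i) as.list(seg[i, ]))
  })
  cfg <- list(
    experiment = attr(spec, "experiment") %||% "reprogram",
    name = spec$name,
    model = model,
    schedule = sched,
    init = if (is.character(spec$init)) spec$init else as.numeric(spec$init),
    run = list(N = spec$N, seed = spec$seed, tau_end = spec$tau_end,
               threshold_on = spec$threshold_on,
               threshold_off = spec$threshold_off,
               sample_dt = spec$sample_dt,
               division_mode = spec$division_mode))
  if (!is.null(attr(spec, "grid"))) cfg$grid <- attr(spec, "grid")
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
    else yaml::write_yaml(cfg, path)
  }
  invisible(cfg)
}

#' Write ensemble results to a deterministic output layout
#'
#' Writes `results.csv` (one row per trajectory: replicate, latency in tau
#' and days, censoring flag), `efficiency_curve.csv`, `summary.json`
#' (efficiency, latency mean/SD/IQR, censored count, N) and
#' `manifest.json` (resolved config, seeds, package version, walltime,
#' file list) under `dir`.
#'
#' @param result a `grn_ensemble` from one of the experiment drivers.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_ensemble <- function(result, dir) {
  stopifnot(inherits(result, "grn_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  res_df <- data.frame(
    replicate = seq_len(result$N),
    latency_tau = result$latencies,
    latency_days = tau_to_days(replace(result$latencies,
                                       is.na(result$latencies), 0)),
    censored = result$censored)
  res_df$latency_days[res_df$censored] <- NA_real_
  utils::write.csv(res_df, file.path(dir, "results.csv"), row.names = FALSE)
  utils::write.csv(result$efficiency_curve,
                   file.path(dir, "efficiency_curve.csv"), row.names = FALSE)

  v <- result$variability
  summary_json <- list(
    name = result$name, N = result$N,
    efficiency_final = result$efficiency_final,
    latency_mean_days = v$mean_days, latency_sd_days = v$sd_days,
    latency_iqr_days = v$iqr_days, censored_n = v$n_censored)
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")

  files <- c("results.csv", "efficiency_curve.csv", "summary.json",
             "manifest.json")
  manifest <- list(
    package = "epigrn",
    version = as.character(utils::packageVersion("epigrn")),
    written = t0,
    config = if (!is.null(result$spec)) save_config(result$spec) else NULL,
    seed = if (!is.null(result$spec)) result$spec$seed else NULL,
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(result$spec))
    save_config(result$spec, file.path(dir, "config.resolved.yaml"))
  invisible(manifest)
}

#' Write a trajectory as tidy CSV
#'
#' One row per (sample time, gene): columns `tau`, `day`, `gene`, the five
#' nucleosome counts, the three protein counts and the replicate index.
#'
#' @param trajectory a `grn_trajectory`.
#' @param path output CSV path.
#' @param replicate replicate index recorded in the file.
#' @export
write_trajectory <- function(trajectory, path, replicate = 1L) {
  utils::write.csv(as.data.frame(trajectory, replicate = replicate), path,
                   row.names = FALSE)
  invisible(path)
}
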