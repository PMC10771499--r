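#' First-passage time of the OCT4 active-mark count
#'
#' Earliest sampled time at which the monitored quantity (by default the
#' OCT4 active-nucleosome count `O.A`) crosses a threshold.
#'
#' @param trajectory a `grn_trajectory`.
#' @param threshold crossing level, in `[0, D_tot]`.
#' @param direction `"up"` for first time `>= threshold` (reactivation
#'   latency), `"down"` for first time `<= threshold` (silencing).
#' @param column monitored state column (default `"O.A"`).
#' @return The first-passage time in \eqn{\tau} units, or `NA` if the
#'   trajectory never crosses within its horizon (censored).
#' @export
first_passage <- function(trajectory, threshold, direction = c("up", "down"),
                          column = "O.A") {
  direction <- match.arg(direction)
  stopifnot(inherits(trajectory, "grn_trajectory"))
  if (length(trajectory$times) == 0) stop("empty trajectory")
  if (threshold < 0 || threshold > trajectory$params$D_tot)
    stop("'threshold' must lie in [0, D_tot]")
  v <- trajectory$states[, column]
  hit <- if (direction == "up") v >= threshold else v <= threshold
  if (!any(hit)) return(NA_real_)
  trajectory$times[which(hit)[1]]
}

#' Ensemble efficiency curve
#'
#' Percentage of trajectories whose latency (first-passage time) is at most
#' each grid time: \eqn{\%O^A(\tau) = 100 \cdot \#\{L_i \le \tau\}/N}.
#' Censored trajectories (`NA` latency) never contribute.
#'
#' @param latencies numeric vector of first-passage times, `NA` = censored.
#' @param tau_grid evaluation times.
#' @return Numeric vector of percentages in `[0, 100]`, non-decreasing.
#' @examples
#' efficiency_curve(c(1, 2, NA, NA), c(1.5, 3))  # 25 then 50
#' @export
efficiency_curve <- function(latencies, tau_grid) {
  if (length(latencies) == 0) stop("at least one trajectory is required")
  vapply(tau_grid, function(tt)
    100 * sum(!is.na(latencies) & latencies <= tt) / length(latencies),
    numeric(1))
}

#' Normalized latency histogram
#'
#' Day-binned distribution of realized latencies, normalized by the ensemble
#' size `N` (so the histogram mass plus the censored fraction is 1). Bin `k`
#' covers days `[(k-1)*bin_days, k*bin_days)`.
#'
#' @param latencies first-passage times in \eqn{\tau} units, `NA` = censored.
#' @param bin_days bin width in days (default 1).
#' @return A list with `breaks_days`, `mids_days`, `f_L` (normalized
#'   frequencies), `censored_fraction`, `n`, and `all_censored` flag.
#' @export
latency_histogram <- function(latencies, bin_days = 1) {
  n <- length(latencies)
  if (n == 0) stop("at least one trajectory is required")
  obs_days <- tau_to_days(latencies[!is.na(latencies)])
  if (length(obs_days) == 0) {
    warning("all trajectories censored: empty latency histogram")
    return(list(breaks_days = numeric(0), mids_days = numeric(0),
                f_L = numeric(0), censored_fraction = 1, n = n,
                all_censored = TRUE))
  }
  k_max <- max(1, ceiling((max(obs_days) + 1e-9) / bin_days))
  breaks <- seq(0, k_max * bin_days, by = bin_days)
  counts <- tabulate(pmin(floor(obs_days / bin_days) + 1, k_max), k_max)
  list(breaks_days = breaks, mids_days = breaks[-1] - bin_days / 2,
       f_L = counts / n, censored_fraction = 1 - length(obs_days) / n,
       n = n, all_censored = FALSE)
}

#' Variability statistics of realized latencies
#'
#' Sample SD, IQR and coefficient of variation of the uncensored latencies,
#' reported in days, with the censored count alongside.
#'
#' @param latencies first-passage times in \eqn{\tau} units, `NA` = censored.
#' @return List with `sd_days`, `iqr_days`, `cv`, `mean_days`,
#'   `n_uncensored`, `n_censored`.
#' @export
latency_variability <- function(latencies) {
  obs <- tau_to_days(latencies[!is.na(latencies)])
  list(mean_days = if (length(obs)) mean(obs) else NA_real_,
       sd_days = if (length(obs) > 1) stats::sd(obs) else NA_real_,
       iqr_days = if (length(obs)) stats::IQR(obs) else NA_real_,
       cv = if (length(obs) > 1 && mean(obs) > 0)
         stats::sd(obs) / mean(obs) else NA_real_,
       n_uncensored = length(obs), n_censored = sum(is.na(latencies)))
}

# Assemble a grn_ensemble from per-trajectory latencies.
make_ensemble_result <- function(latencies, tau_end, name = "",
                                 threshold = NA, direction = "up",
                                 curve_points = 200) {
  tau_grid <- seq(0, tau_end, length.out = curve_points)
  res <- list(
    name = name, N = length(latencies), latencies = latencies,
    censored = is.na(latencies), threshold = threshold,
    direction = direction, tau_end = tau_end,
    efficiency_curve = data.frame(
      tau = tau_grid, day = tau_to_days(tau_grid),
      pct = efficiency_curve(latencies, tau_grid)),
    efficiency_final = efficiency_curve(latencies, tau_end),
    f_L = suppressWarnings(latency_histogram(latencies)),
    variability = latency_variability(latencies))
  class(res) <- "grn_ensemble"
  res
}

#' @export
print.grn_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble result%s: N = %d trajectories\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "", x$N))
  what <- if (x$direction == "up") "reactivation" else "silencing"
  cat(sprintf("  %s efficiency at %.1f days: %.1f%% (%d censored)\n",
              what, tau_to_days(x$tau_end), x$efficiency_final,
              sum(x$censored)))
  v <- x$variability
  if (v$n_uncensored > 0)
    cat(sprintf("  latency: mean %.2f d, SD %.2f d, IQR %.2f d\n",
                v$mean_days, v$sd_days, v$iqr_days))
  invisible(x)
}

#' @export
summary.grn_ensemble <- function(object, ...) {
  v <- object$variability
  out <- data.frame(
    name = object$name, N = object$N,
    efficiency_final = object$efficiency_final,
    latency_mean_days = v$mean_days, latency_sd_days = v$sd_days,
    latency_iqr_days = v$iqr_days, censored_n = v$n_censored)
  rownames(out) <- NULL
  out
}

#' @export
plot.grn_ensemble <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$efficiency_curve$day, x$efficiency_curve$pct, type = "s",
                 xlab = "time (days)", ylab = "%O^A", ylim = c(0, 100),
                 main = x$name, ...)
  h <- x$f_L
  if (!h$all_censored)
    graphics::barplot(h$f_L, names.arg = h$mids_days,
                      xlab = "latency (days)", ylab = "normalized frequency")
  invisible(x)
}
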