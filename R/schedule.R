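#' Piecewise-constant overexpression schedules
#'
#' An overexpression schedule assigns each gene product X in {OCT4, TET1,
#' JMJD2} a piecewise-constant exogenous input \eqn{\bar u_X(\tau)}: the
#' stationary number of molecules contributed by the artificial input (the
#' production channel fires at rate \eqn{\bar u_X \hat\gamma}, balancing
#' first-order decay).
#'
#' Each gene's schedule is a data frame with columns `tau_start`, `tau_end`,
#' `u` describing non-overlapping segments; outside all segments the input
#' is 0. A scalar is shorthand for a single segment covering `[0, Inf)`.
#'
#' @param O,T,J per-gene schedule: a scalar level, or a data frame with
#'   columns `tau_start`, `tau_end`, `u`.
#' @return An object of class `grn_schedule`.
#' @examples
#' overexpression_schedule(O = 320)                      # constant OCT4 input
#' overexpression_schedule(O = 320, T = data.frame(
#'   tau_start = 0, tau_end = 100, u = 160))             # transient TET1
#' @export
overexpression_schedule <- function(O = 0, T = 0, J = 0) {
  sch <- list(O = as_segments(O, "O"), T = as_segments(T, "T"),
              J = as_segments(J, "J"))
  class(sch) <- "grn_schedule"
  sch
}

as_segments <- function(x, gene) {
  if (is.numeric(x) && length(x) == 1) {
    if (is.na(x) || x < 0)
      stop(sprintf("overexpression level for gene %s must be >= 0", gene))
    return(data.frame(tau_start = 0, tau_end = Inf, u = as.numeric(x)))
  }
  if (!is.data.frame(x) || !all(c("tau_start", "tau_end", "u") %in% names(x)))
    stop(sprintf(
      "schedule for gene %s must be a scalar or a data frame with columns tau_start, tau_end, u",
      gene))
  x <- x[order(x$tau_start), c("tau_start", "tau_end", "u"), drop = FALSE]
  if (any(x$u < 0) || any(x$tau_start < 0))
    stop(sprintf("schedule for gene %s: negative level or start time", gene))
  if (any(x$tau_end <= x$tau_start))
    stop(sprintf("schedule for gene %s: segments must have tau_end > tau_start", gene))
  if (nrow(x) > 1 && any(x$tau_start[-1] < x$tau_end[-nrow(x)] - 1e-12))
    stop(sprintf("schedule for gene %s: overlapping segments", gene))
  rownames(x) <- NULL
  x
}

#' @export
print.grn_schedule <- function(x, ...) {
  cat("Overexpression schedule (levels u_bar, normalized time tau)\n")
  for (g in c("O", "T", "J")) {
    seg <- x[[g]]
    active <- seg[seg$u > 0, , drop = FALSE]
    if (nrow(active) == 0) {
      cat(sprintf("  %s: none\n", g))
    } else {
      cat(sprintf("  %s: %s\n", g, paste(
        sprintf("u = %g on [%g, %g)", active$u, active$tau_start,
                active$tau_end), collapse = "; ")))
    }
  }
  invisible(x)
}

#' Evaluate a schedule at a time point
#'
#' @param schedule a `grn_schedule`.
#' @param tau normalized time (scalar).
#' @return Named numeric vector `c(O=, T=, J=)` of input levels at `tau`.
#' @export
schedule_at <- function(schedule, tau) {
  stopifnot(inherits(schedule, "grn_schedule"))
  vapply(c(O = "O", T = "T", J = "J"), function(g) {
    seg <- schedule[[g]]
    hit <- seg$tau_start <= tau & tau < seg$tau_end
    if (any(hit)) seg$u[which(hit)[1]] else 0
  }, numeric(1))
}

# Internal: compress a schedule into global breakpoints and a 3 x K matrix of
# levels on each inter-breakpoint interval, truncated to [0, tau_end].
schedule_table <- function(schedule, tau_end) {
  bps <- sort(unique(c(0, tau_end, unlist(lapply(schedule[c("O", "T", "J")],
    function(seg) c(seg$tau_start, seg$tau_end))))))
  bps <- bps[bps >= 0 & bps <= tau_end]
  if (bps[length(bps)] < tau_end) bps <- c(bps, tau_end)
  mids <- (bps[-length(bps)] + bps[-1]) / 2
  levels <- vapply(mids, function(m) schedule_at(schedule, m), numeric(3))
  list(breaks = bps, levels = matrix(levels, nrow = 3))
}

#' Sequential TET1-then-JMJD2 overexpression schedule
#'
#' Builds the two-phase reprogramming input: TET1 overexpressed at `u_level`
#' on `[0, switch_tau)` to erase CpG methylation first, then JMJD2 at
#' `u_level` on `[switch_tau, tau_end)` to erase H3K9me3, with a constant
#' OCT4 input throughout. The boundary cases reduce to single-modifier
#' transient schedules (`switch_tau = tau_end`: TET1 only; `switch_tau = 0`:
#' JMJD2 only).
#'
#' @param u_level overexpression level for both modifiers (>= 0).
#' @param switch_tau time of the TET1 -> JMJD2 switch, in `[0, tau_end]`.
#' @param tau_end simulation horizon.
#' @param u_O constant OCT4 overexpression level.
#' @return A `grn_schedule`.
#' @export
sequential_schedule <- function(u_level, switch_tau, tau_end, u_O = 0) {
  if (tau_end <= 0) stop("'tau_end' must be > 0")
  if (switch_tau < 0 || switch_tau > tau_end)
    stop("'switch_tau' must lie in [0, tau_end]")
  if (u_level < 0) stop("'u_level' must be >= 0")
  T_seg <- if (switch_tau > 0)
    data.frame(tau_start = 0, tau_end = switch_tau, u = u_level) else 0
  J_seg <- if (switch_tau < tau_end)
    data.frame(tau_start = switch_tau, tau_end = tau_end, u = u_level) else 0
  overexpression_schedule(O = u_O, T = T_seg, J = J_seg)
}
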