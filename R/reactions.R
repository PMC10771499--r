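#' @useDynLib epigrn, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# State layout: for each gene g in (O, T, J), five nucleosome species
# (D, A, R1, R2, R12) at offset 5*(g-1); protein counts X_O, X_T, X_J at
# positions 16:18.  Channel species codes: 0 = none (factor 1), 1..18 a
# state entry, 19..21 = n_R1+n_R2+n_R12 per gene, 22..24 = n_R2+n_R12,
# 25..27 = n_R1+n_R12.  Modifier codes: 0 none, 1 Hill(X_O/K_A),
# 2 g_T = X_T/(p_bar_T*D_tot), 3 g_J = X_J/(p_bar_J*D_tot),
# 4/5/6 overexpression input u_O/u_T/u_J(tau).
GENES <- c("O", "T", "J")

#' Names of the 18 state-vector entries
#'
#' @return Character vector: five nucleosome species per gene
#'   (`D`, `A`, `R1`, `R2`, `R12` prefixed by gene) followed by the three
#'   protein counts `X_O`, `X_T`, `X_J`.
#' @export
state_names <- function() {
  c(paste(rep(GENES, each = 5), rep(c("D", "A", "R1", "R2", "R12"), 3),
          sep = "."),
    paste0("X_", GENES))
}

#' Build the stochastic reaction system of the three-gene network
#'
#' Constructs all reaction channels of the epigenetic OCT4 network: for each
#' gene (OCT4, TET1, JMJD2) the 27 chromatin channels of the five-state
#' modification circuit plus 3 protein channels (production, decay,
#' overexpression input), 30 channels per gene and 90 in total. Propensities
#' are expressed in normalized time \eqn{\tau}; the auto-catalytic writing of
#' activating marks has unit rate constant (it defines the time unit).
#'
#' Channel families per gene (a/b variants act on states without/with the
#' other repressive mark, at identical rates):
#' \describe{
#'   \item{A1}{`D -> A`, OCT4-recruited writing of activating marks,
#'     `kappa_wa * hill(X_O) * n_D`}
#'   \item{A2}{`D -> A` auto-catalysis, `(1/D_tot) * n_A * n_D`}
#'   \item{A3, A4}{`A -> D` replication dilution `eps_d * n_A` and basal
#'     erasure `eps_e * n_A`}
#'   \item{A5}{`A -> D` erasure recruited by repressive marks,
#'     `(eps_prime/D_tot) * n_A * (n_R1+n_R2+n_R12)`}
#'   \item{K1--K6}{establishment, dilution and JMJD2-mediated erasure of
#'     H3K9me3 (`D -> R2`, `R1 -> R12` and reverse)}
#'   \item{M1--M5}{establishment, replication loss (DNMT1-balanced) and
#'     TET1-mediated erasure of CpG methylation (`D -> R1`, `R2 -> R12` and
#'     reverse)}
#'   \item{P1--P3}{protein production `p_bar_X * gamma_hat * n_A`, decay
#'     `gamma_hat * X`, and overexpression input `u_X(tau) * gamma_hat`}
#' }
#'
#' TET1 and JMJD2 counts enter every gene's CpGme / H3K9me3 erasure channels
#' through the linear scalings `g_T = X_T/(p_bar_T*D_tot)` and
#' `g_J = X_J/(p_bar_J*D_tot)`, normalized so that a fully active,
#' non-overexpressed modifier gene (stationary count `p_bar*D_tot`)
#' reproduces the nominal single-gene erasure asymmetries `mu_tilde`,
#' `mu_tilde_prime`.
#'
#' @param params a [grn_params()] object.
#' @param schedule a [overexpression_schedule()]; `NULL` for no input.
#' @param division if `TRUE`, build the system for the binomial-partitioning
#'   division mode: the first-order dilution channels (A3, K4, M3) and
#'   protein decay (P2) are omitted, their effect being realised by
#'   partitioning at division times instead.
#' @return An object of class `grn_system`: a list with the channel table
#'   (`channels`), the 18 x M integer update matrix (`update`), `params`
#'   and `schedule`.
#' @examples
#' sys <- build_reaction_system(grn_params())
#' nrow(sys$channels)  # 90
#' @export
build_reaction_system <- function(params, schedule = NULL, division = FALSE) {
  stopifnot(inherits(params, "grn_params"))
  validate_grn_params(params)
  if (is.null(schedule)) schedule <- overexpression_schedule()
  stopifnot(inherits(schedule, "grn_schedule"))
  p <- params
  Dt <- p$D_tot

  rows <- list()
  upd <- list()
  add <- function(label, gene, rate, s1, s2, mod, from, to) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = label, gene = gene, rate = rate, s1 = s1, s2 = s2, mod = mod,
      stringsAsFactors = FALSE)
    u <- integer(18)
    if (!is.na(from)) u[from] <- u[from] - 1L
    if (!is.na(to)) u[to] <- u[to] + 1L
    upd[[length(upd) + 1]] <<- u
  }

  p_bar <- c(p$p_bar_O, p$p_bar_T, p$p_bar_J)
  for (g in 1:3) {
    o <- 5L * (g - 1L)
    D <- o + 1L; A <- o + 2L; R1 <- o + 3L; R2 <- o + 4L; R12 <- o + 5L
    Rall <- 18L + g; R2p12 <- 21L + g; R1p12 <- 24L + g
    X <- 15L + g
    gn <- GENES[g]
    lab <- function(s) paste0(gn, ".", s)

    # activating marks
    add(lab("A1"), gn, p$kappa_wa, D, 0L, 1L, D, A)
    add(lab("A2"), gn, 1 / Dt, A, D, 0L, D, A)
    if (!division) add(lab("A3"), gn, p$eps_d, A, 0L, 0L, A, D)
    add(lab("A4"), gn, p$eps_e, A, 0L, 0L, A, D)
    add(lab("A5"), gn, p$eps_prime / Dt, A, Rall, 0L, A, D)
    # H3K9me3
    add(lab("K1a"), gn, p$kappa_wr2, D, 0L, 0L, D, R2)
    add(lab("K1b"), gn, p$kappa_wr2, R1, 0L, 0L, R1, R12)
    add(lab("K2a"), gn, p$alpha / Dt, R2p12, D, 0L, D, R2)
    add(lab("K2b"), gn, p$alpha / Dt, R2p12, R1, 0L, R1, R12)
    add(lab("K3a"), gn, p$alpha_bar / Dt, R1p12, D, 0L, D, R2)
    add(lab("K3b"), gn, p$alpha_bar / Dt, R1p12, R1, 0L, R1, R12)
    if (!division) {
      add(lab("K4a"), gn, p$eps_d, R2, 0L, 0L, R2, D)
      add(lab("K4b"), gn, p$eps_d, R12, 0L, 0L, R12, R1)
    }
    add(lab("K5a"), gn, p$b_tilde * p$mu_tilde * p$eps_e, R2, 0L, 3L, R2, D)
    add(lab("K5b"), gn, p$b_tilde * p$mu_tilde * p$eps_e, R12, 0L, 3L, R12, R1)
    add(lab("K6a"), gn, p$mu_tilde * p$eps_prime / Dt, A, R2, 3L, R2, D)
    add(lab("K6b"), gn, p$mu_tilde * p$eps_prime / Dt, A, R12, 3L, R12, R1)
    # CpG methylation
    add(lab("M1a"), gn, p$kappa_wr1, D, 0L, 0L, D, R1)
    add(lab("M1b"), gn, p$kappa_wr1, R2, 0L, 0L, R2, R12)
    add(lab("M2a"), gn, p$alpha_prime / Dt, R2p12, D, 0L, D, R1)
    add(lab("M2b"), gn, p$alpha_prime / Dt, R2p12, R2, 0L, R2, R12)
    if (!division) {
      add(lab("M3a"), gn, p$eta * p$eps_d, R1, 0L, 0L, R1, D)
      add(lab("M3b"), gn, p$eta * p$eps_d, R12, 0L, 0L, R12, R2)
    }
    add(lab("M4a"), gn, p$beta_tilde * p$mu_tilde_prime * p$eps_e, R1, 0L, 2L, R1, D)
    add(lab("M4b"), gn, p$beta_tilde * p$mu_tilde_prime * p$eps_e, R12, 0L, 2L, R12, R2)
    add(lab("M5a"), gn, p$mu_tilde_prime * p$eps_prime / Dt, A, R1, 2L, R1, D)
    add(lab("M5b"), gn, p$mu_tilde_prime * p$eps_prime / Dt, A, R12, 2L, R12, R2)
    # gene product
    add(lab("P1"), gn, p_bar[g] * p$gamma_hat, A, 0L, 0L, NA, X)
    if (!division) add(lab("P2"), gn, p$gamma_hat, X, 0L, 0L, X, NA)
    add(lab("P3"), gn, p$gamma_hat, 0L, 0L, 3L + g, NA, X)
  }

  channels <- do.call(rbind, rows)
  rownames(channels) <- NULL
  update <- matrix(unlist(upd), nrow = 18,
                   dimnames = list(state_names(), channels$label))
  sys <- list(channels = channels, update = update, params = p,
              schedule = schedule, division = division)
  class(sys) <- "grn_system"
  sys
}

#' @export
print.grn_system <- function(x, ...) {
  cat(sprintf(
    "Reaction system: %d channels (%s)%s\n", nrow(x$channels),
    paste(sprintf("%s: %d", GENES, table(factor(x$channels$gene, GENES))),
          collapse = ", "),
    if (isTRUE(x$division)) " [division mode]" else ""))
  print(x$schedule)
  invisible(x)
}

#' Evaluate all channel propensities at a state
#'
#' Reference (pure R) evaluation of every channel's propensity at a full
#' system state and time; used by the validation oracles and tests. The
#' compiled simulation engine evaluates the same channel table and is
#' cross-checked against this function.
#'
#' @param system a `grn_system`.
#' @param state numeric state vector of length 18 (see [state_names()]);
#'   continuous values are allowed (mean-field use).
#' @param tau time at which to evaluate time-dependent inputs.
#' @return Named numeric vector of propensities, one per channel.
#' @export
propensities <- function(system, state, tau = 0) {
  stopifnot(inherits(system, "grn_system"), length(state) == 18)
  p <- system$params
  u_now <- schedule_at(system$schedule, tau)
  vals <- derived_values(state)
  hillO <- hill_activation(max(state[16], 0), p$K_A)
  gT <- state[17] / (p$p_bar_T * p$D_tot)
  gJ <- state[18] / (p$p_bar_J * p$D_tot)
  mods <- c(hillO, gT, gJ, u_now[["O"]], u_now[["T"]], u_now[["J"]])
  ch <- system$channels
  f1 <- ifelse(ch$s1 == 0, 1, vals[pmax(ch$s1, 1)])
  f2 <- ifelse(ch$s2 == 0, 1, vals[pmax(ch$s2, 1)])
  fm <- ifelse(ch$mod == 0, 1, mods[pmax(ch$mod, 1)])
  a <- ch$rate * f1 * f2 * fm
  names(a) <- ch$label
  a
}

# species values plus derived sums (codes 19..27)
derived_values <- function(state) {
  vals <- numeric(27)
  vals[1:18] <- state
  for (g in 1:3) {
    o <- 5 * (g - 1)
    vals[18 + g] <- state[o + 3] + state[o + 4] + state[o + 5]
    vals[21 + g] <- state[o + 4] + state[o + 5]
    vals[24 + g] <- state[o + 3] + state[o + 5]
  }
  vals
}
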