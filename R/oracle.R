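#' Enumerate the single-gene chromatin state space
#'
#' For one gene with frozen modifier and TF inputs (protein counts held
#' fixed), enumerates all compositions of `D_tot` nucleosomes into the five
#' species (D, A, R1, R2, R12) — `choose(D_tot + 4, 4)` states — and builds
#' the transition-rate (generator) matrix of the continuous-time Markov
#' chain from the gene's chromatin channels. This is an independent
#' reference for the stochastic engine: the chemical master equation on the
#' enumerated space is solved exactly by matrix exponentiation.
#'
#' @param params a [grn_params()] (its `D_tot` should be small; the
#'   enumeration refuses `D_tot > 6`, i.e. more than 210 states).
#' @param X_O,X_T,X_J frozen protein counts entering the Hill input and the
#'   modifier scalings.
#' @param gene which gene's circuit to enumerate (they are identical up to
#'   the protein column read).
#' @return An object of class `grn_state_space`: list with `states`
#'   (matrix, one row per composition), `generator` (dense rate matrix, rows
#'   summing to 0), `params`.
#' @export
enumerate_state_space <- function(params, X_O = 0, X_T = 0, X_J = 0,
                                  gene = "O") {
  stopifnot(inherits(params, "grn_params"))
  Dt <- as.integer(params$D_tot)
  if (Dt > 6)
    stop("state space too large: enumeration requires D_tot <= 6 (",
         choose(Dt + 4, 4), " states)")
  gene <- match.arg(gene, GENES)

  # all 5-part compositions of Dt
  comp <- list()
  for (d in 0:Dt) for (a in 0:(Dt - d)) for (r1 in 0:(Dt - d - a))
    for (r2 in 0:(Dt - d - a - r1))
      comp[[length(comp) + 1]] <- c(d, a, r1, r2, Dt - d - a - r1 - r2)
  states <- do.call(rbind, comp)
  colnames(states) <- c("D", "A", "R1", "R2", "R12")
  n <- nrow(states)
  stopifnot(n == choose(Dt + 4, 4))
  key <- apply(states, 1, paste, collapse = ",")
  index <- stats::setNames(seq_len(n), key)

  sys <- build_reaction_system(params)
  sel <- sys$channels$gene == gene &
    !grepl("\\.P[123]$", sys$channels$label)
  g <- match(gene, GENES)
  o <- 5 * (g - 1)

  full_state <- function(x) {
    s <- numeric(18)
    s[o + 1:5] <- x
    s[16:18] <- c(X_O, X_T, X_J)
    s
  }
  G <- matrix(0, n, n)
  upd <- sys$update[o + 1:5, sel, drop = FALSE]
  for (i in seq_len(n)) {
    a <- propensities(sys, full_state(states[i, ]), tau = 0)[sel]
    for (j in which(a > 0)) {
      to <- states[i, ] + upd[, j]
      k <- index[[paste(to, collapse = ",")]]
      G[i, k] <- G[i, k] + a[j]
    }
  }
  diag(G) <- diag(G) - rowSums(G)
  structure(list(states = states, generator = G, params = params,
                 gene = gene, frozen = c(X_O = X_O, X_T = X_T, X_J = X_J)),
            class = "grn_state_space")
}

#' Solve the chemical master equation exactly
#'
#' Propagates a probability distribution over the enumerated single-gene
#' state space: \eqn{p(\tau)^\top = p_0^\top \exp(G\tau)} with `G` the
#' generator of [enumerate_state_space()].
#'
#' @param space a `grn_state_space`.
#' @param p0 initial probability vector (length `nrow(space$states)`), or a
#'   single state index.
#' @param tau time at which to evaluate.
#' @return Probability vector at `tau` (sums to 1 within 1e-9).
#' @export
cme_solve <- function(space, p0, tau) {
  stopifnot(inherits(space, "grn_state_space"))
  n <- nrow(space$states)
  if (length(p0) == 1 && p0 == round(p0) && p0 >= 1 && p0 <= n) {
    v <- numeric(n); v[p0] <- 1; p0 <- v
  }
  if (length(p0) != n || any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("'p0' must be a probability vector over the state space")
  if (tau < 0) stop("'tau' must be >= 0")
  if (tau == 0) return(p0)
  Pt <- Matrix::expm(Matrix::Matrix(t(space$generator) * tau))
  p <- as.numeric(Pt %*% p0)
  if (abs(sum(p) - 1) > 1e-9 || any(p < -1e-12))
    stop("CME solution failed normalization check")
  p / sum(p)
}

#' Mean-field ODE reduction of the full network
#'
#' Deterministic rate equations obtained by replacing molecule counts with
#' continuous means in the exact propensity table:
#' \eqn{dx/d\tau = \sum_j a_j(x, \tau)\, \nu_j}. Conservation of each
#' gene's nucleosome total holds along solutions to integrator tolerance.
#' Useful as a law-of-large-numbers check on SSA ensemble means away from
#' bistable switching regimes.
#'
#' @param system a `grn_system`.
#' @param init length-18 initial state (continuous values allowed).
#' @param tau_grid output times.
#' @param ... passed to [deSolve::ode()].
#' @return Matrix with a `tau` column and one column per state entry.
#' @export
meanfield_ode <- function(system, init, tau_grid, ...) {
  stopifnot(inherits(system, "grn_system"), length(init) == 18)
  upd <- system$update
  rhs <- function(t, y, parms) {
    a <- propensities(system, pmax(y, 0), tau = t)
    list(as.numeric(upd %*% a))
  }
  out <- deSolve::ode(y = stats::setNames(as.numeric(init), state_names()),
                      times = tau_grid, func = rhs, parms = NULL, ...)
  if (attr(out, "istate")[1] < 0)
    stop("mean-field ODE integration failed; deSolve istate = ",
         attr(out, "istate")[1])
  colnames(out)[1] <- "tau"
  unclass(out)
}

#' Total-variation distance between two distributions
#'
#' @param p,q probability vectors over the same support.
#' @return \eqn{\frac12 \sum_i |p_i - q_i|}.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(p - q)) / 2
}

#' Empirical state distribution of SSA endpoints over an enumerated space
#'
#' Runs `n_runs` independent SSA trajectories of the single-gene,
#' frozen-modifier system and returns the empirical distribution of the
#' five nucleosome counts at time `tau` on the enumerated state space —
#' the companion of [cme_solve()] in oracle-equivalence checks.
#'
#' @param space a `grn_state_space`.
#' @param init_index index of the initial state in `space$states`.
#' @param tau endpoint time.
#' @param n_runs number of SSA replicates.
#' @param seed base seed.
#' @return Probability vector over `space$states` rows.
#' @export
ssa_endpoint_distribution <- function(space, init_index, tau, n_runs = 10000,
                                      seed = 1L) {
  params <- space$params
  sys <- build_reaction_system(params)
  keep <- space$gene == sys$channels$gene &
    !grepl("\\.P[123]$", sys$channels$label)
  sub <- sys
  sub$channels <- sys$channels[keep, , drop = FALSE]
  sub$update <- sys$update[, keep, drop = FALSE]
  g <- match(space$gene, GENES)
  o <- 5 * (g - 1)
  init <- numeric(18)
  # other genes: park all nucleosomes unmodified so conservation holds
  for (gg in 1:3) init[5 * (gg - 1) + 1] <- params$D_tot
  init[o + 1:5] <- space$states[init_index, ]
  init[16:18] <- space$frozen
  cfg <- sim_config(tau_end = tau, sample_grid = c(0, tau), seed = seed)
  key <- apply(space$states, 1, paste, collapse = ",")
  index <- stats::setNames(seq_len(nrow(space$states)), key)
  counts <- numeric(nrow(space$states))
  for (i in seq_len(n_runs)) {
    tr <- simulate_grn(sub, init, cfg, traj_index = i)
    endpoint <- tr$states[nrow(tr$states), o + 1:5]
    k <- index[[paste(endpoint, collapse = ",")]]
    counts[k] <- counts[k] + 1
  }
  counts / n_runs
}
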