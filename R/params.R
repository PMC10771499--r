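#' Dimensionless parameters of the epigenetic OCT4 network
#'
#' Constructs the full set of normalized rate parameters for the three-gene
#' network (OCT4, TET1, JMJD2), each gene carrying a five-state chromatin
#' modification circuit. Time is measured in the normalized unit
#' \eqn{\tau = t \, k_M^A D_{tot}}, i.e. rates are expressed relative to the
#' auto-catalytic writing rate of activating histone marks; 21 days of real
#' time correspond to \eqn{\tau = 201.6} (9.6 \eqn{\tau}-units per day).
#'
#' @param D_tot total number of modifiable nucleosomes per gene.
#' @param alpha normalized auto-catalytic rate of repressive histone
#'   methylation (H3K9me3 enhancing its own establishment).
#' @param alpha_bar normalized cross-catalytic rate with which CpG
#'   methylation enhances H3K9me3 establishment.
#' @param r ratio \eqn{r = \alpha'/\alpha} between H3K9me3-driven
#'   enhancement of CpG methylation and H3K9me3 auto-catalysis. Exactly one
#'   of `r` and `alpha_prime` may be given; the other is derived.
#' @param alpha_prime normalized cross-catalytic rate with which H3K9me3
#'   enhances CpG methylation establishment (\eqn{\alpha' = r\,\alpha}).
#' @param eta DNMT1 maintenance inefficiency \eqn{\eta = \delta'/\delta}
#'   in `[0, 1]`: 0 = perfect maintenance of CpG methylation across DNA
#'   replication, 1 = no maintenance.
#' @param mu_tilde erasure-rate asymmetry between repressive histone marks
#'   and activating marks (JMJD2-mediated H3K9me3 demethylation scale).
#' @param mu_tilde_prime erasure-rate asymmetry between CpG methylation and
#'   activating marks (TET1-mediated demethylation scale). If `B`, `K_B`,
#'   `F2`, `F5` are all supplied, this is instead derived from the
#'   methyl-CpG-binding-domain (MBD) protein competition model via
#'   [mbd_modulated_mu()].
#' @param eps_d normalized dilution rate due to DNA replication
#'   (\eqn{\varepsilon_d = \delta/(k_M^A D_{tot})}); proxies the
#'   proliferation rate.
#' @param eps_e normalized basal erasure scale
#'   (\eqn{\varepsilon_e = \bar k_E^A/(k_M^A D_{tot})}).
#' @param eps_prime normalized recruited erasure scale
#'   (\eqn{\varepsilon' = k_E^A/k_M^A}).
#' @param beta_tilde,b_tilde O(1) coefficients linking basal to recruited
#'   repressive-mark erasure.
#' @param kappa_wa normalized scale of TF-recruited writing of activating
#'   marks (Hill-modulated by OCT4 abundance).
#' @param kappa_wr1,kappa_wr2 normalized de-novo writing rates of CpG
#'   methylation and H3K9me3.
#' @param K_A dissociation constant (in molecule counts) of OCT4 binding to
#'   DNA in the Hill writing function.
#' @param p_bar_O,p_bar_T,p_bar_J expression capacity per active nucleosome:
#'   the stationary product count of a fully active, non-overexpressed gene
#'   is \eqn{\bar p_X D_{tot}}.
#' @param gamma_hat normalized first-order protein decay (dilution +
#'   degradation) rate.
#' @param B,K_B,F2,F5 optional MBD-protein model: abundance `B`,
#'   dissociation constant `K_B`, and coefficients of the saturating
#'   competition law \eqn{\tilde\mu' = F_5/(F_2 B/K_B + 1)}.
#'
#' @details
#' The de-novo writing rates `kappa_wr1`, `kappa_wr2`, the recruited-writing
#' scale `kappa_wa`, `K_A` and `gamma_hat` are calibrated defaults (they are
#' not fixed by the dimensionless parameter definitions); see the package
#' vignette for the calibration rationale.
#'
#' @return An object of class `grn_params` (a named list).
#' @examples
#' p <- grn_params(mu_tilde_prime = 0.5, eps_d = 0.2)
#' p$alpha_prime  # equals r * alpha
#' @export
grn_params <- function(D_tot = 50,
                       alpha = 0.3,
                       alpha_bar = 0.3,
                       r = NULL,
                       alpha_prime = NULL,
                       eta = 0.1,
                       mu_tilde = 1,
                       mu_tilde_prime = 1,
                       eps_d = 0.3,
                       eps_e = 0.3,
                       eps_prime = 1,
                       beta_tilde = 1,
                       b_tilde = 1,
                       kappa_wa = 4,
                       kappa_wr1 = 0.06,
                       kappa_wr2 = 0.05,
                       K_A = 100,
                       p_bar_O = 5,
                       p_bar_T = 5,
                       p_bar_J = 5,
                       gamma_hat = 0.2,
                       B = NULL, K_B = NULL, F2 = NULL, F5 = NULL) {
  if (!is.null(r) && !is.null(alpha_prime)) {
    if (abs(alpha_prime - r * alpha) > 1e-12 * max(1, abs(alpha_prime)))
      stop("inconsistent 'r' and 'alpha_prime': alpha_prime must equal r * alpha")
  }
  if (is.null(r) && is.null(alpha_prime)) r <- 1
  if (is.null(alpha_prime)) alpha_prime <- r * alpha
  if (is.null(r)) r <- if (alpha > 0) alpha_prime / alpha else NA_real_

  mbd <- list(B = B, K_B = K_B, F2 = F2, F5 = F5)
  if (!all(vapply(mbd, is.null, logical(1)))) {
    if (any(vapply(mbd, is.null, logical(1))))
      stop("MBD model requires all of 'B', 'K_B', 'F2', 'F5'")
    mu_tilde_prime <- mbd_modulated_mu(B, K_B, F2, F5)
  }

  p <- list(D_tot = D_tot, alpha = alpha, alpha_bar = alpha_bar,
            alpha_prime = alpha_prime, r = r, eta = eta,
            mu_tilde = mu_tilde, mu_tilde_prime = mu_tilde_prime,
            eps_d = eps_d, eps_e = eps_e, eps_prime = eps_prime,
            beta_tilde = beta_tilde, b_tilde = b_tilde,
            kappa_wa = kappa_wa, kappa_wr1 = kappa_wr1,
            kappa_wr2 = kappa_wr2, K_A = K_A,
            p_bar_O = p_bar_O, p_bar_T = p_bar_T, p_bar_J = p_bar_J,
            gamma_hat = gamma_hat,
            B = B, K_B = K_B, F2 = F2, F5 = F5)
  class(p) <- "grn_params"
  validate_grn_params(p)
  p
}

#' @export
print.grn_params <- function(x, ...) {
  cat("Dimensionless parameters of the epigenetic OCT4 network\n")
  cat(sprintf("  nucleosomes per gene (D_tot): %d\n", as.integer(x$D_tot)))
  cat(sprintf("  catalysis: alpha = %g, alpha_bar = %g, alpha_prime = %g (r = %g)\n",
              x$alpha, x$alpha_bar, x$alpha_prime, x$r))
  cat(sprintf("  erasure: mu_tilde = %g, mu_tilde_prime = %g, eps_e = %g, eps_prime = %g\n",
              x$mu_tilde, x$mu_tilde_prime, x$eps_e, x$eps_prime))
  cat(sprintf("  replication: eps_d = %g, eta = %g\n", x$eps_d, x$eta))
  cat(sprintf("  writing: kappa_wa = %g, kappa_wr1 = %g, kappa_wr2 = %g, K_A = %g\n",
              x$kappa_wa, x$kappa_wr1, x$kappa_wr2, x$K_A))
  cat(sprintf("  expression: p_bar = (%g, %g, %g), gamma_hat = %g\n",
              x$p_bar_O, x$p_bar_T, x$p_bar_J, x$gamma_hat))
  if (!is.null(x$B))
    cat(sprintf("  MBD model: B = %g, K_B = %g, F2 = %g, F5 = %g\n",
                x$B, x$K_B, x$F2, x$F5))
  invisible(x)
}

validate_grn_params <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop(sprintf("parameter '%s' must be a single finite number", field))
    v
  }
  nonneg <- c("D_tot", "alpha", "alpha_bar", "alpha_prime", "eta",
              "mu_tilde", "mu_tilde_prime", "eps_d", "eps_e", "eps_prime",
              "beta_tilde", "b_tilde", "kappa_wa", "kappa_wr1", "kappa_wr2",
              "K_A", "p_bar_O", "p_bar_T", "p_bar_J", "gamma_hat")
  for (f in nonneg) {
    if (num1(f) < 0) stop(sprintf("parameter '%s' must be >= 0", f))
  }
  if (p$eta > 1) stop("parameter 'eta' must lie in [0, 1]")
  if (p$K_A <= 0) stop("parameter 'K_A' must be > 0")
  if (p$D_tot < 1 || p$D_tot != round(p$D_tot))
    stop("parameter 'D_tot' must be a positive integer")
  invisible(p)
}

#' Hill-type transcription-factor activation
#'
#' Fractional occupancy of the gene's regulatory region by the activating
#' transcription factor, modeled as a Hill function with cooperativity 1:
#' \eqn{h(X) = (X/K_A)/(1 + X/K_A)}. This multiplies the recruited writing
#' rate of activating chromatin marks.
#'
#' @param X transcription-factor molecule count (non-negative).
#' @param K_A dissociation constant in molecule counts (> 0).
#' @return Value in `[0, 1)`, monotone increasing in `X`.
#' @examples
#' hill_activation(0, 100)    # 0
#' hill_activation(100, 100)  # 0.5
#' @export
hill_activation <- function(X, K_A) {
  if (!is.numeric(K_A) || length(K_A) != 1 || is.na(K_A) || K_A <= 0)
    stop("'K_A' must be a single positive number")
  if (any(X < 0)) stop("'X' must be >= 0")
  (X / K_A) / (1 + X / K_A)
}

#' CpG-methylation erasure asymmetry under MBD protein competition
#'
#' Methyl-CpG-binding-domain (MBD) proteins bind methylated DNA and shield
#' it from TET1, reducing the effective demethylation asymmetry:
#' \eqn{\tilde\mu' = F_5 / (F_2 \, B/K_B + 1)}. Knocking MBD down
#' (`B = 0`) or preventing binding (`K_B` large) raises \eqn{\tilde\mu'}
#' to its ceiling `F5`.
#'
#' @param B MBD protein abundance (count-like, >= 0).
#' @param K_B dissociation constant of MBD binding to methylated DNA (> 0).
#' @param F2,F5 non-negative coefficients independent of `B` and `K_B`.
#' @return The modulated \eqn{\tilde\mu'}, decreasing in `B`, increasing
#'   in `K_B`.
#' @examples
#' mbd_modulated_mu(0, 1, 2, 0.5)   # 0.5 (= F5)
#' mbd_modulated_mu(1, 1, 1, 1)     # 0.5
#' @export
mbd_modulated_mu <- function(B, K_B, F2, F5) {
  for (v in list(B = B, K_B = K_B, F2 = F2, F5 = F5)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("all MBD arguments must be single non-negative numbers")
  }
  if (K_B == 0) stop("'K_B' must be > 0")
  F5 / (F2 * B / K_B + 1)
}

#' Convert between days and normalized time
#'
#' The simulator runs in normalized time \eqn{\tau}; the calibration
#' 21 days \eqn{\equiv \tau = 201.6} fixes the conversion at 9.6
#' \eqn{\tau}-units per day.
#'
#' @param days,tau non-negative time values.
#' @return The converted time(s).
#' @examples
#' days_to_tau(21)   # 201.6
#' tau_to_days(9.6)  # 1
#' @export
days_to_tau <- function(days) {
  if (any(days < 0)) stop("time must be >= 0")
  days * TAU_PER_DAY
}

#' @rdname days_to_tau
#' @export
tau_to_days <- function(tau) {
  if (any(tau < 0)) stop("time must be >= 0")
  tau / TAU_PER_DAY
}

# 21 days == tau 201.6
TAU_PER_DAY <- 9.6
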