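#' Breit-Wigner transmission between the two contacts
#'
#' `T = sum_k Gamma_L Gamma_R |psi_L^k|^2 |psi_R^k|^2 /
#' ((mu - E_k)^2 + (Gamma^k/2)^2)` with the lifetime broadening
#' `Gamma^k = Gamma_L |psi_L^k|^2 + Gamma_R |psi_R^k|^2`. A single level at
#' resonance with symmetric couplings transmits with probability one.
#'
#' @param es an `electronic_structure`.
#' @param contacts a `contact_pair`.
#' @param mu chemical potential (eV); defaults to `es$mu`.
#' @param window level indices.
#' @return dimensionless transmission (nonnegative).
#' @export
breit_wigner_T <- function(es, contacts, mu = es$mu,
                           window = select_window(es, "levels_k", 20)) {
  b <- contact_broadening(es, contacts, window)
  E <- es$energies[window]
  sum(contacts$Gamma_L * contacts$Gamma_R * b$psi_L^2 * b$psi_R^2 /
        ((mu - E)^2 + (b$Gamma_i / 2)^2))
}

# same-contact transmissions T_L, T_R entering the mixed mechanism
contact_transmissions <- function(es, contacts, mu, window) {
  b <- contact_broadening(es, contacts, window)
  E <- es$energies[window]
  den <- (mu - E)^2 + (b$Gamma_i / 2)^2
  list(T_L = sum(contacts$Gamma_L^2 * b$psi_L^4 / den),
       T_R = sum(contacts$Gamma_R^2 * b$psi_R^4 / den))
}

#' Thermal excitation weights Z_L and Z_R
#'
#' `Z_{L/R} = sum_k Gamma_{L/R} |psi_{L/R}^k|^2 /
#' (4 kT cosh^2((mu - E_k)/2kT))`: proportional to the probability that an
#' electron is thermally excited from the contact into a molecular level.
#' Evaluated in log space (log-sum-exp) so that the exponential suppression
#' at low temperature underflows gracefully; both the linear and the log
#' values are returned.
#'
#' @inheritParams breit_wigner_T
#' @param kT thermal energy (eV); `kT = 0` returns exact zeros with a
#'   `zero_T` flag.
#' @return list with `Z_L`, `Z_R`, `log_Z_L`, `log_Z_R`, `zero_T`.
#' @export
thermal_weights <- function(es, contacts, mu = es$mu, kT,
                            window = select_window(es, "levels_k", 20)) {
  b <- contact_broadening(es, contacts, window)
  if (kT == 0) {
    return(list(Z_L = 0, Z_R = 0, log_Z_L = -Inf, log_Z_R = -Inf,
                zero_T = TRUE))
  }
  x <- (mu - es$energies[window]) / (2 * kT)
  lc2 <- 2 * logcosh(x)
  log_terms <- function(Gamma, psi) {
    lt <- log(Gamma) + log(psi^2) - log(4 * kT) - lc2
    logsumexp(lt[is.finite(lt) | lt == -Inf])
  }
  lZL <- log_terms(contacts$Gamma_L, b$psi_L)
  lZR <- log_terms(contacts$Gamma_R, b$psi_R)
  list(Z_L = exp(lZL), Z_R = exp(lZR), log_Z_L = lZL, log_Z_R = lZR,
       zero_T = FALSE)
}

#' Three-mechanism conductance G = G_LB + G_T + G_M
#'
#' The fast-relaxation (slow-escape) decomposition of the full Liouville
#' conductance into three transport mechanisms:
#' \itemize{
#'   \item `G_LB = (2e^2/h) T` - coherent elastic tunneling (Landauer-
#'     Buettiker, Breit-Wigner transmission `T`), temperature independent;
#'   \item `G_T = (2e^2/hbar) Z_L Z_R / (Z_L + Z_R)` - thermal-excitation
#'     transport: in and out of the molecule via phonon-assisted excitation
#'     (the weights `Z` are rate-like, hence the hbar prefactor);
#'   \item `G_M = (e^2/h) [Z_L/(Z_L+Z_R) T_R + Z_R/(Z_L+Z_R) T_L]` - mixed
#'     process: tunneling in through one contact, thermal exit at the other.
#' }
#' The branching ratios `Z/(Z_L+Z_R)` are evaluated via log-sum-exp so the
#' low-temperature plateau of `G_M` is reachable numerically.
#'
#' @inheritParams thermal_weights
#' @param harmonize_hbar if TRUE, use `h` rather than `hbar` in the thermal
#'   term (sensitivity analysis only; the printed formula uses hbar).
#' @return a `conductance_result` with components `G_LB`, `G_T`, `G_M` and
#'   extras `T`, `T_L`, `T_R`, `Z_L`, `Z_R`.
#' @export
three_term_conductance <- function(es, contacts, mu = es$mu, kT,
                                   window = select_window(es, "levels_k", 20),
                                   harmonize_hbar = FALSE) {
  Tr <- breit_wigner_T(es, contacts, mu, window)
  TLR <- contact_transmissions(es, contacts, mu, window)
  Z <- thermal_weights(es, contacts, mu, kT, window)

  e2h <- mc_constants$e2_over_h
  e2hbar <- if (harmonize_hbar) e2h else mc_constants$e2_over_hbar

  G_LB <- 2 * e2h * Tr
  if (Z$zero_T || (Z$log_Z_L == -Inf && Z$log_Z_R == -Inf)) {
    G_T <- 0
    G_M <- 0
  } else {
    lden <- logsumexp(c(Z$log_Z_L, Z$log_Z_R))
    G_T <- 2 * e2hbar * exp(Z$log_Z_L + Z$log_Z_R - lden)
    wL <- exp(Z$log_Z_L - lden)
    wR <- exp(Z$log_Z_R - lden)
    G_M <- e2h * (wL * TLR$T_R + wR * TLR$T_L)
  }
  conductance_result(
    G_S = G_LB + G_T + G_M,
    components = list(G_LB = G_LB, G_T = G_T, G_M = G_M),
    extras = list(transmission = Tr, T_L = TLR$T_L, T_R = TLR$T_R,
                  Z_L = Z$Z_L, Z_R = Z$Z_R),
    method = if (harmonize_hbar) "three_term_harmonized" else "three_term",
    parameters = list(mu = mu, kT = kT, Gamma_L = contacts$Gamma_L,
                      Gamma_R = contacts$Gamma_R, window = range(window),
                      n_window = length(window)))
}

#' Conductance between many orbital pairs
#'
#' Applies [three_term_conductance()] to a list of contact-orbital pairs and
#' tabulates the per-mechanism conductances, one row per pair. Distances are
#' taken between the host atoms of the two orbitals when coordinates are
#' available in `es$meta`.
#'
#' @param es an `electronic_structure`.
#' @param pairs two-column matrix or data.frame of orbital indices (columns
#'   `a`, `b` or positional).
#' @param Gamma_L,Gamma_R escape strengths (eV).
#' @param kT thermal energy (eV).
#' @param mu chemical potential; defaults to `es$mu`.
#' @param window level indices.
#' @return data.frame with columns `site_L`, `site_R`, `distance_A`, `G_nS`,
#'   `G_LB_nS`, `G_T_nS`, `G_M_nS`.
#' @export
pairwise_G <- function(es, pairs, Gamma_L = 0.1, Gamma_R = 0.1, kT,
                       mu = es$mu,
                       window = select_window(es, "levels_k", 20)) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  N <- nrow(es$psi)
  if (nrow(pairs) == 0) {
    return(data.frame(site_L = integer(), site_R = integer(),
                      distance_A = numeric(), G_nS = numeric(),
                      G_LB_nS = numeric(), G_T_nS = numeric(),
                      G_M_nS = numeric()))
  }
  if (any(pairs < 1 | pairs > N)) stop("pair indices out of range 1..", N)
  has_xyz <- !is.null(es$meta) && all(c("x", "y", "z") %in% names(es$meta))
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    d <- if (has_xyz) {
      sqrt(sum((unlist(es$meta[a, c("x", "y", "z")]) -
                  unlist(es$meta[b, c("x", "y", "z")]))^2))
    } else NA_real_
    cp <- contact_pair(a, b, Gamma_L, Gamma_R, distance = d)
    g <- three_term_conductance(es, cp, mu = mu, kT = kT, window = window)
    data.frame(site_L = a, site_R = b, distance_A = d,
               G_nS = g$G_nS, G_LB_nS = g$components$G_LB * 1e9,
               G_T_nS = g$components$G_T * 1e9,
               G_M_nS = g$components$G_M * 1e9)
  })
  do.call(rbind, rows)
}
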