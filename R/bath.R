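#' Ohmic phonon-bath specification
#'
#' The bath is characterized by a dimensionless coupling `eta`, a cutoff
#' energy `hbar_omega_c` (eV) and a temperature `T` (K). Alternatively the
#' coupling can be supplied as a reorganization energy `E_R` (eV), from which
#' `eta = 2 pi E_R / hbar_omega_c`. Defaults are typical protein values.
#'
#' @param eta dimensionless electron-phonon coupling.
#' @param hbar_omega_c cutoff energy (eV).
#' @param T temperature (K); `T = 0` is handled as the zero-temperature limit.
#' @param E_R optional reorganization energy (eV) that overrides `eta`.
#' @return object of class `bath_spec`.
#' @export
bath_spec <- function(eta = 1.46, hbar_omega_c = 0.0185, T = 300, E_R = NULL) {
  if (!is.null(E_R)) eta <- 2 * pi * E_R / hbar_omega_c
  if (eta <= 0) stop("eta must be positive")
  if (hbar_omega_c <= 0) stop("hbar_omega_c must be positive")
  if (T < 0) stop("T must be nonnegative")
  structure(list(eta = eta, hbar_omega_c = hbar_omega_c, T = T, E_R = E_R),
            class = "bath_spec")
}

#' @export
print.bath_spec <- function(x, ...) {
  cat(sprintf("bath_spec: Ohmic, eta = %.4g, cutoff %.4g eV, T = %.4g K (kT = %.4g eV)\n",
              x$eta, x$hbar_omega_c, x$T, kT_eV(x$T)))
  invisible(x)
}

#' Ohmic spectral density with exponential cutoff
#'
#' `gamma(hw) = eta * hw * exp(-|hw|/hw_c) / (exp(hw/kT) - 1)` with the
#' analytic limit `gamma(0) = eta * kT`. The function satisfies detailed
#' balance `gamma(hw)/gamma(-hw) = exp(-hw/kT)` exactly. At `T = 0` only
#' emission survives: `gamma(hw) = eta * |hw| * exp(-|hw|/hw_c)` for
#' `hw < 0` and zero otherwise.
#'
#' @param hw transition energy `hbar * omega` in eV (vectorized; the sign
#'   convention is `hw = E_i - E_j` for a transition j -> i).
#' @param bath a `bath_spec`.
#' @param log if TRUE return `log(gamma)`, evaluated stably even where the
#'   linear value underflows (e.g. absorption across 1 eV at 10 K); the
#'   detailed-balance identity is exact in this representation.
#' @return rate in energy units (eV, i.e. hbar times the rate in 1/s), or its
#'   natural logarithm.
#' @export
spectral_density <- function(hw, bath, log = FALSE) {
  if (bath$T == 0) {
    if (log) stop("log spectral density is undefined at T = 0")
    cut <- exp(-abs(hw) / bath$hbar_omega_c)
    return(ifelse(hw < 0, bath$eta * abs(hw) * cut, 0))
  }
  kT <- kT_eV(bath$T)
  x <- hw / kT
  if (log) {
    # log(eta kT) + log(x/expm1(x)) - |hw|/hw_c, stable over the whole axis;
    # the detailed-balance identity log g(x) - log g(-x) = -x/kT is exact here
    lr <- ifelse(abs(x) < 1e-12, -x / 2,
                 ifelse(x > 0, log(x) - x - log1p(-exp(-x)),
                        log(-x) - log1p(-exp(x))))
    return(log(bath$eta * kT) + lr - abs(hw) / bath$hbar_omega_c)
  }
  cut <- exp(-abs(hw) / bath$hbar_omega_c)
  # eta * hw / expm1(x) = eta * kT * x / expm1(x); the ratio -> 1 as x -> 0
  ratio <- ifelse(abs(x) < 1e-12, 1 - x / 2, x / expm1(x))
  bath$eta * kT * ratio * cut
}

#' Level-to-level phonon transition rates
#'
#' `gamma_ij = gamma(E_i - E_j) * sum_n |psi_n^i|^2 |psi_n^j|^2`: the bath
#' spectral density at the transition energy times the spatial overlap of the
#' two molecular-orbital densities. Restricted to the given level window.
#' A warning (not an error) is issued when the rates are not small compared
#' to the level spacing, where the weak-coupling master equation becomes
#' questionable.
#'
#' @param es an `electronic_structure`.
#' @param window integer level indices (see [select_window()]).
#' @param bath a `bath_spec`.
#' @param warn_weak_coupling check rates against the minimum level spacing.
#' @return object of class `rate_matrix`: list with `gamma` (Nw x Nw, eV),
#'   `overlap`, `window`, `energies`.
#' @export
transition_rates <- function(es, window, bath, warn_weak_coupling = TRUE) {
  stopifnot(all(window >= 1), all(window <= length(es$energies)))
  E <- es$energies[window]
  P2 <- es$psi[, window, drop = FALSE]^2
  overlap <- crossprod(P2)              # sum_n |psi_n^i|^2 |psi_n^j|^2
  omega <- outer(E, E, "-")             # hbar*omega_ij = E_i - E_j
  gam <- spectral_density(omega, bath) * overlap
  if (warn_weak_coupling && length(E) > 1) {
    dE <- diff(sort(E))
    dE <- dE[dE > 1e-12]
    if (length(dE) && max(gam) > min(dE)) {
      warning("max phonon rate (", format(max(gam), digits = 3),
              " eV) exceeds the minimum level spacing (",
              format(min(dE), digits = 3),
              " eV): weak-coupling assumption questionable")
    }
  }
  structure(list(gamma = gam, overlap = overlap, window = window,
                 energies = E, bath = bath),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("rate_matrix:", length(x$window), "levels; max gamma =",
      format(max(x$gamma), digits = 4), "eV",
      if (!is.null(x$gamma_tilde)) "; tilded rates attached" else "", "\n")
  invisible(x)
}

#' Occupation-corrected (tilded) rates of the linearized evolution operator
#'
#' The linearization of the Pauli-blocked relaxation term around the
#' Fermi-Dirac equilibrium replaces the bare rates by
#' `gtilde_ij = gamma_ij * (1 - F(E_i, mu)) / (1 - F(E_j, mu))`.
#' For levels far above mu (F ~ 0) the tilded rates reduce to the bare ones.
#'
#' @param rates a `rate_matrix` from [transition_rates()].
#' @param es the `electronic_structure` that produced it.
#' @param T temperature (K) used for the Fermi factors; defaults to the bath
#'   temperature stored in `rates`.
#' @param allow_low_T if FALSE (default), temperatures below 1 K are floored
#'   to 1 K in the Fermi denominators to avoid overflow of the occupation
#'   correction; set TRUE to use the exact low-T branch.
#' @return the `rate_matrix` with a `gamma_tilde` field added.
#' @export
tilde_rates <- function(rates, es, T = NULL, allow_low_T = FALSE) {
  if (is.null(T)) T <- rates$bath$T
  if (T == 0) {
    stop("tilde rates diverge at T = 0 for occupied levels; use a small positive T",
         call. = FALSE)
  }
  if (!allow_low_T && T < 1) T <- 1
  kT <- kT_eV(T)
  # log(1 - F(E, mu)) = log(plogis((E - mu)/kT)), stable far below mu
  log1mF <- stats::plogis((rates$energies - es$mu) / kT, log.p = TRUE)
  # gamma_tilde in log space: deep-lying i with high-lying j would overflow
  # the direct ratio, but the cutoff in gamma kills those elements first
  rates$gamma_tilde <- exp(log(rates$gamma) + outer(log1mF, log1mF, "-"))
  rates$tilde_T <- T
  rates
}
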