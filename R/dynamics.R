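# Time-domain master-equation oracle. Works in internal units hbar = 1:
# energies in eV, time in hbar/eV (~0.658 fs). Used to validate the
# linearized superoperator and the conductance formulas against brute-force
# steady states.

#' Right-hand side of the Liouville master equation
#'
#' `drho/dt = -i(E_i - E_j) rho^{ij} - (1/2) sum_r (Gamma^{ir} rho^{rj} +
#' rho^{ir} Gamma^{rj}) + R^{ij}(rho) + J^{ij}` (time in hbar/eV units),
#' where the Pauli-blocked relaxation term is
#' `R^{ij} = (delta_ij - rho^{ij}) sum_p (1/2)(gamma^{ip} + gamma^{jp})
#' rho^{pp} - rho^{ij} sum_p (1/2)(gamma^{pi} + gamma^{pj})(1 - rho^{pp})`.
#' With `Gamma = J = 0` the Fermi-Dirac density matrix
#' `rho^{ij} = delta_ij F(E_i, mu)` is stationary.
#'
#' @param rho complex Hermitian density matrix over the window.
#' @param energies window level energies (eV).
#' @param gamma bare phonon rate matrix (eV), as in [transition_rates()].
#' @param Gamma_ij contact escape matrix (eV) or NULL.
#' @param J injected-current matrix (eV) or NULL.
#' @return complex matrix `drho/dt` (per hbar/eV of time).
#' @export
me_rhs <- function(rho, energies, gamma, Gamma_ij = NULL, J = NULL) {
  Nw <- length(energies)
  stopifnot(nrow(rho) == Nw, ncol(rho) == Nw,
            nrow(gamma) == Nw, ncol(gamma) == Nw)
  drho <- -1i * outer(energies, energies, "-") * rho
  if (!is.null(Gamma_ij)) {
    drho <- drho - 0.5 * (Gamma_ij %*% rho + rho %*% Gamma_ij)
  }
  p <- Re(diag(rho))
  a <- 0.5 * as.vector(gamma %*% p)             # a_i = (1/2) sum_p gamma^{ip} rho^{pp}
  b <- 0.5 * as.vector(crossprod(gamma, 1 - p)) # b_i = (1/2) sum_p gamma^{pi} (1 - rho^{pp})
  A <- matrix(a, Nw, Nw) + matrix(a, Nw, Nw, byrow = TRUE)  # a_i + a_j
  B <- matrix(b, Nw, Nw) + matrix(b, Nw, Nw, byrow = TRUE)  # b_i + b_j
  drho <- drho + (diag(Nw) - rho) * A - rho * B
  if (!is.null(J)) drho <- drho + J
  drho
}

# pack/unpack complex matrices for deSolve
cplx_to_real <- function(M) c(Re(M), Im(M))
real_to_cplx <- function(v, Nw) {
  n2 <- Nw * Nw
  matrix(v[1:n2], Nw, Nw) + 1i * matrix(v[n2 + (1:n2)], Nw, Nw)
}

#' Relax a density matrix to equilibrium under the phonon bath
#'
#' Integrates the nonlinear master equation with `Gamma = J = 0` until
#' `max |drho/dt| < tol`. The fixed point has vanishing off-diagonals and
#' Fermi-Dirac diagonal occupations at an effective chemical potential fixed
#' by the conserved trace of `rho0`.
#'
#' @param rho0 initial complex Hermitian density matrix with diagonal
#'   occupations in `[0, 1]`.
#' @param energies window energies (eV).
#' @param gamma bare phonon rates (eV).
#' @param tol stationarity tolerance on `max |drho/dt|`.
#' @param t_max maximum integration time (hbar/eV units).
#' @return list with `rho` (converged), `t` (time used), `residual`.
#' @export
relax_to_equilibrium <- function(rho0, energies, gamma, tol = 1e-12,
                                 t_max = 1e9) {
  Nw <- length(energies)
  occ <- Re(diag(rho0))
  if (any(occ < -1e-12 | occ > 1 + 1e-12)) {
    stop("initial occupations must lie in [0, 1]")
  }
  deriv <- function(t, y, parms) {
    rho <- real_to_cplx(y, Nw)
    list(cplx_to_real(me_rhs(rho, energies, gamma)))
  }
  resid <- function(rho) max(abs(me_rhs(rho, energies, gamma)))
  rho <- rho0
  if (resid(rho) < tol) return(list(rho = rho, t = 0, residual = resid(rho)))
  t_now <- 0
  t_step <- 10 / max(gamma, 1e-12)   # ~10 relaxation times per chunk
  while (t_now < t_max) {
    sol <- deSolve::ode(y = cplx_to_real(rho), times = c(0, t_step),
                        func = deriv, parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    rho <- real_to_cplx(sol[nrow(sol), -1], Nw)
    rho <- (rho + Conj(t(rho))) / 2
    t_now <- t_now + t_step
    r <- resid(rho)
    if (r < tol) return(list(rho = rho, t = t_now, residual = r))
    t_step <- t_step * 2
  }
  stop("no convergence to equilibrium after t = ", format(t_now),
       " (residual ", format(resid(rho)), ")")
}

#' Linear-response conductance from the stationary master equation
#'
#' Ground-truth route to the conductance: for each small bias `eU` the
#' injected-current matrix `J` is built from the contact occupancy responses,
#' the stationary perturbation `drho` of the linearized equation
#' `0 = L drho + J` is obtained both by stiff time integration and by a
#' direct linear solve (the two must agree), and the conductance follows from
#' the physical net current at the contacts,
#' `I/e = Tr J_L - Tr(Gamma_L drho)` (equivalently at R), extrapolated to
#' `U -> 0`. Like the master equation itself, this is the current of a single
#' spin channel, matching the convention of [conductance_full()].
#'
#' @param es an `electronic_structure`.
#' @param contacts a `contact_pair`.
#' @param bath a `bath_spec`.
#' @param window level indices.
#' @param eU_values bias energies (eV) used for the extrapolation (>= 2).
#' @param agree_tol required agreement between the time-integrated and the
#'   directly solved `drho` (max abs difference relative to its scale).
#' @param t_max maximum integration time per bias (hbar/eV).
#' @return list with `G_S`, `G_nS`, `drho` (per unit eU), and the per-bias
#'   diagnostics `currents` (data.frame of eU, I_L, I_R).
#' @export
linear_response_G <- function(es, contacts, bath, window,
                              eU_values = c(1e-4, 2e-4),
                              agree_tol = 1e-8, t_max = 1e10) {
  if (length(eU_values) < 2) stop("need at least two bias values")
  Nw <- length(window)
  kT <- kT_eV(bath$T)
  broad <- contact_broadening(es, contacts, window)
  rates <- transition_rates(es, window, bath, warn_weak_coupling = FALSE)
  rates <- tilde_rates(rates, es)
  sop <- build_superoperator(es, window, rates, broad)
  D <- compute_D(sop$energies, broad$Gamma_i, es$mu, kT)
  J1 <- external_current(broad, D, eU = 1)     # per unit eU

  # direct stationary solve per unit eU: L drho + J = 0
  drho1_vec <- solve(sop$L, -flatten_pairs(J1) + 0i)
  drho1 <- unflatten_pairs(drho1_vec, Nw)

  # time integration of the linearized equation to the same steady state
  Lr <- sop$L
  deriv <- function(t, y, parms) {
    v <- y[1:(Nw^2)] + 1i * y[Nw^2 + 1:(Nw^2)]
    dv <- as.vector(Lr %*% v) + parms
    list(c(Re(dv), Im(dv)))
  }
  slow <- max(min(abs(Re(eigen(Lr, only.values = TRUE)$values)), na.rm = TRUE),
              1e-12)
  currents <- lapply(eU_values, function(eU) {
    Jv <- flatten_pairs(J1) * eU
    Jscale <- max(abs(Jv))
    # single uninterrupted stiff integration with geometrically spaced
    # output times: the first output row whose residual ||L drho + J|| has
    # converged is the stationary state. One call avoids restart noise, and
    # the step size grows freely once the transients have decayed.
    t_hi <- min(40 / slow, t_max)
    times <- c(0, exp(seq(log(1e-2), log(t_hi), length.out = 50)))
    # tolerance anchored to the stationary scale from the direct solve
    scale0 <- max(abs(drho1)) * eU
    sol <- deSolve::ode(y = rep(0, 2 * Nw^2), times = times, func = deriv,
                        parms = Jv, method = "lsoda",
                        rtol = 1e-10, atol = max(1e-13 * scale0, 1e-300),
                        maxsteps = 500000L)
    resids <- apply(sol[-1, -1, drop = FALSE], 1, function(y) {
      v <- y[1:(Nw^2)] + 1i * y[Nw^2 + 1:(Nw^2)]
      max(abs(as.vector(Lr %*% v) + Jv))
    })
    best <- which(resids < 1e-9 * Jscale)[1]
    if (is.na(best)) {
      stop("no stationary state after t = ", format(t_hi),
           " (best residual ", format(min(resids) / Jscale), " relative)")
    }
    y <- sol[best + 1, -1]
    v <- y[1:(Nw^2)] + 1i * y[Nw^2 + 1:(Nw^2)]
    drho_t <- unflatten_pairs(v, Nw)
    scale <- max(abs(drho1) * eU, 1e-300)
    if (max(abs(drho_t - drho1 * eU)) > agree_tol * scale) {
      stop("time-integrated steady state disagrees with the direct solve (",
           format(max(abs(drho_t - drho1 * eU)) / scale), " relative)")
    }
    # physical net current (units: eV of energy flow per hbar, per charge e)
    I_L <- sum(diag(broad$Gamma_L_ij) * D) * eU -
      Re(sum(broad$Gamma_L_ij * t(drho_t)))
    I_R <- Re(sum(broad$Gamma_R_ij * t(drho_t))) +
      sum(diag(broad$Gamma_R_ij) * D) * eU
    data.frame(eU = eU, I_L = I_L, I_R = I_R)
  })
  currents <- do.call(rbind, currents)
  # I is linear in eU; fit the slope through the origin
  slope <- sum(currents$I_L * currents$eU) / sum(currents$eU^2)
  G_S <- slope * mc_constants$e2_over_hbar   # single spin channel
  list(G_S = G_S, G_nS = G_S * 1e9, drho = drho1, currents = currents)
}
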