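#' Contact pair specification
#'
#' Two atomic orbitals (in the orthonormal Loewdin basis) are coupled to
#' electrodes with escape strengths `Gamma_L` and `Gamma_R` (energy units;
#' the physical escape rates are `Gamma/hbar`).
#'
#' @param site_L,site_R 1-based orbital indices of the left/right contact.
#' @param Gamma_L,Gamma_R escape strengths in eV (positive).
#' @param distance optional contact separation in Angstrom (metadata only).
#' @return object of class `contact_pair`.
#' @export
contact_pair <- function(site_L, site_R, Gamma_L = 0.1, Gamma_R = 0.1,
                         distance = NA_real_) {
  if (site_L == site_R) stop("contact sites must differ")
  if (Gamma_L < 0 || Gamma_R < 0) stop("escape strengths must be nonnegative")
  structure(list(site_L = as.integer(site_L), site_R = as.integer(site_R),
                 Gamma_L = Gamma_L, Gamma_R = Gamma_R, distance = distance),
            class = "contact_pair")
}

#' @export
print.contact_pair <- function(x, ...) {
  cat(sprintf("contact_pair: L = orbital %d (Gamma_L = %g eV), R = orbital %d (Gamma_R = %g eV)%s\n",
              x$site_L, x$Gamma_L, x$site_R, x$Gamma_R,
              if (is.na(x$distance)) "" else sprintf(", d = %.2f A", x$distance)))
  invisible(x)
}

#' Contact-induced level broadening matrices
#'
#' In the level basis the contacts contribute
#' `Gamma_ij = Gamma_L psi_L^i psi_L^j + Gamma_R psi_R^i psi_R^j`, a rank <= 2
#' symmetric PSD matrix; its diagonal `Gamma^i` is the lifetime broadening of
#' level i.
#'
#' @param es an `electronic_structure`.
#' @param contacts a `contact_pair`.
#' @param window level indices.
#' @return list with `Gamma_ij` (matrix, eV), `Gamma_i` (diagonal vector),
#'   `Gamma_L_ij`, `Gamma_R_ij` (the two rank-1 parts), `psi_L`, `psi_R`
#'   (contact-orbital amplitudes of the window levels).
#' @export
contact_broadening <- function(es, contacts, window) {
  psi_L <- es$psi[contacts$site_L, window]
  psi_R <- es$psi[contacts$site_R, window]
  GL <- contacts$Gamma_L * outer(psi_L, psi_L)
  GR <- contacts$Gamma_R * outer(psi_R, psi_R)
  G <- GL + GR
  list(Gamma_ij = G, Gamma_i = diag(G), Gamma_L_ij = GL, Gamma_R_ij = GR,
       psi_L = psi_L, psi_R = psi_R)
}

#' Contact occupancy response D^i(mu)
#'
#' `D^i = integral f(E, mu) d_i(E) dE`, the thermal derivative of the Fermi
#' function convolved with the unit-normalized Lorentzian density of states
#' `d_i(E) = (1/2pi) Gamma^i / ((E - E_i)^2 + (Gamma^i/2)^2)` of the
#' lifetime-broadened level. Units 1/eV. In the `Gamma^i -> 0` limit
#' `D^i -> f(E_i, mu)`; in the `kT -> 0` limit `D^i -> d_i(mu)`.
#'
#' @param energies level energies (eV) of the window.
#' @param Gamma_i level broadenings (eV, nonnegative).
#' @param mu chemical potential (eV).
#' @param kT thermal energy (eV, positive).
#' @param rel_tol quadrature relative tolerance.
#' @return numeric vector of D^i values (1/eV).
#' @export
compute_D <- function(energies, Gamma_i, mu, kT, rel_tol = 1e-9) {
  stopifnot(length(energies) == length(Gamma_i), all(Gamma_i >= 0), kT > 0)
  vapply(seq_along(energies), function(k) {
    Ek <- energies[k]; Gk <- Gamma_i[k]
    # delta-function limit: the Lorentzian is far narrower than the thermal
    # kernel, so the convolution is f(E_k) to O((Gamma/kT)^2)
    if (Gk < 1e-7 * kT) return(fermi_deriv(Ek, mu, kT))
    # substitute E = E_k + (Gamma/2) tan(theta): the Lorentzian measure
    # becomes d(theta)/pi on (-pi/2, pi/2), leaving a bounded smooth integrand
    f <- function(theta) {
      fermi_deriv(Ek + (Gk / 2) * tan(theta), mu, kT) / pi
    }
    # the thermal kernel peaks at theta* (E = mu) with theta-width ~ dtheta;
    # seed the adaptive rule with subdivisions on that scale
    theta_star <- atan(2 * (mu - Ek) / Gk)
    dtheta <- max(2 * kT * cos(theta_star)^2 / Gk, 1e-10)
    # geometric ladder away from the thermal peak keeps the log-variation of
    # the integrand bounded on every subinterval
    ladder <- dtheta * 5 * 4^(0:14)
    pieces <- sort(unique(pmax(-pi / 2, pmin(pi / 2,
      c(-pi / 2, 0, theta_star, theta_star + ladder, theta_star - ladder,
        pi / 2)))))
    total <- 0
    for (i in seq_len(length(pieces) - 1)) {
      if (pieces[i + 1] - pieces[i] < 1e-14) next
      q <- stats::integrate(f, pieces[i], pieces[i + 1], rel.tol = rel_tol,
                            abs.tol = 1e-16 / kT, subdivisions = 400L)
      if (q$message != "OK") {
        stop("D^i quadrature failed for level ", k, ": ", q$message,
             " (rel_tol = ", rel_tol, ")")
      }
      total <- total + q$value
    }
    total
  }, numeric(1))
}

#' Build the linearized Liouville evolution superoperator
#'
#' The superoperator acts on level-pair perturbations `drho^{pq}` of the
#' equilibrium density matrix and has four parts: the coherent term
#' `-i (E_i - E_j)`, the contact escape term
#' `-(1/2)(Gamma^{ip} delta_jq + delta_ip Gamma^{qj})`, the phonon gain term
#' `+(1/2)(gtilde^{ip} + gtilde^{jp}) delta_ij delta_pq`, and the phonon loss
#' term `-(1/2) sum_r (gtilde^{ri} + gtilde^{rj}) delta_ip delta_jq`.
#' Level pairs are flattened row-major: `(i, j) -> k = (i-1)*Nw + j`.
#' All entries are in eV; the physical generator is `L/hbar`.
#'
#' @param es an `electronic_structure`.
#' @param window level indices.
#' @param rates a `rate_matrix` carrying `gamma_tilde` (see [tilde_rates()]).
#' @param broad output of [contact_broadening()] on the same window (or NULL
#'   for no contacts).
#' @param max_window largest allowed window (the dense superoperator is
#'   Nw^2 x Nw^2).
#' @return object of class `superoperator`: list with complex matrix `L`,
#'   the four `components`, `window`, `energies`.
#' @export
build_superoperator <- function(es, window, rates, broad = NULL,
                                max_window = 80L) {
  Nw <- length(window)
  if (Nw > max_window) {
    stop("window of ", Nw, " levels gives a ", Nw^2, "^2 superoperator; ",
         "use the three-term approximation (three_term_conductance) instead")
  }
  if (!identical(as.integer(rates$window), as.integer(window))) {
    stop("rate matrix window does not match the requested window")
  }
  gt <- rates$gamma_tilde
  if (is.null(gt)) stop("rates must carry gamma_tilde; call tilde_rates() first")
  E <- es$energies[window]
  I <- diag(Nw)
  Gij <- if (is.null(broad)) matrix(0, Nw, Nw) else broad$Gamma_ij

  dE <- diag(E, nrow = Nw)
  coherent <- -1i * (kronecker(dE, I) - kronecker(I, dE))
  escape <- -0.5 * (kronecker(Gij, I) + kronecker(I, t(Gij)))
  gain <- matrix(0, Nw^2, Nw^2)
  idx_diag <- ((seq_len(Nw) - 1L) * Nw) + seq_len(Nw)   # (i,i) pairs
  gain[idx_diag, idx_diag] <- gt
  csum <- colSums(gt)                                   # sum_r gtilde^{ri}
  loss <- diag(-0.5 * (kronecker(csum, rep(1, Nw)) + kronecker(rep(1, Nw), csum)),
               nrow = Nw^2)

  L <- coherent + escape + gain + loss
  structure(list(L = L, components = list(coherent = coherent, escape = escape,
                                          gain = gain, loss = loss),
                 window = as.integer(window), energies = E),
            class = "superoperator")
}

#' @export
print.superoperator <- function(x, ...) {
  Nw <- length(x$window)
  cat(sprintf("superoperator: %d levels -> %d x %d complex matrix\n",
              Nw, Nw^2, Nw^2))
  invisible(x)
}

#' Net injected current matrix per contact bias
#'
#' `J^{ij} = (eU/2hbar) (Gamma_L^{ij} - Gamma_R^{ij}) (D^j + D^i)`: the
#' occupancy bias of the two contacts injects electrons near the left contact
#' and removes them near the right one. Returned in energy units per unit
#' `eU` (i.e. multiply by `eU/hbar` for a rate in 1/s).
#'
#' @param broad output of [contact_broadening()].
#' @param D vector of occupancy responses from [compute_D()].
#' @param eU bias energy `e*U` in eV (default 1: per-unit-bias matrix).
#' @return Nw x Nw symmetric matrix (dimensionless per eV of bias times eV).
#' @export
external_current <- function(broad, D, eU = 1) {
  dd <- outer(D, D, "+")
  0.5 * eU * (broad$Gamma_L_ij - broad$Gamma_R_ij) * dd
}

#' Full linear-response conductance from the Liouville superoperator
#'
#' Evaluates the exact linear-response conductance
#' `G = -(e^2 Gamma_L Gamma_R / hbar) * sum_{ijpq} { psi_L^i psi_L^j
#' [L^-1]^{jipq} psi_R^p psi_R^q + psi_R^i psi_R^j [L^-1]^{jipq}
#' psi_L^p psi_L^q } D^p(mu)` via two linear solves against the transposed
#' superoperator (the dense inverse is never formed). The formula carries the
#' spin degeneracy factor of two conduction channels.
#'
#' @param es an `electronic_structure`.
#' @param contacts a `contact_pair`.
#' @param bath a `bath_spec`.
#' @param window level indices; default `select_window(es, "levels_k", 20)`.
#' @param T temperature (K); defaults to `bath$T`.
#' @param rates optional precomputed `rate_matrix` with tilded rates.
#' @param ridge_rel Tikhonov ridge (relative to `max|L|`) applied when the
#'   plain solve fails on a near-singular superoperator.
#' @return object of class `conductance_result`.
#' @export
conductance_full <- function(es, contacts, bath,
                             window = select_window(es, "levels_k", 20),
                             T = NULL, rates = NULL, ridge_rel = 1e-12) {
  if (is.null(T)) T <- bath$T
  kT <- kT_eV(T)
  broad <- contact_broadening(es, contacts, window)
  if (is.null(rates)) {
    rates <- transition_rates(es, window, bath, warn_weak_coupling = FALSE)
    rates <- tilde_rates(rates, es, T = T)
  }
  sop <- build_superoperator(es, window, rates, broad)
  D <- compute_D(sop$energies, broad$Gamma_i, es$mu, kT)

  # l^{(L)}[(j,i)] = psi_L^i psi_L^j (symmetric); r^{(R)}[(p,q)] = psi_R^p psi_R^q D^p
  lL <- flatten_pairs(outer(broad$psi_L, broad$psi_L))
  lR <- flatten_pairs(outer(broad$psi_R, broad$psi_R))
  rR <- flatten_pairs(outer(broad$psi_R * D, broad$psi_R))
  rL <- flatten_pairs(outer(broad$psi_L * D, broad$psi_L))

  Lt <- t(sop$L)
  y <- tryCatch(solve(Lt, cbind(lL, lR) + 0i),
                error = function(e) {
                  ridge <- ridge_rel * max(abs(sop$L))
                  warning("superoperator near singular (", conditionMessage(e),
                          "); applying Tikhonov ridge ", format(ridge))
                  solve(Lt + ridge * diag(nrow(Lt)), cbind(lL, lR) + 0i)
                })
  contraction <- sum(y[, 1] * rR) + sum(y[, 2] * rL)
  # The printed weight D^p is asymmetric in the pair (p, q); its antisymmetric
  # part is purely imaginary in the contraction, so the real part equals the
  # (exactly real) symmetrized-D contraction. Verify that identity and report
  # the real part.
  Dsym <- outer(D, D, "+") / 2
  rRs <- flatten_pairs(outer(broad$psi_R, broad$psi_R) * Dsym)
  rLs <- flatten_pairs(outer(broad$psi_L, broad$psi_L) * Dsym)
  contraction_sym <- sum(y[, 1] * rRs) + sum(y[, 2] * rLs)
  if (abs(Re(contraction) - Re(contraction_sym)) >
      1e-9 * max(abs(Re(contraction_sym)), 1e-300)) {
    warning("asymmetric-D contraction deviates from its symmetrized real part by ",
            format(abs(Re(contraction) - Re(contraction_sym)) /
                     max(abs(Re(contraction_sym)), 1e-300)), " relative")
  }
  Gdim <- -contacts$Gamma_L * contacts$Gamma_R * contraction
  G_S <- Re(Gdim) * mc_constants$e2_over_hbar
  if (G_S < -1e-12) {
    stop("negative conductance (", format(G_S), " S): parameter regime outside ",
         "the validity of the linearized master equation")
  }
  conductance_result(G_S = G_S, method = "liouville_full",
                     parameters = list(mu = es$mu, T = T, kT = kT,
                                       Gamma_L = contacts$Gamma_L,
                                       Gamma_R = contacts$Gamma_R,
                                       window = range(window),
                                       n_window = length(window)))
}

#' Conductance result container
#'
#' @param G_S total conductance in Siemens.
#' @param components optional named list of component conductances (Siemens).
#' @param extras optional named list merged into the object (transmissions,
#'   thermal weights, ...).
#' @param method provenance tag.
#' @param parameters named list echoing the parameters used.
#' @return object of class `conductance_result` with `G_nS` and `G_overG0`
#'   (units of e^2/h) views.
#' @export
conductance_result <- function(G_S, components = NULL, extras = NULL,
                               method = "unspecified", parameters = list()) {
  out <- list(G_S = G_S, G_nS = G_S * 1e9,
              G_overG0 = G_S / mc_constants$e2_over_h,
              components = components, method = method,
              parameters = parameters)
  if (!is.null(extras)) out <- c(out, extras)
  structure(out, class = "conductance_result")
}

#' @export
print.conductance_result <- function(x, ...) {
  cat(sprintf("conductance_result (%s): G = %.6g nS  (%.6g e^2/h)\n",
              x$method, x$G_nS, x$G_overG0))
  if (!is.null(x$components)) {
    comp <- unlist(x$components)
    for (nm in names(comp)) {
      cat(sprintf("  %-6s = %.6g nS\n", nm, comp[[nm]] * 1e9))
    }
  }
  invisible(x)
}
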