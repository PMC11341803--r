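test_that("contact broadening is rank-2, PSD and traces to Gamma_L + Gamma_R", {
  set.seed(21)
  es <- rand_structure(8)
  cp <- contact_pair(2, 7, 0.05, 0.02)
  b <- contact_broadening(es, cp, 1:8)
  ev <- eigen(b$Gamma_ij, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(sum(abs(ev) > 1e-12 * max(abs(ev))), 3)   # rank <= 2
  expect_true(all(ev > -1e-14))
  # completeness: trace equals the total escape strength
  expect_equal(sum(b$Gamma_i), 0.05 + 0.02, tolerance = 1e-12)

  # a level fully localized on the contact orbital carries the full Gamma_L
  es1 <- electronic_structure(c(-1, 1), diag(2), 0, 1, 2)
  b1 <- contact_broadening(es1, contact_pair(1, 2, 0.3, 0.1), 1:2)
  expect_equal(b1$Gamma_i, c(0.3, 0.1))
})

test_that("occupancy response D^i has the correct limits and quadrature", {
  kT <- 0.025
  mu <- 0
  # Gamma -> 0: D -> f(E_i, mu)
  expect_equal(compute_D(0.1, 0, mu, kT), fermi_deriv(0.1, mu, kT))
  expect_equal(compute_D(0.1, 1e-9, mu, kT), fermi_deriv(0.1, mu, kT),
               tolerance = 1e-6)
  # kT -> 0 (relative to Gamma): D -> Lorentzian DOS at mu
  G <- 0.1
  d_mu <- (G / (2 * pi)) / (0.05^2 + (G / 2)^2)
  expect_equal(compute_D(0.05, G, mu, kT = 1e-5), d_mu, tolerance = 1e-3)
  # on-resonance E = mu, Gamma = kT against brute-force trapezoid
  E <- seq(mu - 50 * kT, mu + 50 * kT, length.out = 1e6)
  f <- fermi_deriv(E, mu, kT) * (kT / (2 * pi)) / (E^2 + (kT / 2)^2)
  brute <- sum((f[-1] + f[-length(f)]) / 2) * diff(E[1:2])
  expect_equal(compute_D(mu, kT, mu, kT), brute, tolerance = 1e-7)
  # positivity
  set.seed(2)
  D <- compute_D(rnorm(5), runif(5, 0, 0.2), mu, kT)
  expect_true(all(D > 0))
})

test_that("superoperator matches the element-wise definition at N_w = 4", {
  set.seed(31)
  es <- rand_structure(4)
  bath <- bath_spec(T = 300)
  cp <- contact_pair(1, 4, 0.03, 0.07)
  b <- contact_broadening(es, cp, 1:4)
  rm <- tilde_rates(transition_rates(es, 1:4, bath, warn_weak_coupling = FALSE), es)
  sop <- build_superoperator(es, 1:4, rm, b)
  Lnaive <- naive_superoperator(es$energies, rm$gamma_tilde, b$Gamma_ij)
  expect_lt(max(abs(sop$L - Lnaive)), 1e-12)

  # action on a random perturbation agrees with the quadruple-loop contraction
  drho <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  v <- molcond:::flatten_pairs(drho)
  expect_lt(max(abs(sop$L %*% v - Lnaive %*% v)), 1e-12)

  # N_w = 1 degenerates to the scalar -Gamma^11
  es1 <- electronic_structure(c(-1, 1), diag(2), 0, 1, 2)
  b1 <- contact_broadening(es1, contact_pair(1, 2, 0.2, 0.3), 1)
  rm1 <- tilde_rates(transition_rates(es1, 1, bath, warn_weak_coupling = FALSE), es1)
  sop1 <- build_superoperator(es1, 1, rm1, b1)
  expect_equal(as.complex(sop1$L), as.complex(-b1$Gamma_ij[1, 1]),
               tolerance = 1e-14)
})

test_that("relaxation part annihilates the Fermi-linearization direction", {
  # with Gamma = 0, the diagonal vector drho^pq = delta_pq f(E_p, mu) is a
  # zero mode of the phonon part (gain + loss), and the spectrum of L has no
  # positive real parts
  set.seed(32)
  es <- rand_structure(5)
  bath <- bath_spec(T = 300)
  rm <- tilde_rates(transition_rates(es, 1:5, bath, warn_weak_coupling = FALSE), es)
  sop <- build_superoperator(es, 1:5, rm, broad = NULL)
  fvec <- fermi_deriv(es$energies, es$mu, kT_eV(300))
  v <- molcond:::flatten_pairs(diag(fvec))
  expect_lt(max(abs(sop$L %*% v)), 1e-12 * max(abs(sop$L)))
  ev <- eigen(sop$L, only.values = TRUE)$values
  expect_lt(max(Re(ev)), 1e-10 * max(abs(sop$L)))

  # diagonal-pair sector with Gamma = 0 is a classical master-equation
  # generator: columns sum to zero
  idx <- (0:4) * 5 + 1:5
  M <- Re(sop$L[idx, idx])
  expect_lt(max(abs(colSums(M))), 1e-12 * max(abs(M)))
})

test_that("window cap and mismatched rate window are rejected", {
  set.seed(33)
  es <- rand_structure(6)
  bath <- bath_spec(T = 300)
  rm <- tilde_rates(transition_rates(es, 1:6, bath, warn_weak_coupling = FALSE), es)
  b <- contact_broadening(es, contact_pair(1, 6), 1:6)
  expect_error(build_superoperator(es, 1:6, rm, b, max_window = 2),
               "three_term")
  rm2 <- tilde_rates(transition_rates(es, 1:5, bath, warn_weak_coupling = FALSE), es)
  expect_error(build_superoperator(es, 1:6, rm2, b), "window")
})

test_that("external current is antisymmetric under contact exchange", {
  set.seed(34)
  es <- rand_structure(6)
  cp <- contact_pair(1, 6, 0.04, 0.09)
  b <- contact_broadening(es, cp, 1:6)
  D <- compute_D(es$energies, b$Gamma_i, es$mu, 0.025)
  J <- external_current(b, D)
  # naive loop evaluation
  Jn <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    Jn[i, j] <- 0.5 * (b$Gamma_L_ij[i, j] - b$Gamma_R_ij[i, j]) * (D[i] + D[j])
  }
  expect_equal(J, Jn, tolerance = 1e-14)
  # swapping contacts flips the sign
  cp2 <- contact_pair(6, 1, 0.09, 0.04)
  b2 <- contact_broadening(es, cp2, 1:6)
  expect_equal(external_current(b2, D), -J, tolerance = 1e-14)
  # zero bias, identical contact couplings
  expect_equal(external_current(b, D, eU = 0), 0 * J)
  bsame <- b; bsame$Gamma_R_ij <- bsame$Gamma_L_ij
  expect_equal(external_current(bsame, D), 0 * J)
})

test_that("full conductance matches the brute-force contraction at N_w = 4", {
  set.seed(35)
  rs <- make_model("dba_wire", n_sites = 4, t = 0.3, gap = 1, barrier = 2.5)
  es <- build_structure(rs, rs$n_electrons)
  bath <- bath_spec(T = 300)
  cp <- contact_pair(1, 4, 1e-3, 2e-3)
  win <- 1:4
  res <- conductance_full(es, cp, bath, window = win)

  b <- contact_broadening(es, cp, win)
  rm <- tilde_rates(transition_rates(es, win, bath, warn_weak_coupling = FALSE), es)
  D <- compute_D(es$energies[win], b$Gamma_i, es$mu, kT_eV(300))
  Gn <- naive_full_conductance(es$energies[win], rm$gamma_tilde, b$Gamma_ij,
                               b$psi_L, b$psi_R, cp$Gamma_L, cp$Gamma_R, D)
  expect_equal(res$G_S, Gn, tolerance = 1e-12)
  expect_gt(res$G_S, 0)
})

test_that("full conductance is symmetric and vanishes without coupling", {
  rs <- make_model("dba_wire", n_sites = 4, t = 0.3)
  es <- build_structure(rs, rs$n_electrons)
  bath <- bath_spec(T = 300)
  win <- 1:4
  g1 <- conductance_full(es, contact_pair(1, 4, 1e-3, 5e-4), bath, window = win)
  g2 <- conductance_full(es, contact_pair(4, 1, 5e-4, 1e-3), bath, window = win)
  expect_equal(g1$G_S, g2$G_S, tolerance = 1e-10)
  g0 <- conductance_full(es, contact_pair(1, 4, 0, 1e-3), bath, window = win)
  expect_equal(g0$G_S, 0)
})

test_that("conductance is invariant under rotations of degenerate eigenvectors", {
  # two exactly degenerate middle levels
  E <- c(-1, 0.5, 0.5, 2)
  set.seed(36)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  H <- Q %*% diag(E) %*% t(Q)
  sol <- solve_eigensystem(H)
  lev <- assign_levels(sol$energies, 2)
  es <- electronic_structure(sol$energies, sol$psi, lev$mu, lev$homo_index,
                             lev$lumo_index)
  # re-mix the degenerate pair by an arbitrary rotation
  th <- 0.77
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  psi2 <- sol$psi
  psi2[, 2:3] <- psi2[, 2:3] %*% R
  es2 <- electronic_structure(sol$energies, psi2, lev$mu, lev$homo_index,
                              lev$lumo_index)
  bath <- bath_spec(T = 300)
  cp <- contact_pair(1, 4, 1e-3, 1e-3)
  ga <- conductance_full(es, cp, bath, window = 1:4)
  gb <- conductance_full(es2, cp, bath, window = 1:4)
  expect_equal(ga$G_S, gb$G_S, tolerance = 1e-9)
})

test_that("randomized systems give nonnegative conductance", {
  set.seed(37)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    es <- rand_structure(n)
    cp <- contact_pair(1, n, 10^runif(1, -4, -2), 10^runif(1, -4, -2))
    bath <- bath_spec(T = runif(1, 100, 400))
    g <- conductance_full(es, cp, bath, window = seq_len(n))
    expect_gte(g$G_S, 0)
  }
})
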