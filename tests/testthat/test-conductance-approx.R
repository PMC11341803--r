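test_that("Breit-Wigner transmission reaches unity on a symmetric resonance", {
  # one level at mu, equal weight on both contact orbitals, equal couplings
  psi <- matrix(c(1, 1, 1, -1) / sqrt(2), 2)
  es <- electronic_structure(c(0, 1), psi, mu = 0, 1, 2, check = FALSE)
  cp <- contact_pair(1, 2, 0.05, 0.05)
  expect_equal(breit_wigner_T(es, cp, mu = 0, window = 1L), 1, tolerance = 1e-12)

  # no amplitude on one contact: zero transmission
  psi0 <- diag(2)
  es0 <- electronic_structure(c(-1, 1), psi0, 0, 1, 2)
  expect_equal(breit_wigner_T(es0, contact_pair(1, 2), window = 1:2), 0)
})

test_that("transmission sums match a naive loop on a disordered chain", {
  set.seed(41)
  rs <- make_model("disordered_wire", n_sites = 8, W = 1, seed = 4)
  es <- build_structure(rs, rs$n_electrons)
  cp <- contact_pair(2, 7, 0.1, 0.08)
  win <- 1:8
  Tfast <- breit_wigner_T(es, cp, window = win)
  acc <- 0
  accL <- 0; accR <- 0
  for (k in win) {
    pl2 <- es$psi[2, k]^2; pr2 <- es$psi[7, k]^2
    Gk <- 0.1 * pl2 + 0.08 * pr2
    den <- (es$mu - es$energies[k])^2 + (Gk / 2)^2
    acc <- acc + 0.1 * 0.08 * pl2 * pr2 / den
    accL <- accL + 0.1^2 * pl2^2 / den
    accR <- accR + 0.08^2 * pr2^2 / den
  }
  expect_equal(Tfast, acc, tolerance = 1e-12)
  tlr <- molcond:::contact_transmissions(es, cp, es$mu, win)
  expect_equal(tlr$T_L, accL, tolerance = 1e-12)
  expect_equal(tlr$T_R, accR, tolerance = 1e-12)
})

test_that("thermal weights behave like Boltzmann-suppressed excitation", {
  # single level at mu: Z = Gamma |psi|^2 / 4kT
  psi <- matrix(c(1, 1, 1, -1) / sqrt(2), 2)
  es <- electronic_structure(c(0, 1), psi, mu = 0, 1, 2, check = FALSE)
  cp <- contact_pair(1, 2, 0.1, 0.1)
  kT <- 0.025
  z <- thermal_weights(es, cp, kT = kT, window = 1L)
  expect_equal(z$Z_L, 0.1 * 0.5 / (4 * kT), tolerance = 1e-12)

  # 10 kT detuning suppresses by cosh^2(5) relative to resonance
  es2 <- electronic_structure(c(10 * kT, 1), psi, mu = 0, 1, 2, check = FALSE)
  z2 <- thermal_weights(es2, cp, kT = kT, window = 1L)
  expect_equal(z$Z_L / z2$Z_L, cosh(5)^2, tolerance = 1e-10)

  # linearity in Gamma_L
  z3 <- thermal_weights(es, contact_pair(1, 2, 0.2, 0.1), kT = kT, window = 1L)
  expect_equal(z3$Z_L, 2 * z$Z_L, tolerance = 1e-12)

  # kT = 0 returns exact zero with a flag
  z0 <- thermal_weights(es, cp, kT = 0, window = 1L)
  expect_true(z0$zero_T)
  expect_equal(z0$Z_L, 0)

  # monotone increasing in T for an off-resonant spectrum
  esg <- electronic_structure(c(-0.5, 0.5), psi, 0, 1, 2)
  zs <- sapply(c(0.005, 0.01, 0.02, 0.04), function(k)
    thermal_weights(esg, cp, kT = k, window = 1:2)$Z_L)
  expect_true(all(diff(zs) > 0))
})

test_that("three-term conductance assembles the printed prefactors", {
  set.seed(42)
  rs <- make_model("disordered_wire", n_sites = 10, W = 0.8, seed = 9)
  es <- build_structure(rs, rs$n_electrons)
  cp <- contact_pair(1, 10, 0.1, 0.1)
  kT <- kT_eV(300)
  win <- 1:10
  g <- three_term_conductance(es, cp, kT = kT, window = win)

  # independent reimplementation with plain loops and linear-space Z
  e2h <- mc_constants$e2_over_h
  Tsum <- breit_wigner_T(es, cp, window = win)
  Z_L <- sum(0.1 * es$psi[1, win]^2 /
               (4 * kT * cosh((es$mu - es$energies[win]) / (2 * kT))^2))
  Z_R <- sum(0.1 * es$psi[10, win]^2 /
               (4 * kT * cosh((es$mu - es$energies[win]) / (2 * kT))^2))
  tlr <- molcond:::contact_transmissions(es, cp, es$mu, win)
  G_LB <- 2 * e2h * Tsum
  G_T <- 2 * (2 * pi * e2h) * Z_L * Z_R / (Z_L + Z_R)
  G_M <- e2h * (Z_L / (Z_L + Z_R) * tlr$T_R + Z_R / (Z_L + Z_R) * tlr$T_L)
  expect_equal(g$components$G_LB, G_LB, tolerance = 1e-12)
  expect_equal(g$components$G_T, G_T, tolerance = 1e-10)
  expect_equal(g$components$G_M, G_M, tolerance = 1e-10)
  expect_equal(g$G_S, G_LB + G_T + G_M, tolerance = 1e-12)
  expect_true(all(c(G_LB, G_T, G_M) >= 0))

  # harmonized-hbar sensitivity flag rescales only the thermal term
  gh <- three_term_conductance(es, cp, kT = kT, window = win,
                               harmonize_hbar = TRUE)
  expect_equal(gh$components$G_T * 2 * pi, g$components$G_T, tolerance = 1e-10)
  expect_equal(gh$components$G_LB, g$components$G_LB)
})

test_that("symmetric thermal weights halve in the printed combinations", {
  # Z_L = Z_R = Z implies G_T = (2e^2/hbar) Z/2, G_M = (e^2/h)(T_L + T_R)/2
  rs <- make_model("uniform_chain", n_sites = 4, t = 0.3)
  es <- build_structure(rs, 4)
  cp <- contact_pair(1, 4, 0.05, 0.05)   # mirror-symmetric chain
  kT <- 0.025
  z <- thermal_weights(es, cp, kT = kT, window = 1:4)
  expect_equal(z$Z_L, z$Z_R, tolerance = 1e-10)
  g <- three_term_conductance(es, cp, kT = kT, window = 1:4)
  expect_equal(g$components$G_T, 2 * mc_constants$e2_over_hbar * z$Z_L / 2,
               tolerance = 1e-10)
  tlr <- molcond:::contact_transmissions(es, cp, es$mu, 1:4)
  expect_equal(g$components$G_M,
               mc_constants$e2_over_h * (tlr$T_L + tlr$T_R) / 2,
               tolerance = 1e-10)
})

test_that("G_M stays finite at 10 K via log-space branching ratios", {
  rs <- make_model("dba_wire", n_sites = 5, t = 0.2, gap = 1)
  es <- build_structure(rs, rs$n_electrons)
  cp <- contact_pair(1, 5, 0.1, 0.1)
  g10 <- three_term_conductance(es, cp, kT = kT_eV(10), window = 1:5)
  expect_gt(g10$components$G_M, 0)
  expect_false(is.nan(g10$G_S))
  # thermal term is utterly frozen out at 10 K for a ~1 eV gap
  expect_lt(g10$components$G_T, g10$components$G_M * 1e-10)
})

test_that("pairwise tabulation is deterministic and carries distances", {
  rs <- make_model("uniform_chain", n_sites = 6, t = 0.3, spacing = 2)
  es <- build_structure(rs, rs$n_electrons)
  tab <- pairwise_G(es, rbind(c(1, 6), c(2, 5), c(1, 6)), kT = 0.025)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$distance_A, c(10, 6, 10))
  expect_equal(tab[1, -c(1, 2)], tab[3, -c(1, 2)], ignore_attr = TRUE)
  expect_equal(tab$G_nS, tab$G_LB_nS + tab$G_T_nS + tab$G_M_nS,
               tolerance = 1e-10)
  empty <- pairwise_G(es, matrix(integer(), ncol = 2), kT = 0.025)
  expect_equal(nrow(empty), 0)
  expect_error(pairwise_G(es, rbind(c(0, 3)), kT = 0.025), "out of range")
})
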