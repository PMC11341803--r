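# Independent brute-force oracles used to validate the vectorized
# implementations. All of these are deliberately naive (explicit loops,
# direct dense inverses) and small-N only.

rand_symmetric <- function(n, scale = 1) {
  A <- matrix(stats::rnorm(n * n, sd = scale), n, n)
  (A + t(A)) / 2
}

rand_spd_overlap <- function(n, strength = 0.3) {
  A <- matrix(stats::rnorm(n * n, sd = strength), n, n)
  S <- diag(n) + (A + t(A)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0.05) S <- S + (0.05 - min(ev)) * diag(n)
  S
}

# random electronic structure on an orthogonal basis with a gap at mu
rand_structure <- function(n, gap = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- rand_symmetric(n)
  sol <- solve_eigensystem(H)
  n_el <- 2 * floor(n / 2)
  if (n_el >= 2 * n) n_el <- 2 * n - 2
  lev <- assign_levels(sol$energies, n_el)
  electronic_structure(sol$energies, sol$psi, lev$mu, lev$homo_index,
                       lev$lumo_index, basis = "orthogonal")
}

# element-by-element construction of the linearized superoperator
naive_superoperator <- function(E, gt, Gij) {
  Nw <- length(E)
  L <- matrix(0 + 0i, Nw^2, Nw^2)
  idx <- function(i, j) (i - 1) * Nw + j
  for (i in 1:Nw) for (j in 1:Nw) for (p in 1:Nw) for (q in 1:Nw) {
    v <- 0 + 0i
    if (i == p && j == q) v <- v - 1i * (E[i] - E[j])
    if (j == q) v <- v - 0.5 * Gij[i, p]
    if (i == p) v <- v - 0.5 * Gij[q, j]
    if (i == j && p == q) v <- v + 0.5 * (gt[i, p] + gt[j, p])
    if (i == p && j == q) v <- v - 0.5 * sum(gt[, i] + gt[, j])
    L[idx(i, j), idx(p, q)] <- v
  }
  L
}

# quadruple-loop evaluation of the full conductance contraction, using a
# dense inverse of the superoperator
naive_full_conductance <- function(E, gt, Gij, psi_L, psi_R, Gamma_L, Gamma_R, D) {
  Nw <- length(E)
  L <- naive_superoperator(E, gt, Gij)
  Linv <- solve(L)
  idx <- function(i, j) (i - 1) * Nw + j
  acc <- 0 + 0i
  for (i in 1:Nw) for (j in 1:Nw) for (p in 1:Nw) for (q in 1:Nw) {
    acc <- acc +
      psi_L[i] * psi_L[j] * Linv[idx(j, i), idx(p, q)] * psi_R[p] * psi_R[q] * D[p] +
      psi_R[i] * psi_R[j] * Linv[idx(j, i), idx(p, q)] * psi_L[p] * psi_L[q] * D[p]
  }
  Re(-Gamma_L * Gamma_R * acc) * mc_constants$e2_over_hbar
}

# term-by-term master-equation right-hand side (hbar = 1 units)
naive_me_rhs <- function(rho, E, gamma, Gij = NULL, J = NULL) {
  Nw <- length(E)
  out <- matrix(0 + 0i, Nw, Nw)
  for (i in 1:Nw) for (j in 1:Nw) {
    v <- -1i * (E[i] - E[j]) * rho[i, j]
    if (!is.null(Gij)) {
      for (r in 1:Nw) v <- v - 0.5 * (Gij[i, r] * rho[r, j] + rho[i, r] * Gij[r, j])
    }
    relax <- 0 + 0i
    for (p in 1:Nw) {
      relax <- relax + ((i == j) - rho[i, j]) * 0.5 * (gamma[i, p] + gamma[j, p]) * rho[p, p]
      relax <- relax - rho[i, j] * 0.5 * (gamma[p, i] + gamma[p, j]) * (1 - rho[p, p])
    }
    v <- v + relax
    if (!is.null(J)) v <- v + J[i, j]
    out[i, j] <- v
  }
  out
}

# per-point loop evaluation of the conductivity maps
naive_maps <- function(es, points, kT, window) {
  W <- if (!is.null(es$coeff_ao)) es$coeff_ao else es$psi
  zs <- numeric(nrow(points))
  ts <- numeric(nrow(points))
  for (ipt in seq_len(nrow(points))) {
    for (k in window) {
      psi <- 0
      for (r in seq_len(nrow(es$meta))) {
        psi <- psi + W[r, k] *
          sto_value(points[ipt, , drop = FALSE],
                    c(es$meta$x[r], es$meta$y[r], es$meta$z[r]),
                    es$meta$n[r], es$meta$l[r], es$meta$m[r], es$meta$zeta[r])
      }
      zs[ipt] <- zs[ipt] + psi^2 / cosh((es$mu - es$energies[k]) / (2 * kT))^2
      ts[ipt] <- ts[ipt] + psi^4 / (es$mu - es$energies[k])^2
    }
  }
  list(Z = zs, T = ts)
}

# standard pipeline shared by many tests
toy_pipeline <- function(rs, T = 300, Gamma = 1e-3, sites = NULL) {
  es <- build_structure(rs, rs$n_electrons)
  bath <- bath_spec(T = T)
  n <- length(es$energies)
  if (is.null(sites)) sites <- c(1, n)
  cp <- contact_pair(sites[1], sites[2], Gamma, Gamma)
  list(es = es, bath = bath, cp = cp, window = seq_len(n))
}
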