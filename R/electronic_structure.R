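#' Raw LCAO system: Hamiltonian, overlap and orbital metadata
#'
#' Bundles the real symmetric Hamiltonian `H` (eV) and overlap matrix `S`
#' (dimensionless, symmetric positive definite) in the atomic-orbital basis,
#' together with optional per-orbital metadata (host atom, element, quantum
#' numbers, Slater exponent, coordinates, hydrogen flag).
#'
#' @param H N x N real symmetric Hamiltonian (eV).
#' @param S N x N overlap matrix; defaults to the identity.
#' @param orbital_meta optional data.frame with one row per orbital. Recognised
#'   columns: `atom`, `element`, `n`, `l`, `m`, `zeta`, `x`, `y`, `z`,
#'   `is_hydrogen`.
#' @param sym_tol relative tolerance for the symmetry checks.
#' @return an object of class `raw_system`.
#' @export
raw_system <- function(H, S = NULL, orbital_meta = NULL, sym_tol = 1e-8) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H))
  N <- nrow(H)
  if (is.null(S)) S <- diag(N)
  stopifnot(is.matrix(S), nrow(S) == N, ncol(S) == N)
  scale_H <- max(abs(H), 1e-300)
  if (max(abs(H - t(H))) > sym_tol * scale_H) stop("H is not symmetric")
  if (max(abs(S - t(S))) > sym_tol * max(abs(S))) stop("S is not symmetric")
  if (!is.null(orbital_meta)) {
    stopifnot(is.data.frame(orbital_meta), nrow(orbital_meta) == N)
  }
  structure(list(H = (H + t(H)) / 2, S = (S + t(S)) / 2,
                 n_orbitals = N, orbital_meta = orbital_meta),
            class = "raw_system")
}

#' @export
print.raw_system <- function(x, ...) {
  cat("raw_system:", x$n_orbitals, "orbitals;",
      if (is.null(x$orbital_meta)) "no orbital metadata" else "with orbital metadata",
      "\n")
  invisible(x)
}

#' Loewdin orthogonalization of a non-orthogonal LCAO Hamiltonian
#'
#' Computes the symmetrically orthogonalized Hamiltonian
#' `Ht = S^(-1/2) H S^(-1/2)`. Its ordinary eigenvalues equal the generalized
#' eigenvalues of the pencil (H, S), and its eigenvectors define molecular
#' orbitals in the orthonormal Loewdin atomic-orbital basis.
#'
#' @param x a `raw_system`, or an H matrix if `S` is supplied.
#' @param S overlap matrix when `x` is a plain matrix.
#' @return symmetric matrix `Ht` (eV) with attribute `basis = "lowdin"`.
#' @export
lowdin_orthogonalize <- function(x, S = NULL) {
  if (inherits(x, "raw_system")) {
    H <- x$H; S <- x$S
  } else {
    H <- x
    if (is.null(S)) S <- diag(nrow(H))
  }
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) <= 0) {
    stop("overlap matrix is not positive definite (smallest eigenvalue ",
         format(min(es$values), digits = 6), ")")
  }
  Sinvsqrt <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  Ht <- Sinvsqrt %*% H %*% Sinvsqrt
  Ht <- (Ht + t(Ht)) / 2
  attr(Ht, "basis") <- "lowdin"
  attr(Ht, "Sinvsqrt") <- Sinvsqrt
  Ht
}

#' Solve the symmetric eigenproblem with a fixed sign convention
#'
#' Eigenvalues are returned ascending; every eigenvector is normalized and its
#' sign is fixed so that the largest-magnitude component is positive (ties are
#' broken by the lowest orbital index), making serialized results reproducible
#' across LAPACK builds.
#'
#' @param Ht real symmetric matrix (eV).
#' @param sym_tol relative symmetry tolerance.
#' @return list with `energies` (ascending, eV) and `psi` (orthonormal matrix;
#'   column i is the eigenvector of energy i, rows index orbitals).
#' @export
solve_eigensystem <- function(Ht, sym_tol = 1e-8) {
  stopifnot(is.matrix(Ht))
  if (max(abs(Ht - t(Ht))) > sym_tol * max(abs(Ht), 1e-300)) {
    stop("matrix is not symmetric")
  }
  e <- eigen((Ht + t(Ht)) / 2, symmetric = TRUE)
  ord <- order(e$values)       # eigen() returns decreasing order
  energies <- e$values[ord]
  psi <- e$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(psi))) {
    j <- which.max(abs(psi[, k]))  # first index on ties
    if (psi[j, k] < 0) psi[, k] <- -psi[, k]
  }
  list(energies = energies, psi = psi)
}

#' Assign HOMO/LUMO indices and the chemical potential
#'
#' In the closed-shell single-electron picture each level holds two electrons,
#' so the HOMO index is `n_electrons / 2` (1-based). The chemical potential
#' defaults to the midgap value `(E_HOMO + E_LUMO)/2`; it can be overridden
#' explicitly, and `homo_shift` moves the HOMO by a fixed number of levels
#' (e.g. to correct an electron count that includes spurious atoms).
#'
#' @param energies ascending level energies (eV).
#' @param n_electrons even, positive electron count, at most `2N - 2` so that
#'   an unoccupied LUMO exists.
#' @param homo_shift integer shift applied to the automatic HOMO index.
#' @param mu optional explicit chemical potential (eV).
#' @return list with `homo_index`, `lumo_index` (1-based) and `mu`.
#' @export
assign_levels <- function(energies, n_electrons, homo_shift = 0L, mu = NULL) {
  N <- length(energies)
  if (n_electrons %% 2 != 0) {
    stop("odd electron count: the closed-shell single-electron picture needs an even n_electrons")
  }
  homo <- n_electrons / 2 + homo_shift
  if (homo < 1) stop("no occupied level: n_electrons/2 + homo_shift < 1")
  if (homo >= N) {
    stop("all ", N, " levels occupied (n_electrons/2 + homo_shift = ", homo,
         "): no LUMO exists; reduce the electron count")
  }
  lumo <- homo + 1
  if (is.null(mu)) mu <- (energies[homo] + energies[lumo]) / 2
  list(homo_index = as.integer(homo), lumo_index = as.integer(lumo), mu = mu)
}

#' Construct an electronic-structure object
#'
#' Convenience pipeline: Loewdin-orthogonalize, diagonalize, and position the
#' chemical potential. The result is the central input of all conductance
#' routines.
#'
#' @param raw a `raw_system`.
#' @param n_electrons even electron count.
#' @param homo_shift,mu passed to [assign_levels()].
#' @return object of class `electronic_structure` with fields `energies`,
#'   `psi` (columns are molecular orbitals over Loewdin atomic orbitals),
#'   `mu`, `homo_index`, `lumo_index`, `basis`, `meta` (orbital metadata,
#'   possibly NULL), `mu_is_default` flag.
#' @export
build_structure <- function(raw, n_electrons, homo_shift = 0L, mu = NULL) {
  Ht <- lowdin_orthogonalize(raw)
  sol <- solve_eigensystem(Ht)
  lev <- assign_levels(sol$energies, n_electrons, homo_shift = homo_shift, mu = mu)
  es <- electronic_structure(sol$energies, sol$psi, lev$mu, lev$homo_index,
                             lev$lumo_index, basis = "lowdin",
                             meta = raw$orbital_meta, mu_is_default = is.null(mu))
  # LCAO coefficients over the original (non-orthogonal) atomic orbitals,
  # needed to rebuild molecular orbitals in real space: W = S^(-1/2) psi
  es$coeff_ao <- attr(Ht, "Sinvsqrt") %*% sol$psi
  es
}

#' Low-level electronic-structure constructor
#'
#' @param energies ascending eigenvalues (eV).
#' @param psi orthonormal eigenvector matrix (rows: orbitals, columns: levels).
#' @param mu chemical potential (eV).
#' @param homo_index,lumo_index 1-based level indices.
#' @param basis `"orthogonal"` or `"lowdin"`.
#' @param meta optional orbital metadata data.frame.
#' @param mu_is_default whether `mu` is the automatic midgap placement.
#' @param check validate orthonormality and ordering.
#' @return object of class `electronic_structure`.
#' @export
electronic_structure <- function(energies, psi, mu, homo_index, lumo_index,
                                 basis = c("orthogonal", "lowdin"),
                                 meta = NULL, mu_is_default = TRUE,
                                 check = TRUE) {
  basis <- match.arg(basis)
  if (check) {
    stopifnot(length(energies) == ncol(psi), nrow(psi) == ncol(psi))
    if (is.unsorted(energies)) stop("energies must be ascending")
    ortho <- crossprod(psi)
    if (max(abs(ortho - diag(ncol(psi)))) > 1e-8) {
      stop("eigenvectors are not orthonormal")
    }
    if (mu < energies[homo_index] - 1e-9 || mu > energies[lumo_index] + 1e-9) {
      stop("mu must lie between E_HOMO and E_LUMO")
    }
  }
  structure(list(energies = energies, psi = psi, mu = mu,
                 homo_index = as.integer(homo_index),
                 lumo_index = as.integer(lumo_index),
                 basis = basis, meta = meta, mu_is_default = mu_is_default),
            class = "electronic_structure")
}

#' @export
print.electronic_structure <- function(x, ...) {
  N <- length(x$energies)
  gap <- x$energies[x$lumo_index] - x$energies[x$homo_index]
  cat("electronic_structure:", N, "levels (", x$basis, "basis )\n")
  cat(sprintf("  HOMO %d at %.4f eV, LUMO %d at %.4f eV, gap %.4f eV\n",
              x$homo_index, x$energies[x$homo_index],
              x$lumo_index, x$energies[x$lumo_index], gap))
  cat(sprintf("  mu = %.4f eV%s\n", x$mu,
              if (isTRUE(x$mu_is_default)) " (midgap default)" else ""))
  invisible(x)
}

#' Select a window of levels around the HOMO-LUMO gap
#'
#' Two selection rules are supported: a fixed number of levels on either side
#' of the frontier orbitals (`levels_k`, e.g. HOMO-20 .. LUMO+20), or an
#' energy window of `size` thermal energies around the frontier energies
#' (`energy_kT`, e.g. within 5 kT of HOMO and LUMO). Indices are clipped to
#' the spectrum.
#'
#' @param es an `electronic_structure`.
#' @param mode `"levels_k"` or `"energy_kT"`.
#' @param size window half-width: a level count, or a multiple of kT.
#' @param kT thermal energy in eV (required for `energy_kT`).
#' @return sorted integer vector of level indices.
#' @export
select_window <- function(es, mode = c("levels_k", "energy_kT"), size = 20,
                          kT = NULL) {
  mode <- match.arg(mode)
  N <- length(es$energies)
  if (mode == "levels_k") {
    lo <- max(1L, es$homo_index - as.integer(size))
    hi <- min(N, es$lumo_index + as.integer(size))
    seq.int(lo, hi)
  } else {
    if (is.null(kT) || kT < 0) stop("energy_kT mode needs a nonnegative kT")
    lo <- es$energies[es$homo_index] - size * kT
    hi <- es$energies[es$lumo_index] + size * kT
    which(es$energies >= lo & es$energies <= hi)
  }
}

#' Read atom coordinates and elements from a PDB file
#'
#' Only ATOM/HETATM coordinates (Angstrom), element symbols and hydrogen
#' flags are used; the electronic structure itself always comes from the
#' H/S matrices.
#'
#' @param path PDB file path.
#' @return data.frame with columns `serial`, `element`, `x`, `y`, `z`,
#'   `is_hydrogen`.
#' @export
read_structure_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_structure_pdb requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- a$elesy
  # fallback: derive element from the atom name when the element column is blank
  blank <- is.na(elem) | trimws(elem) == ""
  if (any(blank)) {
    guess <- sub("^[0-9]*", "", trimws(a$elety[blank]))
    elem[blank] <- substr(guess, 1, 1)
  }
  elem <- trimws(elem)
  data.frame(serial = a$eleno, element = elem,
             x = a$x, y = a$y, z = a$z,
             is_hydrogen = toupper(elem) == "H",
             stringsAsFactors = FALSE)
}
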