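# Generators for toy molecules with known physics: tight-binding chains,
# donor-bridge-acceptor wires, disordered wires and two-level systems. These
# stand in for real extended-Hueckel matrices so the whole pipeline can be
# exercised without external data.

#' Synthetic model specification
#'
#' @param kind one of `"uniform_chain"`, `"dba_wire"`, `"disordered_wire"`,
#'   `"two_level"`.
#' @param n_sites number of sites (orbitals); forced to 2 for `two_level`.
#' @param eps on-site energy (eV). For `dba_wire` this is the donor/acceptor
#'   mean; for `two_level` it is the level-pair center.
#' @param t nearest-neighbour hopping (eV, enters as `-t`).
#' @param spacing collinear site spacing (Angstrom).
#' @param gap donor-acceptor (or two-level) gap (eV). Default 1 eV, a
#'   protein-like HOMO-LUMO scale.
#' @param barrier bridge-site offset above `eps` for `dba_wire` (eV).
#' @param W site-disorder width for `disordered_wire` (eV).
#' @param n_electrons electron count; defaults to half filling rounded to the
#'   nearest even count (at least 2, at most 2 n_sites - 2).
#' @param overlap `"identity"` or `"gaussian"` (Gaussian-kernel SPD overlap
#'   with length scale `overlap_r0`).
#' @param overlap_r0 Gaussian overlap length scale (Angstrom).
#' @param seed RNG seed for `disordered_wire`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(kind = c("uniform_chain", "dba_wire",
                                "disordered_wire", "two_level"),
                       n_sites = 10, eps = 0, t = 1, spacing = 1.5,
                       gap = 1, barrier = 3, W = 0.5,
                       n_electrons = NULL, overlap = c("identity", "gaussian"),
                       overlap_r0 = 1, seed = 1) {
  kind <- match.arg(kind)
  overlap <- match.arg(overlap)
  if (kind == "two_level") n_sites <- 2L
  n_sites <- as.integer(n_sites)
  if (n_sites < 2) stop("need at least 2 sites")
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(n_electrons)) {
    n_electrons <- if (kind == "dba_wire") 2L else {
      max(2L, min(2L * n_sites - 2L, 2L * floor(n_sites / 2)))
    }
    if (n_electrons >= 2L * n_sites) n_electrons <- 2L * n_sites - 2L
  }
  structure(list(kind = kind, n_sites = n_sites, eps = eps, t = t,
                 spacing = spacing, gap = gap, barrier = barrier, W = W,
                 n_electrons = as.integer(n_electrons), overlap = overlap,
                 overlap_r0 = overlap_r0, seed = as.integer(seed)),
            class = "model_spec")
}

#' Generate a synthetic model molecule
#'
#' Builds the Hamiltonian, overlap and collinear geometry of the model
#' described by a [model_spec()]:
#' \itemize{
#'   \item `uniform_chain`: tridiagonal H with on-site `eps` and hopping `-t`;
#'   \item `dba_wire`: donor and acceptor sites at `eps -/+ gap/2` joined by a
#'     bridge of sites at `eps + barrier`, giving tunable tunneling decay;
#'   \item `disordered_wire`: chain with on-site energies uniform in
#'     `eps +/- W/2` (seeded);
#'   \item `two_level`: 2 x 2 system with gap `gap` (hopping mixes the sites).
#' }
#'
#' @param spec a `model_spec` (or arguments forwarded to [model_spec()]).
#' @param ... forwarded to [model_spec()] when `spec` is a kind string.
#' @return a [raw_system()] with orbital metadata (single s-orbital per site,
#'   carbon-like, collinear along x).
#' @export
make_model <- function(spec, ...) {
  if (is.character(spec)) spec <- model_spec(spec, ...)
  stopifnot(inherits(spec, "model_spec"))
  n <- spec$n_sites
  onsite <- switch(spec$kind,
    uniform_chain = rep(spec$eps, n),
    dba_wire = {
      v <- rep(spec$eps + spec$barrier, n)
      v[1] <- spec$eps - spec$gap / 2
      v[n] <- spec$eps + spec$gap / 2
      v
    },
    disordered_wire = {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(spec$seed)
      spec$eps + stats::runif(n, -spec$W / 2, spec$W / 2)
    },
    two_level = {
      # site energies +/- sqrt(gap^2/4 - t^2) give eigenvalue gap = spec$gap
      if (2 * spec$t > spec$gap) {
        stop("two_level: need gap >= 2 t for real site energies")
      }
      delta <- sqrt((spec$gap / 2)^2 - spec$t^2)
      c(spec$eps - delta, spec$eps + delta)
    })
  H <- diag(onsite)
  for (i in seq_len(n - 1)) H[i, i + 1] <- H[i + 1, i] <- -spec$t
  x <- (seq_len(n) - 1) * spec$spacing
  S <- if (spec$overlap == "identity") diag(n) else {
    exp(-(outer(x, x, "-") / spec$overlap_r0)^2)
  }
  meta <- data.frame(atom = seq_len(n), element = "C",
                     n = 1L, l = 0L, m = 0L, zeta = 1.3,
                     x = x, y = 0, z = 0, is_hydrogen = FALSE,
                     stringsAsFactors = FALSE)
  rs <- raw_system(H, S, orbital_meta = meta)
  rs$n_electrons <- spec$n_electrons
  rs$spec <- spec
  rs
}

# analytic overlap of two 1s Slater orbitals with equal exponent zeta (1/A)
sto1s_overlap <- function(R, zeta) {
  x <- zeta * R
  exp(-x) * (1 + x + x^2 / 3)
}

#' Toy all-s Slater-orbital system with analytic overlap
#'
#' One 1s Slater orbital per atom on a collinear geometry; the overlap matrix
#' uses the closed-form 1s-1s integral, and the Hamiltonian follows the
#' Wolfsberg-Helmholz extended-Hueckel rule
#' `H_rs = K S_rs (H_rr + H_ss) / 2` with `K = 1.75` (a standard
#' semi-empirical choice). Exercises the spatial-map pipeline end to end.
#'
#' @param n_atoms number of atoms.
#' @param elements element symbols, recycled to `n_atoms`.
#' @param spacing collinear spacing (Angstrom).
#' @param zeta Slater exponent (1/Angstrom).
#' @param H_ii on-site energy (eV), recycled.
#' @param K Wolfsberg-Helmholz constant.
#' @return a [raw_system()] with orbital metadata; `n_electrons` defaults to
#'   `n_atoms` rounded down to even (half filling).
#' @export
make_toy_sto_system <- function(n_atoms, elements = "C", spacing = 1.5,
                                zeta = 1.3, H_ii = -10, K = 1.75) {
  n <- as.integer(n_atoms)
  elements <- rep_len(elements, n)
  H_ii <- rep_len(H_ii, n)
  x <- (seq_len(n) - 1) * spacing
  S <- outer(x, x, function(a, b) sto1s_overlap(abs(a - b), zeta))
  H <- 0.5 * K * S * outer(H_ii, H_ii, "+")
  diag(H) <- H_ii
  meta <- data.frame(atom = seq_len(n), element = elements,
                     n = 1L, l = 0L, m = 0L, zeta = zeta,
                     x = x, y = 0, z = 0,
                     is_hydrogen = toupper(elements) == "H",
                     stringsAsFactors = FALSE)
  rs <- raw_system(H, S, orbital_meta = meta)
  rs$n_electrons <- max(2L, 2L * floor(n / 2))
  if (rs$n_electrons >= 2L * n) rs$n_electrons <- 2L * n - 2L
  rs
}
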