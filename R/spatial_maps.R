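# Spatially continuous conductivity indicators on 3-D rectangular grids.
# Molecular orbitals are rebuilt in real space from LCAO coefficients over
# Slater-type orbitals; the thermal-accessibility map Z(r) and the
# tunneling-accessibility map T(r) locate the conductive regions.

# --- Slater-type orbitals -------------------------------------------------

# radial part N r^(n-1) exp(-zeta r), normalized so int |phi|^2 dV = 1
# with the real-spherical-harmonic angular part
sto_radial <- function(r, n, zeta) {
  norm <- (2 * zeta)^(n + 0.5) / sqrt(factorial(2 * n))
  norm * r^(n - 1) * exp(-zeta * r)
}

# real spherical harmonics for l = 0, 1 (m = -1, 0, 1 -> y, z, x)
sto_angular <- function(l, m, dx, dy, dz, r) {
  if (l == 0) return(rep(sqrt(1 / (4 * pi)), length(r)))
  if (l == 1) {
    comp <- switch(as.character(m), "-1" = dy, "0" = dz, "1" = dx)
    out <- sqrt(3 / (4 * pi)) * comp / r
    out[r == 0] <- 0
    return(out)
  }
  stop("Slater orbitals with l > 1 are not supported")
}

#' Evaluate one Slater orbital on points
#'
#' @param points M x 3 matrix of coordinates (Angstrom).
#' @param center length-3 orbital center (Angstrom).
#' @param n,l,m quantum numbers (l in 0:1).
#' @param zeta Slater exponent; units set by `zeta_unit` (`"invA"` or
#'   `"invBohr"`).
#' @param zeta_unit exponent unit flag.
#' @return numeric vector of orbital amplitudes (Angstrom^-3/2).
#' @export
sto_value <- function(points, center, n = 1, l = 0, m = 0, zeta = 1.3,
                      zeta_unit = c("invA", "invBohr")) {
  zeta_unit <- match.arg(zeta_unit)
  if (zeta_unit == "invBohr") zeta <- zeta / mc_constants$bohr_A
  dx <- points[, 1] - center[1]
  dy <- points[, 2] - center[2]
  dz <- points[, 3] - center[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  sto_radial(r, n, zeta) * sto_angular(l, m, dx, dy, dz, r)
}

# --- grids ----------------------------------------------------------------

#' Rectangular grid covering a molecule
#'
#' @param coords M x 3 atom coordinates (Angstrom), or a `raw_system` /
#'   `electronic_structure` with coordinate metadata.
#' @param spacing grid resolution (Angstrom).
#' @param margin extension beyond the atomic bounding box (Angstrom).
#' @return list with `origin`, `spacing`, `dims` and a `points()` closure
#'   generating the M x 3 coordinates in x-slowest, z-fastest order.
#' @export
make_grid <- function(coords, spacing = 1.5, margin = 3) {
  coords <- grid_coords(coords)
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_def(lo, spacing, dims)
}

grid_coords <- function(x) {
  if (inherits(x, "raw_system")) x <- x$orbital_meta
  if (inherits(x, "electronic_structure")) x <- x$meta
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  stopifnot(is.matrix(x), ncol(x) == 3)
  x
}

grid_def <- function(origin, spacing, dims) {
  origin <- as.numeric(origin); dims <- as.integer(dims)
  g <- list(origin = origin, spacing = spacing, dims = dims)
  g$points <- function() {
    ax <- lapply(1:3, function(k) origin[k] + spacing * (seq_len(dims[k]) - 1))
    # x slowest, z fastest (cube-file ordering)
    as.matrix(expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]]))[, c("x", "y", "z")]
  }
  class(g) <- "mc_grid"
  g
}

#' @export
print.mc_grid <- function(x, ...) {
  cat(sprintf("mc_grid: %d x %d x %d at %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# --- molecular orbitals in space -----------------------------------------

#' Evaluate a molecular orbital on grid points
#'
#' `Psi^k(r) = sum_r W_r^k phi_r(r)` over the Slater basis described by the
#' orbital metadata. Orbital centers farther from a point than `cutoff` are
#' skipped (the Slater tail is below ~1e-6 there).
#'
#' @param coeff LCAO coefficient vector (length = number of basis orbitals).
#' @param meta orbital metadata data.frame with columns `x`, `y`, `z`, `n`,
#'   `l`, `m`, `zeta`.
#' @param points M x 3 coordinate matrix, or an `mc_grid`.
#' @param cutoff evaluation radius per orbital (Angstrom).
#' @param zeta_unit unit of the `zeta` column.
#' @return numeric vector of orbital values at the points.
#' @export
evaluate_mo <- function(coeff, meta, points, cutoff = 7,
                        zeta_unit = c("invA", "invBohr")) {
  zeta_unit <- match.arg(zeta_unit)
  if (inherits(points, "mc_grid")) points <- points$points()
  stopifnot(length(coeff) == nrow(meta))
  M <- nrow(points)
  out <- numeric(M)
  touched <- FALSE
  for (r in seq_len(nrow(meta))) {
    if (coeff[r] == 0) next
    ctr <- c(meta$x[r], meta$y[r], meta$z[r])
    d2 <- (points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2 +
      (points[, 3] - ctr[3])^2
    sel <- d2 <= cutoff^2
    if (!any(sel)) next
    touched <- TRUE
    out[sel] <- out[sel] + coeff[r] *
      sto_value(points[sel, , drop = FALSE], ctr, meta$n[r], meta$l[r],
                meta$m[r], meta$zeta[r], zeta_unit)
  }
  if (!touched) warning("grid does not cover any orbital center within the cutoff")
  out
}

# --- conductivity maps ----------------------------------------------------

#' Volumetric map container
#'
#' @param grid an `mc_grid`.
#' @param values numeric vector in the grid's x-slowest/z-fastest order.
#' @param kind `"Z"` or `"T"`.
#' @return object of class `volumetric_map`.
#' @export
volumetric_map <- function(grid, values, kind = c("Z", "T")) {
  kind <- match.arg(kind)
  stopifnot(length(values) == prod(grid$dims))
  if (any(values < -1e-14)) stop("map values must be nonnegative")
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 dims = grid$dims, values = pmax(values, 0), kind = kind),
            class = "volumetric_map")
}

#' @export
print.volumetric_map <- function(x, ...) {
  cat(sprintf("volumetric_map (%s): %d x %d x %d, max %.4g, %d nonzero voxels\n",
              x$kind, x$dims[1], x$dims[2], x$dims[3], max(x$values),
              sum(x$values > 0)))
  invisible(x)
}

map_window <- function(es, kT, window) {
  if (!is.null(window)) return(window)
  select_window(es, "energy_kT", size = 5, kT = kT)
}

# LCAO coefficients over the real-space atomic orbitals: for a Loewdin
# structure these are S^(-1/2) psi (stored by build_structure); for an
# orthogonal basis they are the eigenvectors themselves
ao_coefficients <- function(es) {
  if (!is.null(es$coeff_ao)) es$coeff_ao else es$psi
}

#' Thermal-accessibility map Z(r)
#'
#' `Z(r) = sum_k |Psi^k(r)|^2 / cosh^2((mu - E_k)/2kT)`, summed over levels
#' within 5 kT of the HOMO and LUMO by default. High values mark regions
#' reachable by thermal excitation.
#'
#' @param es an `electronic_structure` with orbital metadata.
#' @param grid an `mc_grid`.
#' @param kT thermal energy (eV).
#' @param window optional explicit level window (default: 5 kT rule).
#' @param cutoff orbital evaluation radius (Angstrom).
#' @return a `volumetric_map` of kind `"Z"`.
#' @export
z_map <- function(es, grid, kT, window = NULL, cutoff = 7) {
  window <- map_window(es, kT, window)
  pts <- grid$points()
  vals <- numeric(nrow(pts))
  for (k in window) {
    w <- 1 / cosh((es$mu - es$energies[k]) / (2 * kT))^2
    psi_r <- evaluate_mo(ao_coefficients(es)[, k], es$meta, pts, cutoff = cutoff)
    vals <- vals + w * psi_r^2
  }
  volumetric_map(grid, vals, "Z")
}

#' Tunneling-accessibility map T(r)
#'
#' `T(r) = sum_k |Psi^k(r)|^4 / (mu - E_k)^2` over the level window. The sum
#' diverges if a level sits exactly at the chemical potential; this is
#' rejected with an error suggesting a mu shift.
#'
#' @inheritParams z_map
#' @return a `volumetric_map` of kind `"T"`.
#' @export
t_map <- function(es, grid, kT, window = NULL, cutoff = 7) {
  window <- map_window(es, kT, window)
  gap_to_mu <- abs(es$mu - es$energies[window])
  if (any(gap_to_mu < 1e-9)) {
    stop("level(s) ", paste(window[gap_to_mu < 1e-9], collapse = ", "),
         " lie at the chemical potential; shift mu to evaluate T(r)")
  }
  pts <- grid$points()
  vals <- numeric(nrow(pts))
  for (k in window) {
    psi_r <- evaluate_mo(ao_coefficients(es)[, k], es$meta, pts, cutoff = cutoff)
    vals <- vals + psi_r^4 / (es$mu - es$energies[k])^2
  }
  volumetric_map(grid, vals, "T")
}

#' Percentile isovalue over the nonzero voxels
#'
#' Returns the `(1 - top_fraction)` quantile of the strictly positive map
#' values (linear-interpolation quantile, R type 7), i.e. the isovalue that
#' encloses the highest `top_fraction` of the nonzero voxels. Conventional
#' choices: top 5 percent for Z maps, top 20 percent for T maps.
#'
#' @param map a `volumetric_map` (or numeric vector).
#' @param top_fraction fraction of nonzero voxels above the isovalue;
#'   defaults to 0.05 for Z maps and 0.20 for T maps.
#' @return the isovalue.
#' @export
percentile_isovalue <- function(map, top_fraction = NULL) {
  vals <- if (inherits(map, "volumetric_map")) map$values else map
  if (is.null(top_fraction)) {
    top_fraction <- if (inherits(map, "volumetric_map") && map$kind == "T") 0.20 else 0.05
  }
  pos <- vals[vals > 0]
  if (!length(pos)) stop("map has no positive voxels")
  stats::quantile(pos, probs = 1 - top_fraction, type = 7, names = FALSE)
}
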