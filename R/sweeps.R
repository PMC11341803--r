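# Sampling protocols: random orbital-pair conductance distributions,
# distance-binned logarithmic means with a +/- tolerance window, exponential
# decay-constant fits, and temperature scans with mechanism-crossover
# detection.

#' Sample random orbital pairs subject to distance and element filters
#'
#' Uniform sampling without replacement among the eligible orbital pairs.
#' The distance between two orbitals is the Euclidean distance between their
#' host atoms (orbitals are atom-centered). Deterministic under a fixed seed;
#' the caller's RNG state is left untouched.
#'
#' @param es an `electronic_structure` (or `raw_system`) with coordinate
#'   metadata.
#' @param n_pairs number of pairs requested; if fewer pairs are eligible,
#'   all of them are returned with a warning.
#' @param d_range inclusive distance range in Angstrom.
#' @param exclude_H drop orbitals hosted on hydrogen atoms.
#' @param subset optional orbital indices to restrict the sampling to.
#' @param seed RNG seed (required for reproducibility).
#' @return data.frame of class `pair_sample` with columns `a`, `b`,
#'   `distance_A`, plus attributes `seed`.
#' @export
sample_pairs <- function(es, n_pairs, d_range = c(0, Inf), exclude_H = FALSE,
                         subset = NULL, seed) {
  meta <- if (inherits(es, "raw_system")) es$orbital_meta else es$meta
  if (is.null(meta)) stop("orbital metadata with coordinates is required")
  idx <- seq_len(nrow(meta))
  if (!is.null(subset)) idx <- intersect(idx, subset)
  if (exclude_H) idx <- idx[!meta$is_hydrogen[idx]]
  if (length(idx) < 2) stop("fewer than two eligible orbitals")
  cand <- t(utils::combn(idx, 2))
  xyz <- as.matrix(meta[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[cand[, 1], , drop = FALSE] -
                       xyz[cand[, 2], , drop = FALSE])^2))
  keep <- d >= d_range[1] & d <= d_range[2]
  cand <- cand[keep, , drop = FALSE]
  d <- d[keep]
  if (nrow(cand) == 0) stop("no eligible pairs in the distance range")
  if (nrow(cand) < n_pairs) {
    warning("only ", nrow(cand), " eligible pairs (requested ", n_pairs,
            "); returning all")
    sel <- seq_len(nrow(cand))
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    sel <- sample.int(nrow(cand), n_pairs, replace = FALSE)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
  }
  out <- data.frame(a = cand[sel, 1], b = cand[sel, 2], distance_A = d[sel])
  attr(out, "seed") <- seed
  class(out) <- c("pair_sample", class(out))
  out
}

#' Distance profile of logarithmic conductance
#'
#' Bin centers are the observed distances rounded to the 0.1 Angstrom grid;
#' each bin collects all samples within `tolerance` of its center and reports
#' the mean log10 of the strictly positive conductance values per mechanism.
#' Nonpositive values are dropped and counted.
#'
#' @param samples data.frame with a `distance_A` column and conductance
#'   columns (`G_nS`, `G_LB_nS`, `G_T_nS`, `G_M_nS` as produced by
#'   [pairwise_G()]).
#' @param tolerance half-width of the distance window (Angstrom).
#' @return data.frame with one row per nonempty bin: `d`, `n`, `n_dropped`,
#'   and `mean_log10_<term>` columns.
#' @export
distance_profile <- function(samples, tolerance = 0.1) {
  gcols <- intersect(c("G_nS", "G_LB_nS", "G_T_nS", "G_M_nS"),
                     names(samples))
  if (!length(gcols)) stop("no conductance columns found")
  centers <- sort(unique(round(samples$distance_A, 1)))
  rows <- lapply(centers, function(cc) {
    sel <- abs(samples$distance_A - cc) <= tolerance + 1e-12
    if (!any(sel)) return(NULL)
    sub <- samples[sel, , drop = FALSE]
    means <- vapply(gcols, function(col) {
      v <- sub[[col]]
      v <- v[v > 0]
      if (!length(v)) NA_real_ else mean(log10(v))
    }, numeric(1))
    dropped <- vapply(gcols, function(col) sum(sub[[col]] <= 0), numeric(1))
    out <- data.frame(d = cc, n = nrow(sub), n_dropped = max(dropped))
    for (col in gcols) out[[paste0("mean_log10_", col)]] <- means[[col]]
    out
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Fit the exponential distance-decay constant beta
#'
#' Ordinary least squares of `ln G_LB` against distance on a distance
#' profile: `G_LB ~ exp(-beta d)`. Reports the decay constant, its standard
#' error, the intercept and R^2.
#'
#' @param profile output of [distance_profile()]; the column given by `term`
#'   holds mean log10 conductances.
#' @param term profile column to fit (default the coherent-tunneling term).
#' @return list with `beta` (1/Angstrom), `se`, `intercept`, `r_squared`,
#'   `n_bins`.
#' @export
fit_beta <- function(profile, term = "mean_log10_G_LB_nS") {
  ok <- is.finite(profile[[term]])
  if (sum(ok) < 3) stop("need at least 3 bins with finite values to fit beta")
  d <- profile$d[ok]
  lnG <- profile[[term]][ok] * log(10)
  fit <- stats::lm(lnG ~ d)
  sm <- summary(fit)
  list(beta = -unname(stats::coef(fit)["d"]),
       se = unname(sm$coefficients["d", "Std. Error"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       n_bins = sum(ok))
}

#' Temperature scan of the mechanism-resolved conductance
#'
#' Recomputes the three-mechanism conductance for a fixed set of orbital
#' pairs over a temperature grid and reports the mean log10 conductance per
#' mechanism at each temperature, plus the crossover temperature where the
#' mean thermal and mixed terms exchange dominance (linear interpolation
#' between grid points; NA if no crossing).
#'
#' @param es an `electronic_structure`.
#' @param pairs data.frame with columns `a`, `b` (e.g. from
#'   [sample_pairs()]).
#' @param T_grid temperatures in Kelvin.
#' @param Gamma_L,Gamma_R escape strengths (eV).
#' @param window level indices.
#' @return list with `table` (T, mean_log10 per term) and `T_crossover`.
#' @export
temperature_scan <- function(es, pairs, T_grid, Gamma_L = 0.1, Gamma_R = 0.1,
                             window = select_window(es, "levels_k", 20)) {
  rows <- lapply(T_grid, function(Tk) {
    g <- pairwise_G(es, pairs[, c("a", "b")], Gamma_L, Gamma_R,
                    kT = kT_eV(Tk), window = window)
    mlog <- function(v) { v <- v[v > 0]; if (!length(v)) NA_real_ else mean(log10(v)) }
    data.frame(T = Tk,
               mean_log10_G_nS = mlog(g$G_nS),
               mean_log10_G_LB_nS = mlog(g$G_LB_nS),
               mean_log10_G_T_nS = mlog(g$G_T_nS),
               mean_log10_G_M_nS = mlog(g$G_M_nS))
  })
  tab <- do.call(rbind, rows)
  T_cross <- crossover_temperature(tab$T, tab$mean_log10_G_M_nS,
                                   tab$mean_log10_G_T_nS)
  list(table = tab, T_crossover = T_cross)
}

# first temperature where curve1 - curve2 changes sign, by linear interpolation
crossover_temperature <- function(T, curve1, curve2) {
  diffc <- curve1 - curve2
  ok <- is.finite(diffc)
  T <- T[ok]; diffc <- diffc[ok]
  if (length(T) < 2) return(NA_real_)
  s <- sign(diffc)
  flip <- which(s[-1] * s[-length(s)] < 0)
  if (!length(flip)) {
    z <- which(diffc == 0)
    return(if (length(z)) T[z[1]] else NA_real_)
  }
  i <- flip[1]
  T[i] + (T[i + 1] - T[i]) * (0 - diffc[i]) / (diffc[i + 1] - diffc[i])
}
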