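# Numeric helpers shared across modules.

#' Fermi-Dirac distribution F(E, mu)
#'
#' @param E energy (eV), vectorized.
#' @param mu chemical potential (eV).
#' @param kT thermal energy (eV). `kT = 0` gives the step function with
#'   F = 1/2 at `E == mu`.
#' @return occupation in `[0, 1]`.
#' @export
fermi <- function(E, mu, kT) {
  if (kT == 0) {
    return(ifelse(E < mu, 1, ifelse(E > mu, 0, 0.5)))
  }
  x <- (E - mu) / kT
  # stable for large |x|
  ifelse(x > 0, exp(-x) / (1 + exp(-x)), 1 / (1 + exp(x)))
}

#' Derivative of the Fermi function with respect to mu
#'
#' f(E, mu) = dF/dmu = 1 / (4 kT cosh^2((E - mu)/2kT)). Integrates to 1 over E.
#'
#' @inheritParams fermi
#' @return density in 1/eV.
#' @export
fermi_deriv <- function(E, mu, kT) {
  if (kT == 0) stop("fermi_deriv is a delta function at kT = 0; use a positive kT")
  x <- (E - mu) / (2 * kT)
  # sech^2 via exp to avoid cosh overflow
  s <- 2 * exp(-abs(x)) / (1 + exp(-2 * abs(x)))
  s^2 / (4 * kT)
}

# log(cosh(x)) without overflow
logcosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}

# log(sum(exp(x))) without overflow; -Inf entries allowed
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-major flattening of an Nw x Nw level-pair matrix: the vector index of
# element (i, j) is k = (i-1)*Nw + j. This convention is fixed package-wide
# and matches kronecker(A, B)[(i,j),(p,q)] = A[i,p] * B[j,q].
flatten_pairs <- function(M) as.vector(t(M))

unflatten_pairs <- function(v, Nw = as.integer(sqrt(length(v)))) {
  t(matrix(v, nrow = Nw, ncol = Nw))
}

#' Read a dense square matrix from the plain-text exchange format
#'
#' Format: one header line with the dimension N, then N lines of N
#' whitespace-separated numbers. This is the interchange format for
#' Hamiltonian and overlap matrices exported from extended-Hueckel codes.
#'
#' @param path file path.
#' @return an N x N numeric matrix.
#' @export
read_matrix_txt <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  n <- as.integer(scan(con, what = integer(), n = 1, quiet = TRUE))
  vals <- scan(con, what = double(), n = n * n, quiet = TRUE)
  if (length(vals) != n * n) {
    stop("expected ", n * n, " values in ", path, ", got ", length(vals))
  }
  matrix(vals, nrow = n, ncol = n, byrow = TRUE)
}

#' Write a dense square matrix in the plain-text exchange format
#'
#' @param M square numeric matrix.
#' @param path file path.
#' @param digits significant digits to keep.
#' @export
write_matrix_txt <- function(M, path, digits = 17) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  lines <- c(
    as.character(nrow(M)),
    apply(M, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                  collapse = " "))
  )
  writeLines(lines, path)
}
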