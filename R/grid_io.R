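# Volumetric file formats: Gaussian cube (default, widest tool support) and
# OpenDX general arrays (the gridData/VMD route). Both are plain text and
# round-trip map values beyond float32 precision.

#' Write a volumetric map as a Gaussian cube file
#'
#' Coordinates are converted from Angstrom to Bohr as the cube convention
#' requires (positive voxel counts signal Bohr units). Values are written in
#' the native cube ordering (x slowest, z fastest), which is the internal
#' ordering of [volumetric_map()].
#'
#' @param map a `volumetric_map`.
#' @param path output file.
#' @param atoms optional data.frame with columns `Z` (atomic number), `x`,
#'   `y`, `z` (Angstrom) written into the atom block; a single dummy atom is
#'   written when omitted (the format requires at least one).
#' @export
write_cube <- function(map, path, atoms = NULL) {
  b <- mc_constants$bohr_A
  if (is.null(atoms)) atoms <- data.frame(Z = 1, x = 0, y = 0, z = 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("molcond %s map", map$kind),
               "isotropic rectangular grid"), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", nrow(atoms),
                     map$origin[1] / b, map$origin[2] / b, map$origin[3] / b), con)
  step <- map$spacing / b
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", map$dims[1], step, 0, 0), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", map$dims[2], 0, step, 0), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", map$dims[3], 0, 0, step), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f %12.6f", atoms$Z, atoms$Z,
                     atoms$x / b, atoms$y / b, atoms$z / b), con)
  v <- map$values
  pad <- (-length(v)) %% 6
  vv <- c(v, rep(NA_real_, pad))
  m <- matrix(vv, ncol = 6, byrow = TRUE)
  lines <- apply(m, 1, function(r) {
    paste(sprintf("%16.8E", r[!is.na(r)]), collapse = " ")
  })
  writeLines(lines, con)
  invisible(path)
}

#' Read a Gaussian cube file back into a volumetric map
#'
#' @param path cube file path.
#' @param kind map kind tag to attach.
#' @return a `volumetric_map`.
#' @export
read_cube <- function(path, kind = c("Z", "T")) {
  kind <- match.arg(kind)
  b <- mc_constants$bohr_A
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[3:6]), "\\s+")
  natoms <- as.integer(hdr[[1]][1])
  origin <- as.numeric(hdr[[1]][2:4]) * b
  dims <- vapply(2:4, function(i) as.integer(hdr[[i]][1]), integer(1))
  spacing <- as.numeric(hdr[[2]][2]) * b
  vals <- scan(text = lines[-(1:(6 + natoms))], what = double(), quiet = TRUE)
  volumetric_map(grid_def(origin, spacing, dims), vals, kind)
}

#' Write a volumetric map in OpenDX format
#'
#' Regular-grid OpenDX general array, loadable by VMD. Coordinates stay in
#' Angstrom (the convention of structure-aligned DX maps).
#'
#' @param map a `volumetric_map`.
#' @param path output file.
#' @export
write_dx <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- map$dims
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("origin %.8g %.8g %.8g",
                     map$origin[1], map$origin[2], map$origin[3]), con)
  writeLines(sprintf("delta %.8g 0 0", map$spacing), con)
  writeLines(sprintf("delta 0 %.8g 0", map$spacing), con)
  writeLines(sprintf("delta 0 0 %.8g", map$spacing), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows",
    prod(d)), con)
  v <- map$values
  pad <- (-length(v)) %% 3
  vv <- c(v, rep(NA_real_, pad))
  m <- matrix(vv, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) {
    paste(sprintf("%.9e", r[!is.na(r)]), collapse = " ")
  })
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX regular-grid map
#'
#' @param path DX file path.
#' @param kind map kind tag to attach.
#' @return a `volumetric_map`.
#' @export
read_dx <- function(path, kind = c("Z", "T")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  gp <- grep("class gridpositions", lines, value = TRUE)[1]
  dims <- as.integer(utils::tail(strsplit(trimws(gp), "\\s+")[[1]], 3))
  og <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(og), "\\s+")[[1]][2:4])
  dl <- grep("^delta", lines, value = TRUE)
  spacing <- as.numeric(strsplit(trimws(dl[1]), "\\s+")[[1]][2])
  start <- grep("data follows", lines)[1]
  stop_at <- grep("^attribute", lines)
  stop_at <- if (length(stop_at)) min(stop_at[stop_at > start]) else length(lines) + 1
  vals <- scan(text = lines[(start + 1):(stop_at - 1)], what = double(),
               quiet = TRUE)
  volumetric_map(grid_def(origin, spacing, dims), vals, kind)
}
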