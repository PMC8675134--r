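#' Read a Gaussian cube file
#'
#' Standard cube layout: two comment lines; a line with the number of atoms
#' and the grid origin; three axis lines (voxel count then step vector, bohr);
#' one line per atom; then the scalar field in x-outer / z-inner order. Cube
#' values are trusted as electron densities (e/bohr^3); tiny negative values
#' from file round-off are clamped to zero with a warning. A negative atom
#' count (the molecular-orbital cube convention) is rejected, as are negative
#' voxel counts (the Angstrom-axes convention): only bohr-axis density cubes
#' are accepted.
#'
#' @param file path to a cube file, or a character vector of its lines.
#' @return An object of class `density_grid` with fields `origin`, `axes`
#'   (3 x 3, rows are step vectors), `counts`, `values` (array
#'   `counts[1] x counts[2] x counts[3]`) and `atoms`.
#' @export
read_cube <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE)
           else as.character(file)
  if (length(lines) < 7L) stop("cube format error: truncated header")
  num <- function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  hdr <- num(lines[3])
  natoms <- hdr[1]
  if (natoms < 0) {
    stop("cube format error: negative atom count (MO cube convention) ",
         "is not supported; supply a density cube")
  }
  natoms <- as.integer(natoms)
  origin <- hdr[2:4]
  counts <- integer(3); axes <- matrix(0, 3, 3)
  for (k in 1:3) {
    a <- num(lines[3 + k])
    if (a[1] < 0) {
      stop("cube format error: negative voxel count (Angstrom axes) ",
           "is not supported; write the cube in bohr")
    }
    counts[k] <- as.integer(a[1])
    axes[k, ] <- a[2:4]
  }
  if (any(counts < 2L)) stop("cube format error: counts must be >= 2 per axis")
  atoms <- NULL
  if (natoms > 0L) {
    atoms <- do.call(rbind, lapply(lines[6 + seq_len(natoms)], function(l) {
      f <- num(l)
      data.frame(element = as.character(as.integer(f[1])),
                 nuclear_charge = as.integer(f[1]),
                 x = f[3], y = f[4], z = f[5])
    }))
  }
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[(7L + natoms):length(lines)]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  nexp <- prod(counts)
  if (length(vals) < nexp) {
    stop("cube format error: value block truncated (", length(vals),
         " of ", nexp, " values)")
  }
  vals <- vals[seq_len(nexp)]
  if (any(vals < 0)) {
    if (min(vals) < -1e-6) {
      warning("cube contains substantially negative values; clamping to 0")
    } else {
      warning("clamping small negative cube values to 0")
    }
    vals[vals < 0] <- 0
  }
  # file order is x-outer/z-inner; store as values[ix, iy, iz]
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  structure(list(origin = origin, axes = axes, counts = counts,
                 values = arr, atoms = atoms),
            class = "density_grid")
}

#' Write a Gaussian cube file
#'
#' Inverse of [read_cube()]: fixed-width scientific formatting, six values per
#' line, x-outer / z-inner order, so that write/read round-trips are lossless
#' at the printed precision.
#'
#' @param grid a `density_grid`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_cube <- function(grid, file) {
  stopifnot(inherits(grid, "density_grid"))
  if (any(grid$counts < 2L)) stop("refusing to write a grid with a single-voxel axis")
  con <- file(file, "w")
  on.exit(close(con))
  atoms <- grid$atoms
  nat <- if (is.null(atoms)) 0L else nrow(atoms)
  fmt3 <- function(v) paste(sprintf("%12.6f", v), collapse = "")
  writeLines(c("cube file written by mosscalib",
               "electron density (e/bohr^3)"), con)
  writeLines(sprintf("%5d%s", nat, fmt3(grid$origin)), con)
  for (k in 1:3) {
    writeLines(sprintf("%5d%s", grid$counts[k], fmt3(grid$axes[k, ])), con)
  }
  if (nat > 0L) {
    for (i in seq_len(nat)) {
      writeLines(sprintf("%5d%12.6f%s", atoms$nuclear_charge[i],
                         as.numeric(atoms$nuclear_charge[i]),
                         fmt3(as.numeric(atoms[i, c("x", "y", "z")]))), con)
    }
  }
  v <- as.vector(aperm(grid$values, c(3, 2, 1)))  # back to x-outer/z-inner
  full <- length(v) %/% 6L
  if (full > 0L) {
    mat <- matrix(v[seq_len(full * 6L)], ncol = 6L, byrow = TRUE)
    writeLines(apply(mat, 1, function(r) paste(sprintf("%13.5E", r), collapse = "")), con)
  }
  rest <- v[-seq_len(full * 6L)]
  if (length(rest)) writeLines(paste(sprintf("%13.5E", rest), collapse = ""), con)
  invisible(file)
}

#' @export
print.density_grid <- function(x, ...) {
  cat("density_grid:", paste(x$counts, collapse = " x "), "voxels, origin (",
      paste(sprintf("%.4f", x$origin), collapse = ", "), ") bohr\n")
  cat("  value range:", format(range(x$values)), "\n")
  invisible(x)
}

# node coordinates of a grid (used by the interpolators)
grid_node_coords <- function(grid, k) {
  # returns coordinates along logical axis k assuming orthogonal axes
  grid$origin[k] + (seq_len(grid$counts[k]) - 1L) * grid$axes[k, k]
}
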