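# Density, gradient and Laplacian evaluation.

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = FALSE)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix (bohr)")
  if (!all(is.finite(points))) stop("points must be finite")
  points
}

# basis-value matrices at points; which = subset of c("value","grad","lap")
basis_matrices <- function(wf, points, which = "value") {
  n <- nrow(points); nb <- length(wf$basis)
  out <- list()
  if ("value" %in% which) out$value <- matrix(0, n, nb)
  if ("grad" %in% which) out$gx <- out$gy <- out$gz <- matrix(0, n, nb)
  if ("lap" %in% which) out$lap <- matrix(0, n, nb)
  for (k in seq_len(nb)) {
    bf <- wf$basis[[k]]
    rel <- sweep(points, 2, bf$center)
    if ("value" %in% which) out$value[, k] <- pg_eval(bf$terms, rel)
    if ("grad" %in% which || "lap" %in% which) {
      dts <- lapply(1:3, function(d) pg_deriv(bf$terms, d))
      if ("grad" %in% which) {
        out$gx[, k] <- pg_eval(dts[[1]], rel)
        out$gy[, k] <- pg_eval(dts[[2]], rel)
        out$gz[, k] <- pg_eval(dts[[3]], rel)
      }
      if ("lap" %in% which) {
        out$lap[, k] <- pg_eval(pg_deriv(dts[[1]], 1), rel) +
          pg_eval(pg_deriv(dts[[2]], 2), rel) +
          pg_eval(pg_deriv(dts[[3]], 3), rel)
      }
    }
  }
  out
}

#' Evaluate the electron density of a wavefunction
#'
#' Computes \eqn{\rho(p) = \sum_k n_k |\phi_k(p)|^2} analytically from the
#' contracted Gaussian basis, summing over spin channels. This is the quantity
#' whose value at the nuclear coordinate is the classic contact-density
#' descriptor for isomer-shift calibration.
#'
#' @param wf a [wavefunction()].
#' @param points n x 3 matrix of Cartesian points (bohr), or a length-3 vector.
#' @return data.frame with columns `x`, `y`, `z`, `rho` (e/bohr^3).
#' @export
eval_density <- function(wf, points) {
  stopifnot(inherits(wf, "wavefunction"))
  points <- as_points(points)
  B <- basis_matrices(wf, points, "value")$value
  M <- B %*% wf$mo_coefficients
  rho <- as.vector(M^2 %*% wf$occupations)
  data.frame(x = points[, 1], y = points[, 2], z = points[, 3], rho = rho)
}

#' Evaluate density, gradient and Laplacian
#'
#' Analytic first and second derivatives of the Gaussian basis give
#' \eqn{\nabla\rho = 2\sum_k n_k \phi_k\nabla\phi_k} and
#' \eqn{\nabla^2\rho = 2\sum_k n_k(\phi_k\nabla^2\phi_k + |\nabla\phi_k|^2)}.
#' The Laplacian is the standard indicator of atomic shell structure: its
#' positive maximum just outside the K shell motivates the ~0.06 bohr
#' descriptor sphere.
#'
#' @inheritParams eval_density
#' @return data.frame with columns `x`, `y`, `z`, `rho`, `grad_x`, `grad_y`,
#'   `grad_z`, `laplacian`.
#' @export
eval_laplacian <- function(wf, points) {
  stopifnot(inherits(wf, "wavefunction"))
  points <- as_points(points)
  Bm <- basis_matrices(wf, points, c("value", "grad", "lap"))
  C <- wf$mo_coefficients; occ <- wf$occupations
  M <- Bm$value %*% C
  Mx <- Bm$gx %*% C; My <- Bm$gy %*% C; Mz <- Bm$gz %*% C
  Ml <- Bm$lap %*% C
  rho <- as.vector(M^2 %*% occ)
  gx <- as.vector(2 * (M * Mx) %*% occ)
  gy <- as.vector(2 * (M * My) %*% occ)
  gz <- as.vector(2 * (M * Mz) %*% occ)
  lap <- as.vector(2 * (M * Ml + Mx^2 + My^2 + Mz^2) %*% occ)
  data.frame(x = points[, 1], y = points[, 2], z = points[, 3], rho = rho,
             grad_x = gx, grad_y = gy, grad_z = gz, laplacian = lap)
}

#' Interpolate the density from a volumetric grid
#'
#' Grid-based evaluation is approximate: a cube grid cannot resolve the
#' K-shell density peak, so near-nucleus descriptors should come from the
#' analytic path. Results therefore carry an `approximate` attribute.
#'
#' @param grid a `density_grid` from [read_cube()] (orthogonal axes assumed).
#' @param points n x 3 matrix (bohr); all points must lie inside the grid hull.
#' @param method `"trilinear"` (exact at nodes) or `"tricubic"` (Catmull-Rom
#'   cubic convolution per axis).
#' @return data.frame with columns `x`, `y`, `z`, `rho`, attribute
#'   `approximate = TRUE`.
#' @export
eval_density_from_grid <- function(grid, points,
                                   method = c("trilinear", "tricubic")) {
  stopifnot(inherits(grid, "density_grid"))
  method <- match.arg(method)
  points <- as_points(points)
  if (max(abs(grid$axes[upper.tri(grid$axes) | lower.tri(grid$axes)])) > 1e-12) {
    stop("only orthogonal-axis grids are supported for interpolation")
  }
  crd <- lapply(1:3, function(k) grid_node_coords(grid, k))
  # fractional index per axis
  fi <- sapply(1:3, function(k) {
    (points[, k] - grid$origin[k]) / grid$axes[k, k] + 1
  })
  fi <- matrix(fi, ncol = 3)
  eps <- 1e-9
  for (k in 1:3) {
    if (any(fi[, k] < 1 - eps | fi[, k] > grid$counts[k] + eps)) {
      stop("point outside the grid hull on axis ", k)
    }
    fi[, k] <- pmin(pmax(fi[, k], 1), grid$counts[k])
  }
  rho <- if (method == "trilinear") trilinear(grid$values, fi)
         else tricubic(grid$values, fi)
  out <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3], rho = rho)
  attr(out, "approximate") <- TRUE
  out
}

trilinear <- function(v, fi) {
  d <- dim(v)
  i0 <- pmin(pmax(floor(fi), 1), matrix(rep(d, each = nrow(fi)), ncol = 3) - 1)
  t <- fi - i0
  out <- numeric(nrow(fi))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[, 1] else 1 - t[, 1]) *
         (if (dy) t[, 2] else 1 - t[, 2]) *
         (if (dz) t[, 3] else 1 - t[, 3])
    out <- out + w * v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out
}

catmull_rom_w <- function(t) {
  # weights for nodes at offsets -1, 0, 1, 2
  cbind(((-t + 2 * t^2 - t^3) / 2),
        (1 - 2.5 * t^2 + 1.5 * t^3),
        ((t + 4 * t^2 - 3 * t^3) / 2),
        ((-t^2 + t^3) / 2))
}

tricubic <- function(v, fi) {
  d <- dim(v)
  i0 <- pmin(pmax(floor(fi), 1), matrix(rep(d, each = nrow(fi)), ncol = 3) - 1)
  t <- fi - i0
  wx <- catmull_rom_w(t[, 1]); wy <- catmull_rom_w(t[, 2]); wz <- catmull_rom_w(t[, 3])
  clampi <- function(i, k) pmin(pmax(i, 1), d[k])
  out <- numeric(nrow(fi))
  for (dx in -1:2) for (dy in -1:2) for (dz in -1:2) {
    w <- wx[, dx + 2] * wy[, dy + 2] * wz[, dz + 2]
    out <- out + w * v[cbind(clampi(i0[, 1] + dx, 1),
                             clampi(i0[, 2] + dy, 2),
                             clampi(i0[, 3] + dz, 3))]
  }
  out
}
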