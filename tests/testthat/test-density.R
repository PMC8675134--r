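test_that("analytic density matches closed forms for synthetic Gaussians", {
  comp <- cbind(exponent = c(2.0, 40.0), weight = c(1.2, 0.8))
  ctr <- c(0.3, -0.1, 0.5)
  wf <- synthetic_wavefunction(comp, center = ctr)
  got <- eval_density(wf, ctr)$rho
  expect_equal(got, sum(comp[, 2] * (comp[, 1] / pi)^1.5), tolerance = 1e-12)

  # decay far from all atoms
  expect_lt(eval_density(wf, ctr + c(50, 0, 0))$rho, 1e-12)

  # nonnegative everywhere sampled
  set.seed(5)
  pts <- matrix(rnorm(300, sd = 2), ncol = 3)
  expect_true(all(eval_density(wf, pts)$rho >= 0))
})

test_that("contracted 1s density at the nucleus matches a direct evaluation", {
  # STO-3G-like contraction for a 2-electron 1s orbital
  exps <- c(3.42525091, 0.62391373, 0.16885540)
  coefs <- c(0.15432897, 0.53532814, 0.44463454)
  atoms <- data.frame(element = "He", nuclear_charge = 2, x = 0, y = 0, z = 0)
  sh <- list(list(atom_index = 1L, angular_momentum = "s",
                  primitive_exponents = exps,
                  contraction_coefficients = coefs, pure_spherical = TRUE))
  wf <- wavefunction(atoms, sh, matrix(1), 2)

  # independent arithmetic: normalized primitives, contracted renormalization
  prim_n <- (2 * exps / pi)^0.75
  raw <- coefs * prim_n
  overlap <- 0
  for (i in 1:3) for (j in 1:3) {
    overlap <- overlap + raw[i] * raw[j] * (pi / (exps[i] + exps[j]))^1.5
  }
  phi0 <- sum(raw) / sqrt(overlap)
  expect_equal(eval_density(wf, c(0, 0, 0))$rho, 2 * phi0^2, tolerance = 1e-12)
})

test_that("Laplacian closed form and finite differences agree", {
  a <- 2.0
  wf <- synthetic_wavefunction(cbind(a, 1.0))
  l0 <- eval_laplacian(wf, c(0, 0, 0))
  expect_equal(l0$laplacian, -6 * a * l0$rho, tolerance = 1e-10)

  # central finite differences at generic points, mixed shells
  wfm <- read_molden(molden_text(shells = c("s", "p", "d"),
                                 pure_flags = "[5D]", nmo = 4))
  h <- 1e-4
  for (p in list(c(0.2, 0.1, -0.3), c(0.8, -0.5, 0.4))) {
    lap <- eval_laplacian(wfm, p)$laplacian
    fd <- 0
    for (k in 1:3) {
      e <- numeric(3); e[k] <- h
      fd <- fd + (eval_density(wfm, p + e)$rho - 2 * eval_density(wfm, p)$rho +
                    eval_density(wfm, p - e)$rho) / h^2
    }
    expect_equal(lap, fd, tolerance = 1e-5)
  }
})

test_that("two-scale shell density has a Laplacian zero between its scales", {
  comp <- cbind(exponent = c(500, 5), weight = c(2, 2))
  wf <- synthetic_wavefunction(comp)
  # closed form: lap of sum_i w_i (a_i/pi)^1.5 e^{-a_i r^2} at radius r
  lap_cf <- function(r) {
    sum(comp[, 2] * (comp[, 1] / pi)^1.5 * exp(-comp[, 1] * r^2) *
          (4 * comp[, 1]^2 * r^2 - 6 * comp[, 1]))
  }
  root <- uniroot(Vectorize(lap_cf), c(0.01, 0.08), tol = 1e-12)$root
  got <- eval_laplacian(wf, cbind(c(root, root + 0.01), 0, 0))$laplacian
  expect_lt(abs(got[1]), abs(got[2]))
  # zero of the closed form is a zero of the engine too (scale ~1e7 nearby)
  expect_lt(abs(eval_laplacian(wf, c(root, 0, 0))$laplacian), 1e-5)
})

test_that("density and Laplacian are invariant under joint rotation", {
  set.seed(9)
  atoms <- data.frame(element = c("Fe", "O"), nuclear_charge = c(26, 8),
                      x = c(0, 1.7), y = c(0, 0.3), z = c(0, -0.4))
  sh <- list(
    list(atom_index = 1L, angular_momentum = "s",
         primitive_exponents = c(5, 1), contraction_coefficients = c(0.7, 0.5),
         pure_spherical = TRUE),
    list(atom_index = 2L, angular_momentum = "s",
         primitive_exponents = 2, contraction_coefficients = 1,
         pure_spherical = TRUE))
  C <- matrix(rnorm(4), 2, 2)
  wf <- wavefunction(atoms, sh, C, c(2, 1.5))
  R <- random_rotation()
  atoms_r <- atoms
  atoms_r[, c("x", "y", "z")] <- t(R %*% t(as.matrix(atoms[, c("x", "y", "z")])))
  wf_r <- wavefunction(atoms_r, sh, C, c(2, 1.5))
  pts <- matrix(rnorm(60), ncol = 3)
  pts_r <- t(R %*% t(pts))
  expect_equal(eval_density(wf_r, pts_r)$rho, eval_density(wf, pts)$rho,
               tolerance = 1e-10)
  expect_equal(eval_laplacian(wf_r, pts_r)$laplacian,
               eval_laplacian(wf, pts)$laplacian, tolerance = 1e-10)
})

test_that("divergence theorem: Laplacian integrates to zero over a large ball", {
  wf <- synthetic_wavefunction(cbind(exponent = c(4, 0.5), weight = c(1, 1)))
  g <- sphere_grid(c(0, 0, 0), 8, n_radial = 150, n_angular = 26)
  lap_field <- function(p) eval_laplacian(wf, p)$laplacian
  total <- sum(g$weights * lap_field(g$nodes))
  expect_equal(total, 0, tolerance = 1e-6)
})

test_that("grid interpolation reproduces node values and analytic densities", {
  g <- constant_grid(value = 3.5)
  pts <- matrix(c(0, 0, 0, 0.2, -0.1, 0.3), ncol = 3, byrow = TRUE)
  expect_equal(eval_density_from_grid(g, pts, "trilinear")$rho, c(3.5, 3.5))
  expect_true(isTRUE(attr(eval_density_from_grid(g, pts), "approximate")))

  # node identity for trilinear on a random grid
  set.seed(21)
  g$values[] <- abs(rnorm(prod(g$counts)))
  node <- g$origin + c(1, 2, 0) * 0.5
  expect_equal(eval_density_from_grid(g, node, "trilinear")$rho,
               g$values[2, 3, 1])

  # tricubic against the analytic density of a smooth synthetic wavefunction
  wf <- synthetic_wavefunction(cbind(30, 2.0))
  step <- 0.02
  axis <- seq(-0.2, 0.2, by = step)
  vals <- array(0, dim = rep(length(axis), 3))
  mesh <- as.matrix(expand.grid(x = axis, y = axis, z = axis))
  vals[] <- eval_density(wf, mesh)$rho
  gg <- structure(list(origin = rep(-0.2, 3), axes = diag(3) * step,
                       counts = rep(length(axis), 3L), values = vals,
                       atoms = NULL),
                  class = "density_grid")
  probe <- matrix(c(0.013, -0.007, 0.004, 0.031, 0.02, -0.015),
                  ncol = 3, byrow = TRUE)
  got <- eval_density_from_grid(gg, probe, "tricubic")$rho
  want <- eval_density(wf, probe)$rho
  expect_equal(got, want, tolerance = 0.01)

  # out-of-hull points raise a domain error
  expect_error(eval_density_from_grid(gg, c(5, 0, 0)), "outside")
})
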