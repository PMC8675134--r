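test_that("sphere grid weights sum to the ball volume", {
  for (R in c(0.06, 1, 3)) {
    g <- sphere_grid(c(0, 0, 0), R)
    expect_equal(sum(g$weights), 4 * pi * R^3 / 3, tolerance = 1e-12)
    expect_true(all(g$weights > 0))
  }
  # unit field integrates to the volume exactly
  g1 <- sphere_grid(c(1, 2, 3), 1, n_radial = 5, n_angular = 14)
  expect_equal(integrate_sphere(function(p) rep(1, nrow(p)), g1)$value,
               4 * pi / 3, tolerance = 1e-13)
})

test_that("unsupported Lebedev sizes fail with the valid list", {
  expect_error(sphere_grid(c(0, 0, 0), 1, n_angular = 111), "valid sizes")
  expect_error(lebedev_rule(200), "6, 14, 26, 38, 50, 110")
  expect_error(sphere_grid(c(0, 0, 0), 0), "radius")
})

test_that("polynomials integrate to closed form up to the rule order", {
  g <- sphere_grid(c(0, 0, 0), 1)  # 30 x 110, order 17 angular
  quad_poly <- function(i, j, k) {
    integrate_sphere(function(p) {
      p[, 1]^(2 * i) * p[, 2]^(2 * j) * p[, 3]^(2 * k)
    }, g)$value
  }
  ball_moment <- function(i, j, k) {
    # radial: r^{2s+2} on [0,1] -> 1/(2s+3); angular via sphere moments
    s <- i + j + k
    mom <- prod(sapply(c(i, j, k), function(m) {
      if (m == 0) 1 else prod(seq(2 * m - 1, 1, by = -2))
    })) / prod(seq(2 * s + 1, 1, by = -2))
    4 * pi * mom / (2 * s + 3)
  }
  # r^2 over the unit ball: 4 pi / 5
  expect_equal(quad_poly(1, 0, 0) + quad_poly(0, 1, 0) + quad_poly(0, 0, 1),
               4 * pi / 5, tolerance = 1e-12)
  for (m in list(c(0, 0, 0), c(2, 1, 0), c(3, 2, 2), c(4, 3, 1), c(8, 0, 0))) {
    if (2 * sum(m) > 17) next
    expect_equal(quad_poly(m[1], m[2], m[3]), ball_moment(m[1], m[2], m[3]),
                 tolerance = 1e-11)
  }
})

test_that("descriptor integration matches the erf closed form at 30 x 110", {
  wf <- synthetic_wavefunction(cbind(100, 2.0))
  g <- sphere_grid(c(0, 0, 0), 0.06)
  got <- integrate_sphere(wf, g)
  expect_s3_class(got, "sphere_descriptor")
  expect_equal(got$value, sphere_electron_count(cbind(100, 2.0), 0.06),
               tolerance = 1e-8)
  expect_identical(got$source, "analytic")

  # completeness and zero field
  wf2 <- synthetic_wavefunction(cbind(1, 2.0))
  gl <- sphere_grid(c(0, 0, 0), 8, n_radial = 80, n_angular = 14)
  expect_equal(integrate_sphere(wf2, gl)$value, 2.0, tolerance = 1e-7)
  expect_identical(integrate_sphere(function(p) numeric(nrow(p)), g)$value, 0)

  # volume-average variant sits behind an explicit flag
  avg <- integrate_sphere(wf, g, average = TRUE)
  expect_equal(avg$value, got$value / (4 * pi * 0.06^3 / 3), tolerance = 1e-12)
})

test_that("off-center spheres integrate what the erf form says they hold", {
  ctr <- c(0.5, -1.2, 0.8)
  comp <- cbind(exponent = c(300, 20), weight = c(1.4, 0.6))
  wf <- synthetic_wavefunction(comp, center = ctr)
  g <- sphere_grid(ctr, 0.06)
  expect_equal(integrate_sphere(wf, g)$value,
               sphere_electron_count(comp, 0.06), tolerance = 1e-8)
})

test_that("non-finite field values are reported with the node", {
  g <- sphere_grid(c(0, 0, 0), 1, n_radial = 3, n_angular = 6)
  bad <- function(p) { v <- rep(1, nrow(p)); v[4] <- NaN; v }
  expect_error(integrate_sphere(bad, g), "non-finite field value at")
})

test_that("electron count profile is monotone and matches the closed form", {
  set.seed(13)
  comp <- rbind(c(800, 1.1), c(60, 0.9))
  wf <- synthetic_wavefunction(comp)
  radii <- seq(0.02, 0.3, by = 0.02)
  prof <- electron_count_profile(wf, c(0, 0, 0), radii)
  expect_true(all(diff(prof$N) >= 0))
  expect_equal(prof$N, sphere_electron_count(comp, radii), tolerance = 1e-8)
  # last profile point equals a direct integration at the same radius
  g <- sphere_grid(c(0, 0, 0), 0.3)
  expect_equal(prof$N[length(radii)], integrate_sphere(wf, g)$value,
               tolerance = 1e-12)
  expect_error(electron_count_profile(wf, c(0, 0, 0), c(0.3, 0.1)),
               "increasing")
})

test_that("doubling the radial rule leaves the descriptor unchanged", {
  fe <- synthetic_iron_wavefunction()
  v30 <- integrate_sphere(fe, sphere_grid(c(0, 0, 0), 0.06, 30, 110))$value
  v60 <- integrate_sphere(fe, sphere_grid(c(0, 0, 0), 0.06, 60, 110))$value
  expect_lt(abs(v60 - v30), 1e-9)
})

test_that("Laplacian ray profile finds the K-shell depletion maximum", {
  # two-scale shell model: the outermost positive maximum of the Laplacian
  # sits near sqrt(5/(2a)) of the inner (sharper) Gaussian
  comp <- cbind(exponent = c(1000, 10), weight = c(2, 8))
  wf <- synthetic_wavefunction(comp)
  prof <- laplacian_ray_profile(wf, c(0, 0, 0), c(0, 0, 1), 0.4, 400)
  maxima <- attr(prof, "local_maxima")
  expect_gt(length(maxima), 0)
  # oracle: optimize the closed-form Laplacian directly
  lap_cf <- function(r) {
    sum(comp[, 2] * (comp[, 1] / pi)^1.5 * exp(-comp[, 1] * r^2) *
          (4 * comp[, 1]^2 * r^2 - 6 * comp[, 1]))
  }
  oracle <- optimize(Vectorize(lap_cf), c(0.02, 0.2), maximum = TRUE,
                     tol = 1e-10)$maximum
  expect_equal(min(abs(maxima - oracle)), 0, tolerance = 1e-4)
  expect_equal(oracle, sqrt(5 / (2 * 1000)), tolerance = 0.02)

  # opposite directions give identical profiles for a symmetric density
  p1 <- laplacian_ray_profile(wf, c(0, 0, 0), c(1, 1, 0), 0.3, 50)
  p2 <- laplacian_ray_profile(wf, c(0, 0, 0), -c(1, 1, 0), 0.3, 50)
  expect_equal(p1$laplacian, p2$laplacian, tolerance = 1e-12)

  # iron-like test density: positive maximum in the K-shell window
  fe <- synthetic_iron_wavefunction()
  pf <- laplacian_ray_profile(fe, c(0, 0, 0), c(1, 0, 0), 0.3, 300)
  mx <- attr(pf, "local_maxima")
  k_shell <- mx[mx >= 0.03 & mx <= 0.09]
  expect_gt(length(k_shell), 0)
  lap_at_max <- eval_laplacian(fe, c(k_shell[1], 0, 0))$laplacian
  expect_gt(lap_at_max, 0)

  expect_error(laplacian_ray_profile(wf, c(0, 0, 0), c(0, 0, 0), 0.3),
               "nonzero")
})
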