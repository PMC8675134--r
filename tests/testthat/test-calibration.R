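test_that("OLS calibration basics: collinearity, invariances, identities", {
  x <- c(1.1, 1.4, 2.0, 2.7, 3.3)
  y <- 2.5 * x - 1
  f <- fit_calibration(x, y)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$rmsd, 0, tolerance = 1e-10)
  expect_equal(f$slope, 2.5, tolerance = 1e-12)

  set.seed(31)
  y2 <- y + rnorm(5, sd = 0.1)
  f2 <- fit_calibration(x, y2)
  # r^2 equals the squared Pearson correlation for simple OLS
  expect_equal(f2$r_squared, cor(x, y2)^2, tolerance = 1e-12)
  # centering constant is absorbed
  f3 <- fit_calibration(x, y2, center = 1.347)
  expect_equal(predict(f3, x), predict(f2, x), tolerance = 1e-10)
  expect_equal(f3$r_squared, f2$r_squared, tolerance = 1e-12)
  # rescaling x by k scales the slope by 1/k, predictions unchanged
  k <- 250
  f4 <- fit_calibration(x * k, y2)
  expect_equal(f4$slope, f2$slope / k, tolerance = 1e-10)
  expect_equal(predict(f4, x * k), predict(f2, x), tolerance = 1e-10)
  # OLS passes through the centroid
  expect_equal(predict(f2, mean(x)), mean(y2), tolerance = 1e-12)

  expect_error(fit_calibration(rep(1, 5), y), "singular")
  expect_error(fit_calibration(x[1:2], y[1:2]), "at least 3")
})

test_that("calibration on the packaged data has a negative slope", {
  ds <- load_calibration_dataset()
  fit <- published_calibration(ds)
  expect_lt(fit$slope, 0)  # more density in the sphere, smaller shift
  fit0 <- published_calibration(ds, "rho0")
  expect_lt(fit0$slope, 0)
  # the sphere descriptor outperforms the contact density on this basis set
  expect_gt(fit$r_squared, fit0$r_squared)
})

test_that("prediction intervals come from the OLS formula", {
  set.seed(41)
  x <- seq(1, 5, length.out = 20)
  y <- 0.7 * x + rnorm(20, sd = 0.3)
  f <- fit_calibration(x, y)
  pi95 <- predict(f, c(2, 6), interval = "prediction")
  expect_identical(names(pi95), c("fit", "lwr", "upr"))
  expect_true(all(pi95$lwr < pi95$fit & pi95$fit < pi95$upr))
  # wider outside the calibrated range
  expect_gt(pi95$upr[2] - pi95$lwr[2], pi95$upr[1] - pi95$lwr[1])
})

test_that("LOOCV shortcut reproduces the explicit refit loop", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(8:30, 1)
    x <- rnorm(n)
    y <- 1.3 * x + rnorm(n, sd = 0.4)
    hat <- loocv_calibration(x, y, method = "hat")
    loop <- loocv_calibration(x, y, method = "loop")
    expect_equal(hat$per_point$delta_pred, loop$per_point$delta_pred,
                 tolerance = 1e-12)
    expect_equal(hat$q_squared, loop$q_squared, tolerance = 1e-12)
    expect_equal(hat$mae, loop$mae, tolerance = 1e-12)
    # strong tendency (not a theorem): q^2 below the training r^2
    f <- fit_calibration(x, y)
    if (hat$q_squared > f$r_squared) {
      message("note: q^2 exceeded r^2 on a random dataset (allowed)")
    }
  }
  # collinear data cross-validates perfectly
  x <- 1:6
  cv <- loocv_calibration(x, 2 * x + 3)
  expect_equal(cv$q_squared, 1, tolerance = 1e-12)
  expect_equal(cv$mae, 0, tolerance = 1e-10)
  expect_identical(nrow(cv$per_point), 6L)
  expect_error(loocv_calibration(1:3, 1:3), "at least 4")
})

test_that("single-point deletion changes the slope by the leverage formula", {
  ds <- default_signals(load_calibration_dataset())
  x <- ds$rho_sphere_006; y <- ds$delta_exp
  f <- fit_calibration(x, y)
  e <- resid(f$lm)
  h <- lm.influence(f$lm)$hat
  sxx <- sum((x - mean(x))^2)
  for (i in c(1, 44, 92, 103)) {
    fi <- fit_calibration(x[-i], y[-i])
    predicted_change <- e[i] * (x[i] - mean(x)) / ((1 - h[i]) * sxx)
    expect_equal(f$slope - fi$slope, unname(predicted_change),
                 tolerance = 1e-8)
  }
})

test_that("radius sweep recovers the generating radius", {
  set.seed(23)
  n_comp <- 14
  radii <- c(0, seq(0.02, 0.14, by = 0.02))
  comps <- replicate(n_comp, random_components(2, exp_range = c(100, 3000),
                                               w_range = c(0.8, 2)),
                     simplify = FALSE)
  profiles <- t(vapply(comps, function(cp) {
    c(sum(cp[, "weight"] * (cp[, "exponent"] / pi)^1.5),  # rho(0) slot
      sphere_electron_count(cp, radii[-1]))
  }, numeric(length(radii))))

  gen <- which(radii == 0.06)
  delta_clean <- -40 * profiles[, gen] + 8

  # noise-free: perfect correlation at the generating radius
  sw0 <- sweep_radius(profiles, radii, delta_clean)
  expect_equal(sw0$argmax_R, 0.06)
  expect_equal(max(sw0$entries$r_squared), 1, tolerance = 1e-10)

  # with measurement noise the argmax stays at (or next to) 0.06
  delta_noisy <- delta_clean + rnorm(n_comp, sd = 0.02 * sd(delta_clean))
  sw <- sweep_radius(profiles, radii, delta_noisy)
  expect_lte(abs(sw$argmax_R - 0.06), 0.02)

  # control: shifts generated from the contact density peak at the R = 0 slot
  delta_rho0 <- -3 * profiles[, 1] / max(profiles[, 1]) + 2
  sw_rho0 <- sweep_radius(profiles, radii, delta_rho0)
  expect_equal(sw_rho0$argmax_R, 0)

  expect_error(sweep_radius(profiles[, -1], radii, delta_clean),
               "columns")
  pr_na <- profiles; pr_na[2, 3] <- NA
  expect_error(sweep_radius(pr_na, radii, delta_clean), "ragged")
})
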