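# Hertz contact analysis: conversion, contact-point extrapolation, modulus
# recovery, grid processing, and the cell-height analyses.

noiseless_curve <- function(E, ...) {
  simulate_force_curve(curve_sim_spec(E, noise_sd_fraction = 0, ...))
}

test_that("force-indentation conversion applies stiffness and deflection correction", {
  # stiffness 60 pN/nm x 100 nm deflection = 6 nN
  z <- seq(0, 2, by = 0.05)
  defl <- ifelse(z > 1, 100, 0)
  cv <- force_curve(z, deflection = defl, cantilever_stiffness = 60,
                    probe_radius = 2.5)
  fi <- to_force_indentation(cv, contact_z = 1)
  expect_equal(unique(fi$force), 6)
  # delta = piezo travel minus deflection in um; negative deltas dropped
  expected <- (z[z > 1] - 1) - 0.1
  expect_equal(fi$delta, expected[expected >= 0])
  # zero-deflection limit: delta equals raw piezo travel
  cv0 <- force_curve(z, deflection = rep(0, length(z)),
                     cantilever_stiffness = 60)
  fi0 <- to_force_indentation(cv0, contact_z = 1)
  expect_equal(fi0$delta, z[z > 1] - 1)
  # force-mode curves pass the force channel through untouched
  cvf <- force_curve(z, force = defl / 10)
  fif <- to_force_indentation(cvf, contact_z = 1, subtract_deflection = FALSE)
  expect_identical(fif$force, defl[z > 1] / 10)
  expect_error(to_force_indentation(cv, contact_z = 3), "no post-contact data")
})

test_that("contact-point extrapolation recovers the true contact on clean curves", {
  for (E in c(100, 720, 15200)) {
    cv <- noiseless_curve(E, contact_position = 2.0)
    zc <- estimate_contact_point(cv)
    expect_lt(abs(zc - 2.0), cv$truth$sample_spacing)
  }
  # flat curve: nothing ever exceeds the baseline band
  flat <- force_curve(seq(0, 2, by = 0.02), deflection = rep(0, 101),
                      cantilever_stiffness = 60, probe_radius = 2.5)
  expect_error(estimate_contact_point(flat), "no contact detected")
})

test_that("contact estimates stay within two sample spacings on noisy curves", {
  spec <- curve_sim_spec(720, noise_sd_fraction = 0.01, rng_seed = NULL)
  set.seed(202)
  err <- replicate(200, {
    cv <- simulate_force_curve(spec)
    abs(estimate_contact_point(cv) - spec$contact_position)
  })
  expect_lt(mean(err), 2 * spec$sample_spacing)
})

test_that("noiseless fits recover the generating modulus essentially exactly", {
  for (E in c(100, 235, 720, 2100, 15200)) {
    cv <- noiseless_curve(E)
    ft <- fit_hertz(cv, nu = 0.45)
    expect_lt(abs(ft$youngs_modulus - E) / E, 0.005)
    expect_lt(abs(ft$contact_z - cv$truth$contact_position),
              cv$truth$sample_spacing)
    expect_equal(ft$r_squared, 1, tolerance = 1e-6)
  }
})

test_that("fitted modulus is linear in force scale and stable under subsampling", {
  cv <- noiseless_curve(500)
  E1 <- fit_hertz(cv)$youngs_modulus
  # doubling all forces doubles E (Hertz is linear in E)
  cv2 <- cv
  cv2$deflection <- 2 * cv$deflection
  # deflection correction must be off: the doubled signal is no longer a
  # physically consistent deflection of this cantilever
  E2 <- fit_hertz(cv2, subtract_deflection = FALSE)$youngs_modulus
  E1_nc <- fit_hertz(cv, subtract_deflection = FALSE)$youngs_modulus
  expect_equal(E2 / E1_nc, 2, tolerance = 1e-6)
  # halving the sampling density leaves the noiseless fit unchanged
  idx <- seq(1, length(cv$z_piezo), by = 2)
  cv_half <- force_curve(cv$z_piezo[idx], deflection = cv$deflection[idx],
                         cantilever_stiffness = cv$cantilever_stiffness,
                         probe_radius = cv$probe_radius)
  E_half <- fit_hertz(cv_half)$youngs_modulus
  expect_equal(E_half / E1, 1, tolerance = 1e-6)
})

test_that("linearized slope agrees with direct nonlinear least squares", {
  cv <- noiseless_curve(2100)
  ft <- fit_hertz(cv, nu = 0.45)
  fi <- to_force_indentation(cv, ft$contact_z)
  keep <- fi$delta > 0 & fi$delta <= 0.5
  d <- fi$delta[keep]; f <- fi$force[keep]
  # scaleOffset lets nls declare convergence on an exactly-fitting model
  nls_fit <- stats::nls(f ~ C * d^1.5,
                        start = list(C = f[length(f)] / d[length(d)]^1.5),
                        control = stats::nls.control(scaleOffset = 1))
  C <- coef(nls_fit)[["C"]]
  E_nls <- C * (3 / 4) * (1 - 0.45^2) / (sqrt(2.5) * 1e-3)
  expect_equal(ft$youngs_modulus / E_nls, 1, tolerance = 1e-6)
})

test_that("fit quality degrades monotonically with injected noise", {
  set.seed(77)
  mean_r2 <- vapply(c(0.005, 0.01, 0.02), function(ns) {
    mean(replicate(100, {
      cv <- simulate_force_curve(curve_sim_spec(720, noise_sd_fraction = ns))
      fit_hertz(cv)$r_squared
    }))
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("grid processing summarizes fits and flags degenerate cases", {
  cv <- noiseless_curve(2100)
  g <- process_grid(rep(list(cv), 5), grid_shape = c(1, 5))
  expect_equal(g$summary_sd, 0)
  expect_equal(g$summary_mean, 2100, tolerance = 1e-6)
  # single curve: mean defined, SD flagged undefined
  g1 <- process_grid(list(cv))
  expect_true(is.na(g1$summary_sd))
  expect_equal(g1$summary_mean, 2100, tolerance = 1e-6)
  # failed fits are recorded and excluded, not fatal
  flat <- force_curve(seq(0, 2, by = 0.02), deflection = rep(0, 101),
                      cantilever_stiffness = 60, probe_radius = 2.5)
  gmix <- process_grid(list(cv, flat))
  expect_identical(gmix$n_failed, 1L)
  expect_match(gmix$failures, "no contact")
  expect_error(process_grid(list(flat)), "all fits failed")
})

test_that("noisy grid means recover the functionalization-check modulus", {
  set.seed(31)
  curves <- replicate(75, simulate_force_curve(curve_sim_spec(2100)),
                      simplify = FALSE)
  g <- process_grid(curves)
  expect_lt(abs(g$summary_mean - 2100) / 2100, 0.05)
})

test_that("cell height is the symmetric contact-point difference", {
  expect_equal(measure_cell_height(10, 10), 0)
  expect_equal(measure_cell_height(34.7, 10.0), 24.7)
  expect_equal(measure_cell_height(10.0, 34.7), 24.7)
})

test_that("height-modulus regression matches the normal-equation oracle", {
  h <- c(1, 2, 3, 4, 5)
  E <- c(2, 4, 5, 4, 5)
  r <- regress_height_modulus(h, E)
  # independent closed-form oracle from the normal equations
  sxx <- sum((h - mean(h))^2)
  sxy <- sum((h - mean(h)) * (E - mean(E)))
  syy <- sum((E - mean(E))^2)
  expect_equal(r$slope, sxy / sxx, tolerance = 1e-10)
  expect_equal(r$intercept, mean(E) - (sxy / sxx) * mean(h), tolerance = 1e-10)
  expect_equal(r$r_squared, sxy^2 / (sxx * syy), tolerance = 1e-10)
  # exactly collinear points: perfect fit, vanishing p
  rc <- regress_height_modulus(1:5, 2 + 3 * (1:5))
  expect_equal(rc$r_squared, 1)
  expect_lt(rc$p_value, 1e-10)
  expect_error(regress_height_modulus(rep(2, 5), rnorm(5)), "degenerate regressor")
})

test_that("regression p-values are uniform under the null", {
  set.seed(404)
  p <- replicate(500, {
    regress_height_modulus(rnorm(30), rnorm(30))$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
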