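test_that("forward model reproduces the fitted coefficients' predictions", {
  m <- calibration_model()
  expect_equal(forward_signal(m, 0), 0.9984)
  # frozen 30-digit evaluation of the biexponential at the range endpoints
  expect_equal(forward_signal(m, 15), 0.47063038178062080, tolerance = 1e-14)
  expect_equal(forward_signal(m, 5), 0.70692816058812265, tolerance = 1e-14)
  # decays to zero but stays positive
  expect_gt(suppressWarnings(forward_signal(m, 200)), 0)
  expect_lt(suppressWarnings(forward_signal(m, 200)), 1e-3)
  expect_error(forward_signal(m, -1), "nonnegative")
  expect_warning(forward_signal(m, 16), "extrapolating")
})

test_that("forward model is strictly decreasing over the validity range", {
  m <- calibration_model()
  S <- seq(0, 15, length.out = 400)
  expect_true(all(diff(forward_signal(m, S)) < 0))
})

test_that("component ordering is normalized to fast-first", {
  m <- calibration_model(a1 = 0.864, b1 = 0.0405, a2 = 0.1344, b2 = 0.926)
  expect_equal(m$b1, 0.926)
  expect_equal(m$a1, 0.1344)
})

test_that("Newton-Raphson inversion round-trips and matches bisection", {
  m <- calibration_model()
  expect_equal(invert_signal(m, 0.9984), 0, tolerance = 1e-6)
  expect_equal(invert_signal(m, forward_signal(m, 5)), 5, tolerance = 1e-6)
  # seeded signals across the attainable range vs the bisection oracle
  set.seed(71)
  sig <- runif(100, forward_signal(m, 15) + 1e-6, 0.9984 - 1e-6)
  S_nr <- invert_signal(m, sig)
  S_bi <- vapply(sig, function(y) bisect_invert(m, y), numeric(1))
  expect_lt(max(abs(S_nr - S_bi)), 1e-6)
  # monotone: larger signal, smaller stress
  o <- order(sig)
  expect_true(all(diff(S_nr[o]) < 0))
})

test_that("inversion rejects unattainable signals and clamps when asked", {
  m <- calibration_model()
  expect_error(invert_signal(m, 1.2), "attainable")
  expect_error(invert_signal(m, 0.1), "attainable")
  S <- invert_signal(m, c(1.01, 0.8), clamp = TRUE)
  expect_equal(as.numeric(S[1]), 0)
  expect_equal(attr(S, "out_of_range"), c(TRUE, FALSE))
  expect_error(invert_signal(m, 2.0, clamp = TRUE), "more than")
})

test_that("noiseless self-recovery returns the generating coefficients", {
  m <- calibration_model()
  S <- seq(0, 15, length.out = 31)
  fit <- fit_calibration(data.frame(stress_kPa = S,
                                    signal = forward_signal(m, S)))
  expect_equal(fit$a1, 0.1344, tolerance = 1e-3)
  expect_equal(fit$b1, 0.926, tolerance = 1e-3)
  expect_equal(fit$a2, 0.864, tolerance = 1e-3)
  expect_equal(fit$b2, 0.0405, tolerance = 1e-3)
})

test_that("fitting degenerate single-exponential data recovers it", {
  gen <- calibration_model(a1 = 1e-6, b1 = 1, a2 = 0.9, b2 = 0.05)
  S <- seq(0, 15, length.out = 25)
  y <- 0.9 * exp(-0.05 * S)
  fit <- fit_calibration(data.frame(stress_kPa = S, signal = y))
  expect_lt(fit$a1, 0.01)
  expect_equal(fit$a2, 0.9, tolerance = 0.01)
  expect_equal(fit$b2, 0.05, tolerance = 0.01)
})

test_that("replicate fits under 1% noise recover the slow rate", {
  m <- calibration_model()
  S <- seq(0, 15, length.out = 31)
  mu <- forward_signal(m, S)
  set.seed(55)
  b2s <- replicate(200, {
    y <- mu + rnorm(length(S), 0, 0.01)
    fit_calibration(data.frame(stress_kPa = S, signal = abs(y)))$b2
  })
  expect_lt(abs(median(b2s) - 0.0405) / 0.0405, 0.10)
})

test_that("fit precondition violations raise informative errors", {
  S <- c(0, 1, 2, 3, 4)
  expect_error(fit_calibration(data.frame(stress_kPa = S, signal = exp(-S))),
               "6 distinct")
  S2 <- seq(0, 5, length.out = 10)
  expect_error(fit_calibration(data.frame(stress_kPa = S2,
                                          signal = exp(-0.1 * S2))),
               "span")
})

test_that("calibration model JSON round trip preserves all fields", {
  m <- calibration_model(reference_sbr0 = 0.111)
  path <- tempfile(fileext = ".json")
  write_calibration_json(m, path)
  m2 <- read_calibration_json(path)
  expect_equal(m2$a1, m$a1)
  expect_equal(m2$b2, m$b2)
  expect_equal(m2$reference_sbr0, 0.111)
  expect_equal(m2$stress_range, c(0, 15))
})

test_that("strain model is saturating, monotone, and exactly invertible", {
  sm <- particle_strain_model(particle_modulus = 7.5, max_strain = 0.5)
  expect_equal(strain_from_stress(sm, 0), 0)
  expect_equal(strain_from_stress(sm, 7.5), 0.25)  # half saturation
  S <- seq(0, 15, length.out = 100)
  eps <- strain_from_stress(sm, S)
  expect_true(all(diff(eps) > 0))
  expect_true(all(eps < 0.5))
  expect_equal(stress_from_strain(sm, strain_from_stress(sm, 7.3)), 7.3,
               tolerance = 1e-10)
  expect_equal(stress_from_strain(sm, strain_from_stress(sm, 7)), 7,
               tolerance = 1e-8)
  expect_error(stress_from_strain(sm, 0.6), "asymptote")
})
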