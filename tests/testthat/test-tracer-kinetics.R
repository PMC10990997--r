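test_that("arterial curves validate and prepend the implicit (0, 0) sample", {
  curve <- arterial_curve(seq(3, 60, by = 3), rep(50, 20))
  expect_equal(curve$times[1], 0)
  expect_equal(curve$conc[1], 0)
  expect_length(curve$times, 21)

  expect_error(arterial_curve(c(0, 3, 3), c(0, 1, 2)), class = "iap_validation_error")
  expect_error(arterial_curve(c(0, 3), c(0, -1)), class = "iap_validation_error")
  expect_error(arterial_curve(c(-1, 3), c(0, 1)), class = "iap_validation_error")
  expect_error(kinetic_params(lambda = 0), class = "iap_validation_error")
  expect_error(kinetic_params(m = -1), class = "iap_validation_error")
})

test_that("zero flow yields zero uptake and negative flow is rejected", {
  curve <- ramp_curve()
  expect_identical(forward_tissue_concentration(0, curve), 0)
  expect_error(forward_tissue_concentration(-0.1, curve),
               class = "iap_validation_error")
})

test_that("constant-input uptake matches the analytic closed form", {
  curve <- constant_curve(100)
  p <- kinetic_params()
  # K = 1/min at f = 0.8 ml/g/min: lambda * C * (1 - exp(-1))
  expect_equal(forward_tissue_concentration(0.8, curve, p),
               0.8 * 100 * (1 - exp(-1)), tolerance = 1e-12)
  for (kt in c(0.01, 0.1, 0.5, 1, 2, 5, 10, 20)) {
    f <- kt * p$lambda / p$m   # K T = kt with T = 1 min
    expected <- p$lambda * 100 * (1 - exp(-kt))
    expect_equal(forward_tissue_concentration(f, curve, p), expected,
                 tolerance = 1e-10)
  }
})

test_that("uptake agrees with a brute-force quadrature oracle on random curves", {
  set.seed(42)
  p <- kinetic_params()
  for (i in 1:50) {
    curve <- random_curve()
    f <- runif(1, 0.05, 5)
    got <- forward_tissue_concentration(f, curve, p)
    oracle <- trapz_forward(f, curve, p)
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("uptake is bounded by lambda times the arterial maximum", {
  set.seed(7)
  p <- kinetic_params()
  for (i in 1:20) {
    curve <- random_curve()
    for (f in c(0.1, 1, 5, 50)) {
      ci <- forward_tissue_concentration(f, curve, p)
      expect_gte(ci, 0)
      expect_lte(ci, p$lambda * max(curve$conc) * (1 + 1e-12))
    }
  }
})

test_that("uptake increases strictly with flow for rising arterial inputs", {
  set.seed(11)
  p <- kinetic_params()
  fs <- seq(0.05, 5, length.out = 40)
  for (i in 1:10) {
    # ramped-infusion-like input: non-decreasing over the sampling window
    times <- seq(0, 60, by = 3)
    conc <- cumsum(c(0, runif(20, 0, 40)))
    curve <- arterial_curve(times, conc)
    cis <- vapply(fs, forward_tissue_concentration, numeric(1),
                  curve = curve, params = p)
    expect_true(all(diff(cis) > 0))
  }
})

test_that("inversion recovers flow from noiseless uptake (round trip)", {
  p <- kinetic_params()
  curves <- list(ramp = ramp_curve(),
                 gamma = simulate_arterial_curve(800, 60))
  for (curve in curves) {
    for (f in c(0.1, 0.5, 1.0, 2.0, 5.0)) {
      ci <- forward_tissue_concentration(f, curve, p)
      expect_equal(invert_flow(ci, curve, p), f, tolerance = 1e-6)
    }
  }
  expect_identical(invert_flow(0, ramp_curve(), p), 0)
})

test_that("analytic constant-input inverse is recovered", {
  curve <- constant_curve(100)
  ci <- 0.8 * 100 * (1 - exp(-1))  # f = 0.8 ml/g/min
  expect_equal(invert_flow(ci, curve, kinetic_params()), 0.8, tolerance = 1e-6)
})

test_that("inversion flags saturation and degenerate inputs", {
  p <- kinetic_params()
  gam <- simulate_arterial_curve(800, 60)
  # ceiling for this curve is lambda * peak = 640 nCi/g
  expect_error(invert_flow(650, gam, p), class = "iap_saturation_error")
  expect_error(invert_flow(650, gam, p), "ceiling")
  zero <- arterial_curve(c(0, 60), c(0, 0))
  expect_error(invert_flow(10, zero, p), class = "iap_saturation_error")
  expect_error(invert_flow(-1, gam, p), class = "iap_validation_error")
})

test_that("decapitation beyond the arterial coverage is rejected", {
  curve <- ramp_curve()  # samples to 60 s every 3 s
  expect_error(
    forward_tissue_concentration(1, curve, kinetic_params(decap_time_s = 64)),
    class = "iap_validation_error")
  # within one sampling interval: the curve is held at its last value
  ci <- forward_tissue_concentration(1, curve, kinetic_params(decap_time_s = 62))
  expect_gt(ci, 0)
})

test_that("equilibrium tissue:blood ratio equals the partition coefficient", {
  expect_identical(equilibrium_tissue_blood_ratio(kinetic_params()), 0.80)
  expect_identical(equilibrium_tissue_blood_ratio(kinetic_params(lambda = 1)), 1.0)
  # numerical cross-check at K T = 50, constant input
  p <- kinetic_params()
  f <- 50 * p$lambda / p$m
  ratio <- forward_tissue_concentration(f, constant_curve(100), p) / 100
  expect_equal(ratio, p$lambda, tolerance = 1e-10)
})
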