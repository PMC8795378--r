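# The generator is the ground-truth oracle for every surrogate test, so its
# own physics gets checked analytically here.

test_that("irradiance field obeys Beer-Lambert attenuation", {
  geom <- pbr_geometry()
  optics <- optical_params(noise_sd = 0, lateral_blur_sigma = 0)
  # no biomass: no attenuation anywhere
  f0 <- generate_irradiance_field(150, 0, geom, optics)
  expect_true(all(f0 == 150))
  # engineered half-attenuation: extinction * C * depth(row 9) = ln 2
  depth9 <- (9 - 0.5) / 18 * geom$depth_m
  conc <- log(2) / (optics$extinction_coeff * depth9)
  f <- generate_irradiance_field(100, conc, geom, optics)
  expect_equal(f[9, 1], 50, tolerance = 1e-12)
  # monotone decay away from the source
  expect_true(all(diff(f[, 1]) < 0))
  expect_error(generate_irradiance_field(-5, 1), "intensity")
})

test_that("double-source fields are symmetric under row reversal", {
  geom <- pbr_geometry(n_sources = 2L)
  optics <- optical_params(noise_sd = 0)
  f <- generate_irradiance_field(574, 1.2, geom, optics)
  expect_equal(f, f[rev(seq_len(nrow(f))), ], tolerance = 1e-12)
  # superposition: double field equals front + mirrored front
  geom1 <- pbr_geometry(n_sources = 1L)
  f1 <- generate_irradiance_field(574, 1.2, geom1, optics)
  expect_equal(f, f1 + f1[rev(seq_len(nrow(f1))), ], tolerance = 1e-12)
})

test_that("grayscale conversion is linear, clipped and integer-valued", {
  optics <- optical_params(noise_sd = 0, gsv_slope = 0.3, gsv_intercept = 0)
  sat <- irradiance_to_gsv(matrix(1000, 2, 2), optics)
  expect_true(all(sat == 255L))
  optics1 <- optical_params(noise_sd = 0, gsv_slope = 1, gsv_intercept = 0)
  expect_true(all(irradiance_to_gsv(matrix(100, 3, 3), optics1) == 100L))
  # inverse regression of noise-free output recovers the response exactly
  irr <- matrix(seq(10, 700, length.out = 50), 5, 10)
  optics2 <- optical_params(noise_sd = 0, gsv_slope = 0.25, gsv_intercept = 4)
  gsv <- optics2$gsv_slope * irr + optics2$gsv_intercept  # pre-rounding response
  fit <- lm(as.numeric(gsv) ~ as.numeric(irr))
  expect_equal(unname(coef(fit)), c(4, 0.25), tolerance = 1e-10)
})

test_that("generated gray values stay in [0, 255] even under heavy noise", {
  ds <- generate_ldp_dataset(c(50, 700), c(0.1, 3.5),
                             optics = optical_params(noise_sd = 40), seed = 5)
  for (ldp in ds$ldps) {
    expect_true(all(ldp >= 0L & ldp <= 255L))
    expect_true(is.integer(ldp))
  }
})

test_that("dataset generation covers the Cartesian grid and is byte-reproducible", {
  ints <- seq(100, 700, length.out = 5)
  concs <- calibration_concentrations()
  ds1 <- generate_ldp_dataset(ints, concs, seed = 99)
  expect_length(ds1$ldps, 5 * 23)
  ds2 <- generate_ldp_dataset(ints, concs, seed = 99)
  expect_identical(ds1$ldps, ds2$ldps)
  ds3 <- generate_ldp_dataset(ints, concs, seed = 100)
  expect_false(identical(ds1$ldps, ds3$ldps))
  expect_error(generate_ldp_dataset(numeric(0), concs), "non-empty")
})

test_that("dark fraction grows with concentration and shrinks with intensity", {
  optics <- optical_params(noise_sd = 0)
  geom <- pbr_geometry()
  concs <- seq(0.2, 3.8, length.out = 8)
  for (i0 in c(150, 400, 700)) {
    dark <- vapply(concs, function(cc) {
      dark_area_fraction(irradiance_to_gsv(
        generate_irradiance_field(i0, cc, geom, optics), optics))
    }, numeric(1))
    expect_true(all(diff(dark) >= 0))
  }
  ints <- seq(50, 800, length.out = 8)
  for (cc in c(0.5, 1.5, 3)) {
    dark <- vapply(ints, function(i0) {
      dark_area_fraction(irradiance_to_gsv(
        generate_irradiance_field(i0, cc, geom, optics), optics))
    }, numeric(1))
    expect_true(all(diff(dark) <= 0))
  }
})

test_that("true growth simulation has the right limiting behaviour", {
  sched <- constant_light(400, 12)
  # mu_max = 0: flat trajectory
  flat <- simulate_true_growth(1.5, sched, true_growth_model(mu_max = 0))
  expect_true(all(flat$od730 == 1.5))
  # no attenuation, saturated light, no penalty: exponential growth
  optics <- optical_params(extinction_coeff = 1e-9, noise_sd = 0)
  model <- true_growth_model(mu_max = 0.05, light_half_sat = 1e-6)
  dt <- 0.01
  curve <- simulate_true_growth(1, sched, model, pbr_geometry(), optics, dt = dt)
  expect_equal(curve$od730[nrow(curve)], exp(0.05 * 12), tolerance = 1e-3)
  # forced full darkness: rate collapses to ~0 and the trajectory plateaus
  darkm <- true_growth_model(dark_penalty_onset = 0.0001,
                             dark_penalty_full = 0.0002)
  heavy <- optical_params(noise_sd = 0)
  dark_curve <- simulate_true_growth(12, constant_light(60, 12), darkm,
                                     pbr_geometry(), heavy)
  expect_equal(dark_curve$dark_fraction[1], 1)
  expect_equal(dark_curve$od730[nrow(dark_curve)], 12, tolerance = 1e-9)
})

test_that("datasets round-trip through the flat CSV and PNG layouts", {
  ds <- generate_ldp_dataset(c(100, 500), c(0.4, 2.0), seed = 8)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_ldp_dataset(ds, csv, format = "csv")
  back <- read_ldp_dataset(csv)
  expect_identical(back$ldps, ds$ldps)
  expect_equal(back$intensity, ds$intensity)
  expect_equal(back$concentration, ds$concentration)
  dir <- withr::local_tempdir()
  write_ldp_dataset(ds, dir, format = "png")
  back2 <- read_ldp_dataset(dir)
  expect_identical(back2$ldps, ds$ldps)
})

test_that("record-level splits partition the dataset reproducibly", {
  ds <- generate_ldp_dataset(seq(100, 700, length.out = 5),
                             seq(0.2, 3, length.out = 5), seed = 2)
  sp <- split_ldp_dataset(ds, 0.2, seed = 3)
  expect_length(sp$test$ldps, 5)
  expect_length(sp$train$ldps, 20)
  sp2 <- split_ldp_dataset(ds, 0.2, seed = 3)
  expect_identical(sp$test$ldps, sp2$test$ldps)
})
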