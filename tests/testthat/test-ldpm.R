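test_that("a noise-free fit generalizes across the condition grid", {
  fx <- tiny_ldpm_setup()
  ev <- evaluate_ldpm(fx$model, fx$split$test)
  expect_gt(ev$overall_r2, 0.98)
  expect_equal(ev$n_test, length(fx$split$test$ldps))
})

test_that("training rejects degenerate inputs", {
  ds <- generate_ldp_dataset(c(100, 500), c(0.5, 2), seed = 1)
  expect_error(train_ldpm(ds), "at least 10")
  # single repeated condition
  one <- generate_ldp_dataset(300, 1, seed = 1)
  rep12 <- one
  rep12$intensity <- rep(300, 12)
  rep12$concentration <- rep(1, 12)
  rep12$ldps <- rep(one$ldps, 12)
  expect_error(train_ldpm(rep12), "degenerate")
})

test_that("a dataset of identical LDPs trains to a constant predictor", {
  base <- generate_ldp_dataset(seq(100, 400, length.out = 4),
                               seq(0.5, 2, length.out = 3),
                               optics = optical_params(noise_sd = 0), seed = 4)
  const_ldp <- matrix(123L, 18, 40)
  base$ldps <- rep(list(const_ldp), length(base$ldps))
  m <- train_ldpm(base, ldpm_config(grid = NULL))
  pred <- predict_ldp(m, 250, 1.0)
  expect_true(all(pred == 123L))
})

test_that("predictions are integer gray values in [0, 255] across a wide sweep", {
  fx <- tiny_ldpm_setup()
  for (i0 in c(0, 100, 700, 900)) for (cc in c(0, 1, 3.5, 5)) {
    p <- predict_ldp(fx$model, i0, cc, warn = FALSE)
    expect_true(is.integer(p))
    expect_true(all(p >= 0L & p <= 255L))
  }
})

test_that("conditions beyond the training domain are flagged as extrapolation", {
  fx <- tiny_ldpm_setup()
  expect_warning(p <- predict_ldp(fx$model, 300, 5.0), "extrapolation")
  expect_true(attr(p, "extrapolated"))
  p_in <- predict_ldp(fx$model, 300, 1.0)
  expect_false(attr(p_in, "extrapolated"))
})

test_that("training is insensitive to record order", {
  fx <- tiny_ldpm_setup()
  tr <- fx$split$train
  set.seed(5)
  perm <- sample(seq_along(tr$ldps))
  shuffled <- tr
  shuffled$intensity <- tr$intensity[perm]
  shuffled$concentration <- tr$concentration[perm]
  shuffled$ldps <- tr$ldps[perm]
  cfg <- ldpm_config(grid = NULL, cost = 100, epsilon = 0.01, seed = 71)
  m2 <- train_ldpm(shuffled, cfg)
  for (cond in list(c(250, 0.8), c(600, 3.0))) {
    p1 <- predict_ldp(fx$model, cond[1], cond[2])
    p2 <- predict_ldp(m2, cond[1], cond[2])
    expect_lte(max(abs(p1 - p2)), 1L)
  }
})

test_that("pooled R2 equals an independently flattened concatenation", {
  fx <- tiny_ldpm_setup()
  ev <- evaluate_ldpm(fx$model, fx$split$test)
  # brute-force oracle: predict record by record, flatten everything, pool
  test <- fx$split$test
  obs <- c(); pred <- c()
  for (i in seq_along(test$ldps)) {
    p <- predict_ldp(fx$model, test$intensity[i], test$concentration[i],
                     warn = FALSE)
    obs <- c(obs, as.vector(t(test$ldps[[i]])))
    pred <- c(pred, as.vector(t(p)))
  }
  oracle <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  expect_equal(ev$overall_r2, oracle, tolerance = 1e-12)
})

test_that("R2 definitions behave at the boundaries", {
  y <- c(3, 9, 14, 20)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_true(is.na(r_squared(rep(5, 4), c(5, 5, 5, 6))))
})

test_that("pixels with zero test variance are excluded from the map but counted", {
  # low intensities + high concentrations leave deep pixels pinned at the
  # sensor offset, so their test labels have zero variance
  optics <- optical_params(noise_sd = 0)
  ds <- generate_ldp_dataset(seq(30, 120, length.out = 5),
                             seq(2.5, 3.9, length.out = 4),
                             pbr_geometry(), optics, seed = 9)
  sp <- split_ldp_dataset(ds, 0.25, seed = 9)
  m <- train_ldpm(sp$train, ldpm_config(grid = NULL))
  ev <- evaluate_ldpm(m, sp$test)
  expect_gt(ev$n_undefined_pixels, 0)
  expect_equal(sum(is.na(ev$per_pixel_r2)), ev$n_undefined_pixels)
  expect_false(is.na(ev$overall_r2))
})

test_that("held-out error shrinks as the training grid is refined", {
  optics <- optical_params(noise_sd = 0)
  test_ds <- generate_ldp_dataset(seq(130, 670, length.out = 5),
                                  seq(0.35, 3.15, length.out = 5),
                                  pbr_geometry(), optics, seed = 55)
  rmse <- vapply(c(5, 8, 12), function(g) {
    ds <- generate_ldp_dataset(seq(100, 700, length.out = g),
                               seq(0.1, 3.5, length.out = g),
                               pbr_geometry(), optics, seed = 56)
    m <- train_ldpm(ds, ldpm_config(grid = NULL, cost = 100, epsilon = 0.01))
    ev <- evaluate_ldpm(m, test_ds)
    sqrt(mean(vapply(seq_along(test_ds$ldps), function(i) {
      p <- predict_ldp(m, test_ds$intensity[i], test_ds$concentration[i],
                       warn = FALSE)
      mean((as.numeric(p) - as.numeric(test_ds$ldps[[i]]))^2)
    }, numeric(1))))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("a saved model archive reproduces predictions exactly", {
  fx <- tiny_ldpm_setup()
  dir <- withr::local_tempdir()
  save_ldpm(fx$model, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  m2 <- load_ldpm(dir)
  for (cond in list(c(150, 0.3), c(420, 1.9), c(700, 3.5))) {
    expect_identical(
      predict_ldp(fx$model, cond[1], cond[2], warn = FALSE),
      predict_ldp(m2, cond[1], cond[2], warn = FALSE))
  }
})
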