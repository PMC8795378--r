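test_that("finite-difference growth rates recover simple rate laws", {
  t <- 0:10
  lin <- compute_growth_rates(t, 1 + 0.2 * t)
  expect_equal(lin$rate, rep(0.2, 11), tolerance = 1e-12)
  const <- compute_growth_rates(t, rep(2.5, 11))
  expect_equal(const$rate, rep(0, 11))
  expect_error(compute_growth_rates(c(0, 2, 1), c(1, 2, 3)), "increasing")
  expect_error(compute_growth_rates(c(0, 1), c(1, 2)), "3 time points")
})

test_that("central differences track an exponential's analytic derivative within 1%", {
  t <- 0:24
  od <- exp(0.1 * t)
  fd <- compute_growth_rates(t, od)
  interior <- 2:24
  rel_err <- abs(fd$rate[interior] - 0.1 * od[interior]) / (0.1 * od[interior])
  expect_true(all(rel_err < 0.01))
})

test_that("feature extraction flattens, scales and summarises deterministically", {
  all_white <- matrix(255L, 18, 40)
  f <- extract_features(all_white)
  expect_length(f, 722)
  expect_true(all(f[1:721] == 1))
  expect_equal(f[722], 0)  # dark fraction
  all_black <- matrix(0L, 18, 40)
  g <- extract_features(all_black)
  expect_true(all(g[1:721] == 0))
  expect_equal(g[722], 1)
  # row-major order: pixel 41 is row 2, column 1
  m <- matrix(0L, 18, 40); m[2, 1] <- 255L
  expect_equal(extract_features(m, grm_feature_config(summaries = FALSE))[41], 1)
  # pixels-only / summaries-only configurations
  expect_length(extract_features(m, grm_feature_config(summaries = FALSE)), 720)
  expect_length(extract_features(m, grm_feature_config(pixels = FALSE)), 2)
})

test_that("features are invariant to the PNG serialization route", {
  set.seed(21)
  ldp <- matrix(sample(0:255, 720, replace = TRUE), 18, 40)
  path <- withr::local_tempfile(fileext = ".png")
  write_ldp_png(ldp, path)
  expect_identical(extract_features(ldp), extract_features(read_ldp_png(path)))
})

test_that("a noise-free linear rate law is learned almost exactly", {
  optics <- optical_params(noise_sd = 0)
  ds <- generate_ldp_dataset(seq(100, 700, length.out = 9),
                             seq(0.1, 3.5, length.out = 9),
                             pbr_geometry(), optics, seed = 81)
  feats <- t(vapply(ds$ldps, extract_features, numeric(722)))
  rates <- 0.4 * feats[, 721] + 0.02  # linear in mean gray value
  set.seed(81)
  test_idx <- sample(nrow(feats), 16)
  m <- train_grm(feats[-test_idx, ], rates[-test_idx], grm_config(seed = 81))
  r2 <- evaluate_grm(m, feats[test_idx, ], rates[test_idx])
  expect_gt(as.numeric(r2), 0.999)
  # and near-perfect recall of its own training pairs
  r2_train <- evaluate_grm(m, feats[-test_idx, ], rates[-test_idx])
  expect_gt(as.numeric(r2_train), 0.99)
})

test_that("negative raw predictions are floored at zero and counted", {
  optics <- optical_params(noise_sd = 0)
  ds <- generate_ldp_dataset(seq(100, 700, length.out = 6),
                             seq(0.1, 3.5, length.out = 6),
                             pbr_geometry(), optics, seed = 82)
  feats <- t(vapply(ds$ldps, extract_features, numeric(722)))
  rates <- feats[, 721] - 0.35  # negative for dim LDPs
  m <- train_grm(feats, rates, grm_config(grid = NULL, cost = 100,
                                          epsilon = 0.01, gamma = 0.05))
  dark_ldp <- matrix(0L, 18, 40)
  p <- predict_growth_rate(m, dark_ldp)
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "n_floored"), 1)
  expect_error(train_grm(feats, rates[-1]), "differ")
})

test_that("the trained growth-rate surface declines once shading passes the onset", {
  fx <- noise_free_setup()
  concs <- seq(0.3, 3.5, length.out = 30)
  out <- vapply(concs, function(cc) {
    ldp <- predict_ldp(fx$ldpm, 300, cc, warn = FALSE)
    c(dark = dark_area_fraction(ldp),
      rate = as.numeric(predict_growth_rate(fx$grm, ldp)))
  }, numeric(2))
  dark <- out["dark", ]; rate <- out["rate", ]
  onset <- true_growth_model()$dark_penalty_onset
  beyond <- which(dark > onset + 0.05)
  expect_gte(length(beyond), 3)
  # finite sampling: allow tiny regression wiggle, demand overall decline
  diffs <- diff(rate[beyond])
  expect_true(all(diffs < 0.01 * max(rate)))
  expect_lt(rate[max(beyond)], max(rate[beyond]) * 0.7)
})
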