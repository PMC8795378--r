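#' Training configuration for the LDP prediction model
#'
#' Hyperparameters for the pixel-wise support-vector-regression surrogate.
#' Regularization (`cost`) and the epsilon tube are selected by seeded
#' cross-validation over a small grid; to keep 720 per-pixel fits tractable
#' the grid search runs on a spread of `tune_pixels` representative pixels
#' and the winning pair is reused for every pixel. Set `tune = FALSE` to fit
#' all pixels directly with `cost` / `epsilon`.
#'
#' @param kernel SVR kernel (default `"radial"`).
#' @param cost regularization constant used when `tune = FALSE` (and as a
#'   fallback), > 0.
#' @param epsilon epsilon-tube half width on the standardized label scale,
#'   > 0.
#' @param gamma RBF kernel width; `NULL` uses 1 / n_features.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param grid named list with numeric vectors `cost` and `epsilon` scanned
#'   during tuning; `NULL` disables tuning.
#' @param tune_pixels number of evenly spaced pixels used for the grid
#'   search.
#' @param seed integer seed fixing fold assignment.
#' @param test_fraction default held-out fraction used by
#'   [split_ldp_dataset()] in benchmark workflows.
#' @return An `ldpm_config` object.
#' @export
ldpm_config <- function(kernel = "radial",
                        cost = 100,
                        epsilon = 0.01,
                        gamma = NULL,
                        cv_folds = 3L,
                        grid = list(cost = c(1, 10, 100),
                                    epsilon = c(0.01, 0.05, 0.1)),
                        tune_pixels = 9L,
                        seed = 1L,
                        test_fraction = 0.2) {
  assert_scalar_num(cost, "cost", 0, allow_zero = FALSE)
  assert_scalar_num(epsilon, "epsilon", 0, allow_zero = FALSE)
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("`cv_folds` must be >= 2", call. = FALSE)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(kernel = kernel, cost = cost, epsilon = epsilon, gamma = gamma,
         cv_folds = cv_folds, grid = grid, tune_pixels = as.integer(tune_pixels),
         seed = as.integer(seed), test_fraction = test_fraction),
    class = "ldpm_config")
}

# Labels matrix (n_records x n_pixels, row-major pixel order) from a dataset.
dataset_labels <- function(dataset) {
  n_px <- dataset$geometry$rows * dataset$geometry$cols
  t(vapply(dataset$ldps, flatten_ldp, numeric(n_px)))
}

scale_features <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# Deterministic fold assignment.
cv_fold_ids <- function(n, k, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# Fit one standardized-label SVR; constant labels collapse to a stored value.
fit_pixel_svr <- function(xs, y, kernel, cost, epsilon, gamma) {
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale == 0) {
    return(list(constant = y_center))
  }
  fit <- e1071::svm(x = xs, y = (y - y_center) / y_scale,
                    type = "eps-regression", kernel = kernel,
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    scale = FALSE)
  list(svm = fit, y_center = y_center, y_scale = y_scale)
}

predict_pixel_svr <- function(model, xs) {
  if (!is.null(model$constant)) {
    return(rep(model$constant, nrow(xs)))
  }
  as.numeric(stats::predict(model$svm, xs)) * model$y_scale + model$y_center
}

#' Train the LDP prediction model
#'
#' Fits one support-vector regressor per LDP pixel, mapping the two scalar
#' features (incident light intensity, cell concentration) to that pixel's
#' gray value — the training is performed pixel by pixel, with a shared
#' affine standardization of the features. The observed feature ranges are
#' stored so that later predictions outside them can be flagged as
#' extrapolation.
#'
#' @param dataset an `ldp_dataset` of training records (>= 10, spanning more
#'   than one distinct condition).
#' @param config an [ldpm_config()].
#' @return An object of class `ldpm`.
#' @export
train_ldpm <- function(dataset, config = ldpm_config()) {
  stopifnot(inherits(dataset, "ldp_dataset"), inherits(config, "ldpm_config"))
  x <- cbind(intensity = dataset$intensity,
             concentration = dataset$concentration)
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 training records", call. = FALSE)
  if (nrow(unique(x)) < 2L) {
    stop("degenerate dataset: all records share one (intensity, concentration) condition",
         call. = FALSE)
  }
  scaler <- list(center = colMeans(x), scale = apply(x, 2, stats::sd))
  scaler$scale[scaler$scale == 0] <- 1
  xs <- scale_features(x, scaler)
  labels <- dataset_labels(dataset)
  gamma <- if (is.null(config$gamma)) 1 / ncol(xs) else config$gamma

  hp <- list(cost = config$cost, epsilon = config$epsilon)
  if (!is.null(config$grid)) {
    hp <- tune_ldpm_grid(xs, labels, config, gamma)
  }
  pixel_models <- lapply(seq_len(ncol(labels)), function(j) {
    fit_pixel_svr(xs, labels[, j], config$kernel, hp$cost, hp$epsilon, gamma)
  })
  structure(
    list(pixel_models = pixel_models,
         feature_scaler = scaler,
         training_domain = list(intensity = range(dataset$intensity),
                                concentration = range(dataset$concentration)),
         geometry = dataset$geometry,
         config = config,
         hyperparameters = c(hp, gamma = gamma)),
    class = "ldpm")
}

# Seeded k-fold grid search on a spread of representative pixels; returns
# the (cost, epsilon) pair with lowest mean validation MSE.
tune_ldpm_grid <- function(xs, labels, config, gamma) {
  n_px <- ncol(labels)
  px_idx <- unique(round(seq(1, n_px, length.out = config$tune_pixels)))
  px_idx <- px_idx[apply(labels[, px_idx, drop = FALSE], 2, stats::sd) > 0]
  if (length(px_idx) == 0L) {
    return(list(cost = config$cost, epsilon = config$epsilon))
  }
  folds <- cv_fold_ids(nrow(xs), config$cv_folds, config$seed)
  combos <- expand.grid(cost = config$grid$cost, epsilon = config$grid$epsilon,
                        KEEP.OUT.ATTRS = FALSE)
  errs <- vapply(seq_len(nrow(combos)), function(i) {
    mse <- 0
    for (k in seq_len(config$cv_folds)) {
      tr <- folds != k
      for (j in px_idx) {
        m <- fit_pixel_svr(xs[tr, , drop = FALSE], labels[tr, j],
                           config$kernel, combos$cost[i], combos$epsilon[i],
                           gamma)
        pred <- predict_pixel_svr(m, xs[!tr, , drop = FALSE])
        mse <- mse + mean((labels[!tr, j] - pred)^2)
      }
    }
    mse
  }, numeric(1))
  best <- which.min(errs)
  list(cost = combos$cost[best], epsilon = combos$epsilon[best])
}

#' @export
print.ldpm <- function(x, ...) {
  cat(sprintf("ldpm: %d pixel SVRs (%s kernel, cost %g, epsilon %g)\n",
              length(x$pixel_models), x$config$kernel,
              x$hyperparameters$cost, x$hyperparameters$epsilon))
  cat(sprintf("  training domain: intensity [%g, %g], concentration [%g, %g]\n",
              x$training_domain$intensity[1], x$training_domain$intensity[2],
              x$training_domain$concentration[1], x$training_domain$concentration[2]))
  invisible(x)
}

# Raw (unclipped, unrounded) predictions for many conditions at once:
# returns n_conditions x n_pixels matrix.
predict_ldpm_matrix <- function(model, intensity, concentration) {
  x <- cbind(intensity = intensity, concentration = concentration)
  xs <- scale_features(x, model$feature_scaler)
  vapply(model$pixel_models, predict_pixel_svr, numeric(nrow(xs)), xs = xs)
}

in_training_domain <- function(model, intensity, concentration) {
  d <- model$training_domain
  intensity >= d$intensity[1] & intensity <= d$intensity[2] &
    concentration >= d$concentration[1] & concentration <= d$concentration[2]
}

#' Predict an LDP for a given condition
#'
#' Runs all 720 per-pixel regressors at a single (intensity, concentration)
#' point, clips the raw outputs to `[0, 255]` and rounds to integer gray
#' values. Conditions outside the training domain are still predicted but
#' the result carries an `extrapolated` attribute (and a warning by
#' default), since surrogate output is untrustworthy beyond the conditions
#' it has seen — in particular above the trained concentration ceiling.
#'
#' @param model an [train_ldpm()] fit.
#' @param intensity incident light intensity, umol m-2 s-1 (>= 0).
#' @param concentration cell concentration, g/L (>= 0).
#' @param warn warn on extrapolation (default TRUE).
#' @return Integer gray matrix with attribute `extrapolated` (logical).
#' @export
predict_ldp <- function(model, intensity, concentration, warn = TRUE) {
  stopifnot(inherits(model, "ldpm"))
  assert_scalar_num(intensity, "intensity", 0)
  assert_scalar_num(concentration, "concentration", 0)
  raw <- predict_ldpm_matrix(model, intensity, concentration)
  extra <- !in_training_domain(model, intensity, concentration)
  if (extra && warn) {
    warning(sprintf("condition (I = %g, C = %g) outside training domain; prediction is an extrapolation",
                    intensity, concentration), call. = FALSE)
  }
  out <- unflatten_ldp(round(clip(as.numeric(raw), 0, 255)),
                       model$geometry$rows, model$geometry$cols)
  storage.mode(out) <- "integer"
  attr(out, "extrapolated") <- extra
  out
}

#' Evaluate an LDPM on held-out records
#'
#' Reproduces the pixel-by-pixel evaluation scheme: an R-squared per pixel,
#' computed across the test records at that pixel, plus a pooled overall
#' R-squared over all (record, pixel) pairs. Pixels whose test labels have
#' zero variance have no defined per-pixel R-squared; they are excluded
#' from the per-pixel map (and counted) but their residuals still enter the
#' pooled statistic.
#'
#' @param model an `ldpm`.
#' @param test_dataset an `ldp_dataset` with >= 2 records.
#' @return An `ldpm_evaluation`: list with `overall_r2`, `per_pixel_r2`
#'   (rows x cols matrix, `NA` where undefined), `n_undefined_pixels`,
#'   `frac_pixels_above` (function of a threshold `q`), and `n_test`.
#' @export
evaluate_ldpm <- function(model, test_dataset) {
  stopifnot(inherits(model, "ldpm"), inherits(test_dataset, "ldp_dataset"))
  if (length(test_dataset$ldps) < 2L) {
    stop("need at least 2 test records", call. = FALSE)
  }
  labels <- dataset_labels(test_dataset)
  raw <- predict_ldpm_matrix(model, test_dataset$intensity,
                             test_dataset$concentration)
  preds <- round(clip(raw, 0, 255))
  per_px <- vapply(seq_len(ncol(labels)), function(j) {
    r_squared(labels[, j], preds[, j])
  }, numeric(1))
  overall <- r_squared(as.numeric(labels), as.numeric(preds))
  per_px_grid <- unflatten_ldp(per_px, model$geometry$rows, model$geometry$cols)
  structure(
    list(overall_r2 = overall,
         per_pixel_r2 = per_px_grid,
         n_undefined_pixels = sum(is.na(per_px)),
         frac_pixels_above = function(q) mean(per_px > q, na.rm = TRUE),
         n_test = nrow(labels)),
    class = "ldpm_evaluation")
}

#' @export
print.ldpm_evaluation <- function(x, ...) {
  cat(sprintf("ldpm_evaluation: overall R2 = %.4f over %d test LDPs\n",
              x$overall_r2, x$n_test))
  cat(sprintf("  pixels with R2 > 0.90: %.1f%% (%d undefined)\n",
              100 * x$frac_pixels_above(0.90), x$n_undefined_pixels))
  invisible(x)
}

#' Save / load an LDPM archive
#'
#' The archive is a directory holding a JSON metadata header (configuration,
#' hyperparameters, feature scaler, training domain, geometry) next to an
#' RDS store with the per-pixel regressor parameters. A round-tripped model
#' reproduces its predictions exactly.
#'
#' @param model an `ldpm`.
#' @param path archive directory (created if missing).
#' @return `save_ldpm()` returns `path` invisibly; `load_ldpm()` returns
#'   the restored `ldpm`.
#' @export
save_ldpm <- function(model, path) {
  stopifnot(inherits(model, "ldpm"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    class = "ldpm",
    config = unclass(model$config),
    hyperparameters = model$hyperparameters,
    feature_scaler = model$feature_scaler,
    training_domain = model$training_domain,
    geometry = unclass(model$geometry))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(model$pixel_models, file.path(path, "pixel_models.rds"))
  invisible(path)
}

#' @rdname save_ldpm
#' @export
load_ldpm <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  config <- meta$config
  config$grid <- lapply(config$grid, as.numeric)
  class(config) <- "ldpm_config"
  geometry <- meta$geometry
  class(geometry) <- "ldp_geometry"
  structure(
    list(pixel_models = readRDS(file.path(path, "pixel_models.rds")),
         feature_scaler = lapply(meta$feature_scaler, unlist),
         training_domain = lapply(meta$training_domain, as.numeric),
         geometry = geometry,
         config = config,
         hyperparameters = as.list(meta$hyperparameters)),
    class = "ldpm")
}
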