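#' Growth rates from a growth curve by finite differences
#'
#' Instantaneous growth rates (OD730 per hour) at the curve's own time
#' points: central differences at interior points, one-sided differences at
#' the two ends. This pairs each rate with the LDP prevailing at the same
#' time point, which is how rate labels are built for the growth-rate model.
#'
#' @param times sampling times in hours, strictly increasing, length >= 3.
#' @param od730 optical density readings, same length, all > 0.
#' @return Data frame with columns `time` and `rate` (OD730 h-1).
#' @export
compute_growth_rates <- function(times, od730) {
  if (inherits(times, "growth_curve")) {
    od730 <- times$od730
    times <- times$time
  }
  stopifnot(length(times) == length(od730), all(od730 > 0))
  if (length(times) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  n <- length(times)
  rate <- numeric(n)
  rate[1] <- (od730[2] - od730[1]) / (times[2] - times[1])
  rate[n] <- (od730[n] - od730[n - 1]) / (times[n] - times[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    rate[i] <- (od730[i + 1] - od730[i - 1]) / (times[i + 1] - times[i - 1])
  }
  data.frame(time = times, rate = rate)
}

#' Feature configuration for the growth-rate model
#'
#' Which LDP-derived features feed the growth-rate regressor: the full
#' 720-pixel vector (gray values scaled to `[0, 1]`, row-major), optionally
#' followed by two summary statistics — mean gray value (scaled to
#' `[0, 1]`) and the dark-area fraction. Both blocks are on by default.
#'
#' @param pixels include the full pixel vector.
#' @param summaries append mean gray value and dark-area fraction.
#' @param dark_threshold gray threshold for the dark-area summary.
#' @return A `grm_feature_config` object.
#' @export
grm_feature_config <- function(pixels = TRUE, summaries = TRUE,
                               dark_threshold = 25.5) {
  if (!pixels && !summaries) stop("at least one feature block is required", call. = FALSE)
  structure(list(pixels = pixels, summaries = summaries,
                 dark_threshold = dark_threshold),
            class = "grm_feature_config")
}

#' Extract a feature vector from an LDP
#'
#' @param ldp gray-value matrix.
#' @param feature_config a [grm_feature_config()].
#' @return Numeric vector with all entries in `[0, 1]`.
#' @export
extract_features <- function(ldp, feature_config = grm_feature_config()) {
  stopifnot(is.matrix(ldp), inherits(feature_config, "grm_feature_config"))
  out <- numeric(0)
  if (feature_config$pixels) out <- c(out, flatten_ldp(ldp) / 255)
  if (feature_config$summaries) {
    out <- c(out, mean(ldp) / 255,
             dark_area_fraction(ldp, feature_config$dark_threshold))
  }
  out
}

#' Training configuration for the growth-rate model
#'
#' SVR hyperparameters for the LDP-features-to-growth-rate regressor, with
#' a seeded cross-validated grid over cost, epsilon and the RBF width
#' (features live on a low-dimensional manifold inside the 722-dimensional
#' feature space, so the kernel width matters and is tuned rather than left
#' at the 1/n-features default).
#'
#' @param kernel SVR kernel.
#' @param cost,epsilon,gamma values used when `grid = NULL`.
#' @param grid named list of vectors `cost`, `epsilon`, `gamma` for the
#'   cross-validated search; `NULL` disables tuning.
#' @param cv_folds folds for the grid search (>= 2).
#' @param seed integer seed fixing fold assignment.
#' @param use_predicted_ldps when assembling training data with
#'   [build_grm_training_data()], use LDPM-predicted LDPs as the feature
#'   source (the deployment condition); `FALSE` switches to the generator's
#'   raw LDPs for ablation.
#' @return A `grm_config` object.
#' @export
grm_config <- function(kernel = "radial",
                       cost = 100,
                       epsilon = 0.01,
                       gamma = 0.05,
                       grid = list(cost = c(1, 10, 100),
                                   epsilon = c(0.01, 0.05),
                                   gamma = c(0.005, 0.05, 0.5)),
                       cv_folds = 3L,
                       seed = 1L,
                       use_predicted_ldps = TRUE) {
  assert_scalar_num(cost, "cost", 0, allow_zero = FALSE)
  assert_scalar_num(epsilon, "epsilon", 0, allow_zero = FALSE)
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("`cv_folds` must be >= 2", call. = FALSE)
  structure(
    list(kernel = kernel, cost = cost, epsilon = epsilon, gamma = gamma,
         grid = grid, cv_folds = cv_folds, seed = as.integer(seed),
         use_predicted_ldps = isTRUE(use_predicted_ldps)),
    class = "grm_config")
}

#' Train the growth-rate model
#'
#' Fits a support-vector regressor mapping LDP feature vectors to
#' instantaneous growth rates (OD730 h-1). Features and labels must be
#' aligned at identical time points (see [build_grm_training_data()]).
#'
#' @param features numeric matrix, one row per sample.
#' @param rates numeric vector of growth-rate labels, one per row.
#' @param config a [grm_config()].
#' @param feature_config the [grm_feature_config()] the rows were built
#'   with (stored for prediction-time consistency).
#' @return An object of class `grm`.
#' @export
train_grm <- function(features, rates, config = grm_config(),
                      feature_config = grm_feature_config()) {
  stopifnot(is.matrix(features), inherits(config, "grm_config"))
  if (nrow(features) != length(rates)) {
    stop("`features` and `rates` lengths differ", call. = FALSE)
  }
  if (nrow(features) < 10L) stop("need at least 10 training pairs", call. = FALSE)
  hp <- list(cost = config$cost, epsilon = config$epsilon, gamma = config$gamma)
  if (!is.null(config$grid)) {
    hp <- tune_grm_grid(features, rates, config)
  }
  fit <- fit_pixel_svr(features, rates, config$kernel,
                       hp$cost, hp$epsilon, hp$gamma)
  structure(
    list(model = fit,
         feature_config = feature_config,
         hyperparameters = hp,
         rate_range = range(rates),
         n_train = nrow(features)),
    class = "grm")
}

tune_grm_grid <- function(features, rates, config) {
  folds <- cv_fold_ids(nrow(features), config$cv_folds, config$seed)
  combos <- expand.grid(cost = config$grid$cost,
                        epsilon = config$grid$epsilon,
                        gamma = config$grid$gamma,
                        KEEP.OUT.ATTRS = FALSE)
  errs <- vapply(seq_len(nrow(combos)), function(i) {
    mse <- 0
    for (k in seq_len(config$cv_folds)) {
      tr <- folds != k
      m <- fit_pixel_svr(features[tr, , drop = FALSE], rates[tr],
                         config$kernel, combos$cost[i], combos$epsilon[i],
                         combos$gamma[i])
      pred <- predict_pixel_svr(m, features[!tr, , drop = FALSE])
      mse <- mse + mean((rates[!tr] - pred)^2)
    }
    mse
  }, numeric(1))
  best <- which.min(errs)
  list(cost = combos$cost[best], epsilon = combos$epsilon[best],
       gamma = combos$gamma[best])
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: SVR on %d training pairs (cost %g, epsilon %g, gamma %g)\n",
              x$n_train, x$hyperparameters$cost, x$hyperparameters$epsilon,
              x$hyperparameters$gamma))
  cat(sprintf("  trained rate range: [%.4f, %.4f] OD730/h\n",
              x$rate_range[1], x$rate_range[2]))
  invisible(x)
}

#' Predict a growth rate from an LDP
#'
#' Negative raw outputs are floored at zero (cells do not shrink under
#' shading in this model); the number of floored predictions is reported
#' through the `n_floored` attribute.
#'
#' @param model a `grm`.
#' @param ldp a gray-value matrix, or a precomputed feature matrix via
#'   `features =`.
#' @param features optional feature matrix (rows = samples) overriding
#'   `ldp`.
#' @return Numeric rate(s), OD730 h-1, with attribute `n_floored`.
#' @export
predict_growth_rate <- function(model, ldp = NULL, features = NULL) {
  stopifnot(inherits(model, "grm"))
  if (is.null(features)) {
    stopifnot(is.matrix(ldp))
    features <- matrix(extract_features(ldp, model$feature_config), nrow = 1)
  }
  raw <- predict_pixel_svr(model$model, features)
  out <- pmax(0, raw)
  attr(out, "n_floored") <- sum(raw < 0)
  out
}

#' Evaluate a growth-rate model
#'
#' @param model a `grm`.
#' @param features held-out feature matrix.
#' @param rates held-out rate labels.
#' @return R-squared of predicted vs observed rates (after flooring), with
#'   attribute `n_floored`.
#' @export
evaluate_grm <- function(model, features, rates) {
  stopifnot(nrow(features) == length(rates))
  pred <- predict_growth_rate(model, features = features)
  out <- r_squared(rates, as.numeric(pred))
  attr(out, "n_floored") <- attr(pred, "n_floored")
  out
}

#' Build aligned GRM training data from growth curves
#'
#' Mirrors the growth-rate model's training construction: rates are
#' computed from each growth curve by finite differences, and the feature
#' at every time point comes from the LDP for the prevailing light
#' intensity and the concentration implied by the current OD. By default
#' the LDPs are produced by the trained LDPM (the deployment condition:
#' the growth-rate model sees the same surrogate LDPs it will see inside
#' the simulator); with `config$use_predicted_ldps = FALSE` the generator's
#' noise-free LDPs are used instead (ablation).
#'
#' @param ldpm a trained [train_ldpm()] model.
#' @param curves list of `growth_curve` data frames (from
#'   [simulate_true_growth()] or measurements).
#' @param schedules list of [light_schedule()]s, one per curve.
#' @param config a [grm_config()].
#' @param feature_config a [grm_feature_config()].
#' @param geometry,optics generator settings used when
#'   `use_predicted_ldps = FALSE`.
#' @param calibration a [biomass_calibration()].
#' @return List with `features` (matrix), `rates`, `times`, `curve_id`.
#' @export
build_grm_training_data <- function(ldpm, curves, schedules,
                                    config = grm_config(),
                                    feature_config = grm_feature_config(),
                                    geometry = pbr_geometry(),
                                    optics = optical_params(),
                                    calibration = biomass_calibration()) {
  stopifnot(length(curves) == length(schedules))
  quiet_optics <- optics
  quiet_optics$noise_sd <- 0
  rows <- list()
  for (ci in seq_along(curves)) {
    curve <- curves[[ci]]
    sched <- schedules[[ci]]
    fd <- compute_growth_rates(curve$time, curve$od730)
    seg <- lapply(curve$time, schedule_segment, schedule = sched)
    rows[[ci]] <- data.frame(
      curve_id = ci,
      time = fd$time,
      rate = fd$rate,
      intensity = vapply(seg, `[[`, numeric(1), "intensity"),
      n_sources = vapply(seg, `[[`, integer(1), "n_sources"),
      concentration = curve$od730 * calibration$dcw_per_od)
  }
  tab <- do.call(rbind, rows)
  ldp_at <- function(i) {
    if (config$use_predicted_ldps) return(NULL)  # handled in batch below
    geom_i <- geometry
    geom_i$n_sources <- tab$n_sources[i]
    field <- generate_irradiance_field(tab$intensity[i], tab$concentration[i],
                                       geom_i, quiet_optics)
    irradiance_to_gsv(field, quiet_optics)
  }
  if (config$use_predicted_ldps) {
    # one batched pass through the 720 pixel regressors for all time points
    raw <- predict_ldpm_matrix(ldpm, tab$intensity, tab$concentration)
    preds <- round(clip(raw, 0, 255))
    feats <- t(vapply(seq_len(nrow(tab)), function(i) {
      extract_features(unflatten_ldp(preds[i, ], ldpm$geometry$rows,
                                     ldpm$geometry$cols),
                       feature_config)
    }, numeric(feature_length(feature_config, ldpm$geometry))))
  } else {
    feats <- t(vapply(seq_len(nrow(tab)), function(i) {
      extract_features(ldp_at(i), feature_config)
    }, numeric(feature_length(feature_config, geometry))))
  }
  list(features = feats,
       rates = tab$rate,
       times = tab$time,
       curve_id = tab$curve_id)
}

feature_length <- function(feature_config, geometry) {
  (if (feature_config$pixels) geometry$rows * geometry$cols else 0L) +
    (if (feature_config$summaries) 2L else 0L)
}
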