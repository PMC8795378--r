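#' Generate a synthetic irradiance field
#'
#' Forward model for the light field inside a culture: incident photons decay
#' exponentially with optical path length (Beer-Lambert, with the biomass
#' concentration setting the attenuation rate), and a Gaussian blur across
#' columns emulates lateral scattering. For two opposing light sources the
#' field is the superposition of the front field and its row-reversed mirror
#' (each source contributing `intensity`); any clipping to the displayable
#' range happens later, at grayscale conversion.
#'
#' @param intensity incident light intensity per source, umol m-2 s-1.
#' @param concentration biomass concentration, g/L.
#' @param geometry an [ldp_geometry()].
#' @param optics an [optical_params()].
#' @return A `rows x cols` numeric matrix of irradiances (umol m-2 s-1),
#'   row 1 nearest the light source.
#' @examples
#' f <- generate_irradiance_field(100, 0, pbr_geometry(), optical_params())
#' all(f == 100)  # no biomass, no attenuation
#' @export
generate_irradiance_field <- function(intensity, concentration,
                                      geometry = pbr_geometry(),
                                      optics = optical_params()) {
  assert_scalar_num(intensity, "intensity", 0)
  assert_scalar_num(concentration, "concentration", 0)
  stopifnot(inherits(geometry, "ldp_geometry"), inherits(optics, "optical_params"))
  depths <- row_depths(geometry)
  front <- intensity * exp(-optics$extinction_coeff * concentration * depths)
  profile <- if (geometry$n_sources == 2L) front + rev(front) else front
  field <- matrix(profile, nrow = geometry$rows, ncol = geometry$cols)
  blur_columns(field, optics$lateral_blur_sigma)
}

# Gaussian blur along the column axis with reflective padding. A no-op on
# column-constant fields (the default source is laterally uniform).
blur_columns <- function(field, sigma) {
  if (sigma <= 0) return(field)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  ncol_f <- ncol(field)
  idx <- seq_len(ncol_f)
  pad <- c(rev(idx)[-1][seq_len(half)], idx, rev(idx)[-ncol_f][seq_len(half)])
  padded <- field[, pad, drop = FALSE]
  out <- field
  for (j in idx) {
    block <- padded[, j:(j + 2L * half), drop = FALSE]
    out[, j] <- as.vector(block %*% kern)
  }
  out
}

#' Convert an irradiance field to a grayscale LDP
#'
#' Applies the virtual camera's linear response: gray value =
#' `gsv_slope * irradiance + gsv_intercept` plus Gaussian sensor noise,
#' clipped to `[0, gsv_max]` and rounded to integers. Noise is drawn from
#' the current RNG stream, so seeding the session (or using
#' [generate_ldp_dataset()]) makes the output reproducible.
#'
#' @param field non-negative numeric matrix of irradiances.
#' @param optics an [optical_params()]; set `noise_sd = 0` for a noise-free
#'   conversion.
#' @return Integer matrix of gray values in `[0, 255]`, same shape as
#'   `field`.
#' @export
irradiance_to_gsv <- function(field, optics = optical_params()) {
  stopifnot(is.matrix(field), all(field >= 0), inherits(optics, "optical_params"))
  gsv <- optics$gsv_slope * field + optics$gsv_intercept
  if (optics$noise_sd > 0) {
    gsv <- gsv + stats::rnorm(length(gsv), sd = optics$noise_sd)
  }
  out <- round(clip(gsv, 0, optics$gsv_max))
  storage.mode(out) <- "integer"
  out
}

#' Cell concentrations of the packaged calibration corpus
#'
#' The 23 biomass concentrations (g/L) spanned by the reference LDP training
#' corpus, from 0.11973 to 3.6777 g/L.
#'
#' @return Numeric vector of length 23.
#' @export
calibration_concentrations <- function() {
  c(0.11973, 0.21294, 0.40872, 0.45162, 0.54405, 0.62712, 0.74256, 0.82056,
    0.90948, 0.96915, 1.10604, 1.2246, 1.3026, 1.3923, 1.443, 1.5444,
    1.7901, 1.9188, 2.0241, 2.3556, 2.535, 2.9601, 3.6777)
}

#' Generate a dataset of synthetic LDPs
#'
#' Produces one grayscale LDP per (intensity, concentration) combination on
#' the full Cartesian grid of the supplied condition vectors. The whole
#' dataset is reproducible byte-for-byte from `seed`.
#'
#' @param intensities incident intensities per source, umol m-2 s-1.
#' @param concentrations biomass concentrations, g/L (e.g.
#'   [calibration_concentrations()]).
#' @param geometry an [ldp_geometry()].
#' @param optics an [optical_params()].
#' @param seed integer seed controlling the sensor noise.
#' @return An object of class `ldp_dataset`: a list with parallel vectors
#'   `intensity`, `concentration`, a list `ldps` of integer LDP matrices,
#'   and the `seed`, `geometry` and `optics` used.
#' @export
generate_ldp_dataset <- function(intensities, concentrations,
                                 geometry = pbr_geometry(),
                                 optics = optical_params(),
                                 seed = 1L) {
  if (length(intensities) == 0L || length(concentrations) == 0L) {
    stop("condition lists must be non-empty", call. = FALSE)
  }
  stopifnot(all(intensities >= 0), all(concentrations >= 0))
  grid <- expand.grid(intensity = intensities, concentration = concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ldps <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    field <- generate_irradiance_field(grid$intensity[i], grid$concentration[i],
                                       geometry, optics)
    ldps[[i]] <- irradiance_to_gsv(field, optics)
  }
  structure(
    list(intensity = grid$intensity, concentration = grid$concentration,
         ldps = ldps, seed = as.integer(seed), geometry = geometry,
         optics = optics),
    class = "ldp_dataset")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ldp_dataset <- function(x, ...) {
  cat(sprintf("ldp_dataset: %d LDPs (%d x %d), %d intensities x %d concentrations, seed %d\n",
              length(x$ldps), x$geometry$rows, x$geometry$cols,
              length(unique(x$intensity)), length(unique(x$concentration)),
              x$seed))
  invisible(x)
}

#' Split an LDP dataset into training and test records
#'
#' Random record-level split, seeded for reproducibility.
#'
#' @param dataset an `ldp_dataset`.
#' @param test_fraction fraction of records held out (default 0.2).
#' @param seed integer seed for the split.
#' @return List with elements `train` and `test`, both `ldp_dataset`s.
#' @export
split_ldp_dataset <- function(dataset, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "ldp_dataset"),
            test_fraction > 0, test_fraction < 1)
  n <- length(dataset$ldps)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_test <- max(1L, round(test_fraction * n))
  test_idx <- sort(sample.int(n, n_test))
  subset_ds <- function(idx) {
    out <- dataset
    out$intensity <- dataset$intensity[idx]
    out$concentration <- dataset$concentration[idx]
    out$ldps <- dataset$ldps[idx]
    out
  }
  list(train = subset_ds(setdiff(seq_len(n), test_idx)),
       test = subset_ds(test_idx))
}

#' Simulate ground-truth growth under a light schedule
#'
#' Forward-Euler integration of the generator's true rate law: at each step
#' the noise-free light field for the current concentration is computed, and
#' the optical density grows at
#' `mu_max * OD * f(mean irradiance) * g(dark fraction)` (see
#' [true_growth_model()]). This is the oracle the surrogate pipeline is
#' judged against.
#'
#' @param initial_od starting optical density (OD730), > 0.
#' @param schedule a [light_schedule()] covering the horizon.
#' @param model a [true_growth_model()].
#' @param geometry,optics vessel geometry and optics (noise is ignored here;
#'   the truth integrator always uses the noise-free field).
#' @param dt Euler step in hours (default 0.5).
#' @param calibration a [biomass_calibration()] linking OD to g/L.
#' @return A `growth_curve`: data frame with columns `time` (h), `od730`,
#'   `rate` (OD h-1) and `dark_fraction`.
#' @export
simulate_true_growth <- function(initial_od, schedule,
                                 model = true_growth_model(),
                                 geometry = pbr_geometry(),
                                 optics = optical_params(),
                                 dt = 0.5,
                                 calibration = biomass_calibration()) {
  assert_scalar_num(initial_od, "initial_od", 0, allow_zero = FALSE)
  assert_scalar_num(dt, "dt", 0, allow_zero = FALSE)
  stopifnot(inherits(model, "true_growth_model"))
  quiet_optics <- optics
  quiet_optics$noise_sd <- 0
  horizon <- schedule_horizon(schedule)
  times <- seq(0, horizon, by = dt)
  n <- length(times)
  od <- numeric(n); rate <- numeric(n); dark <- numeric(n)
  od[1] <- initial_od
  for (i in seq_len(n)) {
    seg <- schedule_segment(schedule, times[i])
    geom_i <- geometry
    geom_i$n_sources <- seg$n_sources
    conc <- od[i] * calibration$dcw_per_od
    field <- generate_irradiance_field(seg$intensity, conc, geom_i, quiet_optics)
    gsv <- irradiance_to_gsv(field, quiet_optics)
    dark[i] <- dark_area_fraction(gsv)
    r <- model$mu_max * od[i] * light_response(model, mean(field)) *
      shading_penalty(model, dark[i])
    rate[i] <- max(0, r)
    if (i < n) od[i + 1] <- od[i] + rate[i] * dt
  }
  structure(
    data.frame(time = times, od730 = od, rate = rate, dark_fraction = dark),
    class = c("growth_curve", "data.frame"))
}

#' Write / read an LDP dataset
#'
#' `write_ldp_dataset()` serialises a dataset either as a single flat CSV
#' (columns `intensity`, `concentration`, `px_000` ... `px_719` in row-major
#' order, row 0 nearest the source) or as one 8-bit grayscale PNG per LDP
#' plus a manifest CSV (`intensity_umol_m2_s`, `concentration_g_L`,
#' `png_path`). `read_ldp_dataset()` reads either layout back.
#'
#' @param dataset an `ldp_dataset`.
#' @param path for `format = "csv"` the CSV file path; for `format = "png"`
#'   a directory (created if missing).
#' @param format `"csv"` (default) or `"png"`.
#' @return `write_ldp_dataset()` returns `path` invisibly;
#'   `read_ldp_dataset()` returns an `ldp_dataset` (with default geometry /
#'   optics attached, since the files carry only conditions and pixels).
#' @export
write_ldp_dataset <- function(dataset, path, format = c("csv", "png")) {
  stopifnot(inherits(dataset, "ldp_dataset"))
  format <- match.arg(format)
  if (format == "csv") {
    px <- t(vapply(dataset$ldps, flatten_ldp,
                   numeric(dataset$geometry$rows * dataset$geometry$cols)))
    colnames(px) <- sprintf("px_%03d", seq_len(ncol(px)) - 1L)
    df <- cbind(data.frame(intensity = dataset$intensity,
                           concentration = dataset$concentration), px)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    rel <- sprintf("ldp_I%g_C%g_%03d.png", dataset$intensity,
                   dataset$concentration, seq_along(dataset$ldps))
    for (i in seq_along(dataset$ldps)) {
      write_ldp_png(dataset$ldps[[i]], file.path(path, rel[i]))
    }
    manifest <- data.frame(intensity_umol_m2_s = dataset$intensity,
                           concentration_g_L = dataset$concentration,
                           png_path = rel)
    utils::write.csv(manifest, file.path(path, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ldp_dataset
#' @param rows,cols grid shape used to refold flat pixel rows.
#' @export
read_ldp_dataset <- function(path, rows = 18L, cols = 40L) {
  if (dir.exists(path)) {
    manifest <- utils::read.csv(file.path(path, "manifest.csv"))
    ldps <- lapply(file.path(path, manifest$png_path), read_ldp_png)
    intensity <- manifest$intensity_umol_m2_s
    concentration <- manifest$concentration_g_L
  } else {
    df <- utils::read.csv(path)
    px_cols <- grep("^px_", names(df))
    stopifnot(length(px_cols) == rows * cols)
    ldps <- lapply(seq_len(nrow(df)), function(i) {
      m <- unflatten_ldp(as.numeric(df[i, px_cols]), rows, cols)
      storage.mode(m) <- "integer"
      m
    })
    intensity <- df$intensity
    concentration <- df$concentration
  }
  structure(
    list(intensity = intensity, concentration = concentration, ldps = ldps,
         seed = NA_integer_,
         geometry = ldp_geometry(depth_m = 0.05, rows = rows, cols = cols),
         optics = optical_params()),
    class = "ldp_dataset")
}
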