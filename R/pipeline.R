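#' Study presets for the surrogate pipeline
#'
#' Canonical condition grids and cultivation settings for the two vessel
#' presets:
#'
#' * `"pbr_double"` — flat-panel photobioreactor lit from two opposite
#'   sides at 574 umol m-2 s-1 per panel, harvested every 24 h; training
#'   grid 15 intensities x 15 concentrations spanning 100-800
#'   umol m-2 s-1 and 0.1-3.9 g/L.
#' * `"pond"` — 20 cm raceway pond under the stepped Texas-summer daylight
#'   program; training grid 16 intensities x 14 concentrations spanning
#'   0-1500 umol m-2 s-1 and 0.05-2.6 g/L.
#'
#' Growth-curve initial ODs span thin inocula to clearly shaded cultures so
#' the growth-rate model sees both sides of the productivity peak.
#'
#' @param preset `"pbr_double"` or `"pond"`.
#' @return List with `geometry`, `optics`, `intensities`, `concentrations`,
#'   `schedule`, `init_ods`, `plan`.
#' @export
pipeline_preset <- function(preset = c("pbr_double", "pond")) {
  preset <- match.arg(preset)
  if (preset == "pbr_double") {
    list(geometry = pbr_geometry(n_sources = 2L),
         optics = optical_params(),
         intensities = seq(100, 800, length.out = 15),
         concentrations = seq(0.1, 3.9, length.out = 15),
         schedule = constant_light(574, 24, n_sources = 2L),
         init_ods = c(0.6, 1, 1.5, 2.3, 3, 4, 5, 6.5),
         plan = sac_plan(harvest_interval = 24, reset_od = 2.3, n_cycles = 7L))
  } else {
    list(geometry = pond_geometry(),
         optics = pond_optics(),
         intensities = seq(0, 1500, length.out = 16),
         concentrations = seq(0.05, 2.6, length.out = 14),
         schedule = texas_summer_schedule(24),
         init_ods = dcw_to_od(c(0.1, 0.2, 0.3, 0.45, 0.6, 0.8, 1.1, 1.5)),
         plan = sac_plan(harvest_interval = 24, reset_od = dcw_to_od(0.4),
                         n_cycles = 7L))
  }
}

#' Fit the full surrogate pipeline for a preset
#'
#' End-to-end training workflow: generate a synthetic LDP dataset on the
#' preset's condition grid, train the pixel-wise LDP prediction model on
#' all records, simulate ground-truth growth curves from the preset's
#' initial ODs under its light schedule, assemble aligned feature/rate
#' pairs (features from LDPM-predicted LDPs), and train the growth-rate
#' model.
#'
#' @param preset `"pbr_double"` or `"pond"` (see [pipeline_preset()]).
#' @param seed integer seed driving dataset noise, model tuning folds and
#'   any other randomness.
#' @param noise_sd grayscale noise of the training dataset; `NULL` keeps
#'   the preset default.
#' @param truth_dt Euler step (h) of the ground-truth integrator used for
#'   the growth curves.
#' @return List with `ldpm`, `grm`, `dataset`, `curves`, `preset` (the
#'   [pipeline_preset()] list) and `seed`.
#' @export
fit_surrogate_pipeline <- function(preset = c("pbr_double", "pond"),
                                   seed = 1L, noise_sd = NULL,
                                   truth_dt = 0.5) {
  ps <- pipeline_preset(preset)
  if (!is.null(noise_sd)) ps$optics$noise_sd <- noise_sd
  seed <- as.integer(seed)
  dataset <- generate_ldp_dataset(ps$intensities, ps$concentrations,
                                  ps$geometry, ps$optics, seed = seed)
  ldpm <- train_ldpm(dataset, ldpm_config(seed = seed))
  curves <- lapply(ps$init_ods, simulate_true_growth, schedule = ps$schedule,
                   model = true_growth_model(), geometry = ps$geometry,
                   optics = ps$optics, dt = truth_dt)
  td <- build_grm_training_data(ldpm, curves,
                                rep(list(ps$schedule), length(curves)),
                                config = grm_config(seed = seed),
                                geometry = ps$geometry, optics = ps$optics)
  grm <- train_grm(td$features, td$rates, grm_config(seed = seed))
  list(ldpm = ldpm, grm = grm, dataset = dataset, curves = curves,
       training_pairs = td, preset = ps, seed = seed)
}
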