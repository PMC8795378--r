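#' Optical parameters of the synthetic light-field generator
#'
#' Bundles the constants that control how the generator turns an incident
#' photon flux and a cell concentration into a grayscale light distribution
#' pattern (LDP): Beer-Lambert extinction along the light path, a lateral
#' Gaussian blur standing in for scattering, additive sensor noise, and the
#' linear irradiance-to-grayscale response of the virtual camera.
#'
#' The grayscale response is deliberately linear with saturation at
#' `gsv_max`, emulating the near-linear grayscale/irradiance relationship
#' that makes 8-bit images usable as quantitative light maps.
#'
#' @param extinction_coeff attenuation rate per (g/L) of biomass per metre of
#'   light path. Default 40: at 3.7 g/L a 5 cm path transmits well under 0.1%
#'   of incident light, so dense cultures go dark at depth.
#' @param lateral_blur_sigma standard deviation, in pixels, of the Gaussian
#'   blur applied across columns (scattering proxy).
#' @param noise_sd standard deviation of additive grayscale noise, in gray
#'   units. Default 3: small relative to the 0-255 signal range.
#' @param gsv_slope gray units per (umol m-2 s-1) of irradiance.
#' @param gsv_intercept gray units at zero irradiance (sensor offset).
#' @param gsv_max saturation gray value, at most 255.
#' @return An object of class `optical_params`.
#' @seealso [pond_optics()] for the top-lit pond preset.
#' @export
optical_params <- function(extinction_coeff = 40,
                           lateral_blur_sigma = 1,
                           noise_sd = 3,
                           gsv_slope = 0.3,
                           gsv_intercept = 2,
                           gsv_max = 255) {
  assert_scalar_num(extinction_coeff, "extinction_coeff", 0, allow_zero = FALSE)
  assert_scalar_num(lateral_blur_sigma, "lateral_blur_sigma", 0)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(gsv_slope, "gsv_slope", 0, allow_zero = FALSE)
  assert_scalar_num(gsv_intercept, "gsv_intercept")
  assert_scalar_num(gsv_max, "gsv_max", 0, allow_zero = FALSE)
  if (gsv_max > 255) stop("`gsv_max` cannot exceed 255", call. = FALSE)
  structure(
    list(extinction_coeff = extinction_coeff,
         lateral_blur_sigma = lateral_blur_sigma,
         noise_sd = noise_sd,
         gsv_slope = gsv_slope,
         gsv_intercept = gsv_intercept,
         gsv_max = gsv_max),
    class = "optical_params")
}

#' @rdname optical_params
#' @details `pond_optics()` halves the camera gain (`gsv_slope = 0.15`) so
#'   that the much higher surface irradiance of outdoor-style light programs
#'   (up to 1500 umol m-2 s-1) stays below grayscale saturation.
#' @export
pond_optics <- function(extinction_coeff = 40,
                        lateral_blur_sigma = 1,
                        noise_sd = 3) {
  optical_params(extinction_coeff = extinction_coeff,
                 lateral_blur_sigma = lateral_blur_sigma,
                 noise_sd = noise_sd,
                 gsv_slope = 0.15,
                 gsv_intercept = 2,
                 gsv_max = 255)
}

#' Vessel geometry for LDP generation
#'
#' Describes the imaged cross-section of a culture vessel as an 18 x 40 grid,
#' with rows running along the light path (row 1 nearest the light source)
#' and columns parallel to the light panel.
#'
#' @param depth_m length of the light path in metres.
#' @param width_m lateral extent of the imaged section in metres (used for
#'   areal-productivity conversions, not for attenuation).
#' @param rows,cols grid dimensions; the standard compressed LDP is 18 x 40.
#' @param n_sources 1 for single-sided illumination, 2 for two opposing
#'   light panels.
#' @return An object of class `ldp_geometry`.
#' @export
ldp_geometry <- function(depth_m, width_m = 0.10, rows = 18L, cols = 40L,
                         n_sources = 1L) {
  assert_scalar_num(depth_m, "depth_m", 0, allow_zero = FALSE)
  assert_scalar_num(width_m, "width_m", 0, allow_zero = FALSE)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("grid dimensions must be positive", call. = FALSE)
  n_sources <- as.integer(n_sources)
  if (!n_sources %in% c(1L, 2L)) stop("`n_sources` must be 1 or 2", call. = FALSE)
  structure(
    list(depth_m = depth_m, width_m = width_m, rows = rows, cols = cols,
         n_sources = n_sources),
    class = "ldp_geometry")
}

#' @rdname ldp_geometry
#' @details `pbr_geometry()` is a flat-panel photobioreactor with a 5 cm
#'   front-to-back light path; `pond_geometry()` is a raceway pond with a
#'   20 cm top-to-bottom path and top illumination.
#' @export
pbr_geometry <- function(n_sources = 1L) {
  ldp_geometry(depth_m = 0.05, width_m = 0.10, n_sources = n_sources)
}

#' @rdname ldp_geometry
#' @export
pond_geometry <- function() {
  ldp_geometry(depth_m = 0.20, width_m = 0.15, n_sources = 1L)
}

# Depth (metres from the light source) of each row's midpoint.
row_depths <- function(geometry) {
  (seq_len(geometry$rows) - 0.5) / geometry$rows * geometry$depth_m
}

#' Ground-truth growth-rate law for the synthetic generator
#'
#' The generator's "true" physiology: specific growth rate is
#' `mu_max * f(I) * g(d)` where `f` is a Monod saturation in the
#' culture-mean irradiance `I` and `g` penalises mutual shading through the
#' dark-area fraction `d` of the (noise-free) LDP. `g` equals 1 below
#' `dark_penalty_onset`, then ramps linearly down, reaching
#' `1 - penalty_strength` at `dark_penalty_full` (zero for the default
#' strength of 1). The default onset/full values of 0.431 and 0.65 place
#' the growth-rate peak and collapse where dense cyanobacterial cultures
#' show them.
#'
#' @param mu_max maximum specific growth rate, per hour.
#' @param light_half_sat irradiance at half-maximal growth, umol m-2 s-1.
#' @param dark_penalty_onset dark-area fraction at which shading starts to
#'   inhibit growth.
#' @param dark_penalty_full dark-area fraction at which the penalty is fully
#'   developed.
#' @param penalty_strength fraction of growth removed at
#'   `dark_penalty_full`; 1 means growth stops entirely.
#' @return An object of class `true_growth_model`.
#' @export
true_growth_model <- function(mu_max = 0.1,
                              light_half_sat = 150,
                              dark_penalty_onset = 0.431,
                              dark_penalty_full = 0.65,
                              penalty_strength = 1) {
  assert_scalar_num(mu_max, "mu_max", 0)
  assert_scalar_num(light_half_sat, "light_half_sat", 0, allow_zero = FALSE)
  assert_scalar_num(penalty_strength, "penalty_strength", 0)
  if (!(dark_penalty_onset >= 0 && dark_penalty_onset < dark_penalty_full &&
        dark_penalty_full <= 1)) {
    stop("need 0 <= dark_penalty_onset < dark_penalty_full <= 1", call. = FALSE)
  }
  structure(
    list(mu_max = mu_max, light_half_sat = light_half_sat,
         dark_penalty_onset = dark_penalty_onset,
         dark_penalty_full = dark_penalty_full,
         penalty_strength = penalty_strength),
    class = "true_growth_model")
}

# Shading penalty g(dark fraction) in [0, 1].
shading_penalty <- function(model, dark_fraction) {
  ramp <- (dark_fraction - model$dark_penalty_onset) /
    (model$dark_penalty_full - model$dark_penalty_onset)
  clip(1 - model$penalty_strength * clip(ramp, 0, 1), 0, 1)
}

# Monod light response f(mean irradiance) in [0, 1).
light_response <- function(model, mean_irradiance) {
  mean_irradiance / (mean_irradiance + model$light_half_sat)
}
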