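#' Optical density / dry cell weight calibration
#'
#' Linear calibration linking OD730 to dry cell weight (DCW). The default,
#' 0.39 g DCW per litre per OD730 unit, is the standard pre-established
#' calibration for fast-growing Synechococcus cultures.
#'
#' @param dcw_per_od grams DCW per litre per OD730 unit.
#' @return A `biomass_calibration` object.
#' @export
biomass_calibration <- function(dcw_per_od = 0.39) {
  assert_scalar_num(dcw_per_od, "dcw_per_od", 0, allow_zero = FALSE)
  structure(list(dcw_per_od = dcw_per_od), class = "biomass_calibration")
}

#' Convert between OD730 and dry cell weight
#'
#' @param od optical density at 730 nm (non-negative).
#' @param dcw dry cell weight, g/L (non-negative).
#' @param calibration a [biomass_calibration()].
#' @return Dry cell weight in g/L, or OD730 for the inverse.
#' @examples
#' od_to_dcw(1.0)   # 0.39 g/L
#' od_to_dcw(357)   # 139.23 g/L -> prints as 139.2
#' @export
od_to_dcw <- function(od, calibration = biomass_calibration()) {
  if (any(od < 0)) stop("`od` must be non-negative", call. = FALSE)
  od * calibration$dcw_per_od
}

#' @rdname od_to_dcw
#' @export
dcw_to_od <- function(dcw, calibration = biomass_calibration()) {
  if (any(dcw < 0)) stop("`dcw` must be non-negative", call. = FALSE)
  dcw / calibration$dcw_per_od
}

#' Solids content of a harvested slurry
#'
#' Mass percent of dry solids in the settled output, on a nominal slurry
#' density of 1000 g/L. Reported values are conventionally rounded to the
#' nearest whole percent (e.g. a 139.2 g/L bottom concentration reports as
#' 14% solids).
#'
#' @param dcw_g_per_l dry cell weight of the slurry, g/L.
#' @param slurry_density_g_per_l slurry density basis, g/L (default 1000).
#' @return Solids content in percent (unrounded).
#' @export
solids_content <- function(dcw_g_per_l, slurry_density_g_per_l = 1000) {
  if (any(dcw_g_per_l < 0)) stop("`dcw_g_per_l` must be non-negative", call. = FALSE)
  100 * dcw_g_per_l / slurry_density_g_per_l
}

#' Convert volumetric to areal productivity (and back)
#'
#' A pond of depth `d` metres holds `1000 * d` litres under each square
#' metre, so g/L/day times `1000 * d` gives g/m2/day.
#'
#' @param rate_g_per_l_per_day volumetric productivity, g/L/day.
#' @param rate_g_per_m2_per_day areal productivity, g/m2/day.
#' @param geometry a geometry with a `depth_m` field (e.g.
#'   [pond_geometry()]).
#' @return The converted productivity.
#' @export
volumetric_to_areal <- function(rate_g_per_l_per_day, geometry = pond_geometry()) {
  rate_g_per_l_per_day * geometry$depth_m * 1000
}

#' @rdname volumetric_to_areal
#' @export
areal_to_volumetric <- function(rate_g_per_m2_per_day, geometry = pond_geometry()) {
  rate_g_per_m2_per_day / (geometry$depth_m * 1000)
}

#' Cumulative yield from daily values
#'
#' Total yield over a run, computed by adding the per-day yields together.
#'
#' @param daily_values numeric vector of per-day yields (may be empty).
#' @return Their sum (0 for an empty vector).
#' @export
cumulative_yield <- function(daily_values) {
  if (length(daily_values) == 0L) return(0)
  sum(daily_values)
}

#' Biochemical composition of the cell
#'
#' Mass fractions of protein, carbohydrate and lipid, with the residual
#' balance treated as water-like material, plus component densities. The
#' defaults describe a glycogen-rich Synechococcus cell: 42.8% protein
#' (1300 kg/m3), 36.5% carbohydrate (1500 kg/m3), 11.2% lipid (860 kg/m3),
#' residual at water density.
#'
#' @param protein_frac,carb_frac,lipid_frac mass fractions, summing to at
#'   most 1.
#' @param densities named numeric vector of component densities in kg/m3
#'   (`protein`, `carbohydrate`, `lipid`, `water`).
#' @return A `cell_composition` object.
#' @export
cell_composition <- function(protein_frac = 0.428, carb_frac = 0.365,
                             lipid_frac = 0.112,
                             densities = c(protein = 1300, carbohydrate = 1500,
                                           lipid = 860, water = 1000)) {
  fr <- c(protein_frac, carb_frac, lipid_frac)
  if (any(fr < 0) || sum(fr) > 1 + 1e-9) {
    stop("fractions must be non-negative and sum to at most 1", call. = FALSE)
  }
  stopifnot(all(c("protein", "carbohydrate", "lipid", "water") %in% names(densities)))
  structure(
    list(protein_frac = protein_frac, carb_frac = carb_frac,
         lipid_frac = lipid_frac, residual_frac = 1 - sum(fr),
         densities = densities),
    class = "cell_composition")
}

#' Mass-fraction-weighted cell density
#'
#' Average density of a cell given its composition, with the residual
#' fraction at water density. Cells denser than the medium settle under
#' gravity; this is the density that enters [stokes_velocity()].
#'
#' @param composition a [cell_composition()].
#' @return Density in kg/m3.
#' @examples
#' composite_density(cell_composition())  # ~1295 kg/m3
#' @export
composite_density <- function(composition = cell_composition()) {
  stopifnot(inherits(composition, "cell_composition"))
  d <- composition$densities
  composition$protein_frac * d[["protein"]] +
    composition$carb_frac * d[["carbohydrate"]] +
    composition$lipid_frac * d[["lipid"]] +
    composition$residual_frac * d[["water"]]
}

#' Stokes settling velocity
#'
#' Terminal velocity of a small sphere in a viscous fluid:
#' `v = 2 (rho_p - rho_f) g r^2 / (9 mu)`. Positive values settle,
#' negative values float. Sedimentation speed grows with the square of the
#' particle radius, which is why cell aggregation is so effective at
#' enabling gravity harvest.
#'
#' @param radius_m particle radius in metres (> 0).
#' @param particle_density particle density, kg/m3.
#' @param fluid_density fluid density, kg/m3 (default 1000, water).
#' @param viscosity_pa_s dynamic viscosity, Pa s (> 0; default 1e-3, water).
#' @param g gravitational acceleration, m/s2.
#' @return Velocity in m/s.
#' @export
stokes_velocity <- function(radius_m, particle_density, fluid_density = 1000,
                            viscosity_pa_s = 1e-3, g = 9.81) {
  assert_scalar_num(radius_m, "radius_m", 0, allow_zero = FALSE)
  assert_scalar_num(viscosity_pa_s, "viscosity_pa_s", 0, allow_zero = FALSE)
  2 * (particle_density - fluid_density) * g * radius_m^2 / (9 * viscosity_pa_s)
}

#' Settled fraction from a surface-concentration time course
#'
#' Sedimentation efficiency over time, measured as the relative drop of the
#' surface cell concentration: `1 - surface(t) / surface(0)`, clipped to
#' `[0, 1]`.
#'
#' @param times sampling times (increasing).
#' @param surface surface concentrations (OD or g/L), same length;
#'   `surface[1]` is the initial value.
#' @return Data frame with columns `time` and `settled_fraction`.
#' @export
settled_fraction <- function(times, surface) {
  stopifnot(length(times) == length(surface), length(times) >= 1,
            all(diff(times) > 0), surface[1] > 0)
  data.frame(time = times,
             settled_fraction = clip(1 - surface / surface[1], 0, 1))
}

#' Aggregated-cell fraction from hemocytometer counts
#'
#' Fraction of engineered cells found in aggregates, estimated by comparing
#' free (unaggregated) cell counts against a non-aggregating reference
#' culture at matched concentration.
#'
#' @param free_count_engineered free cells counted in the aggregating strain.
#' @param free_count_reference free cells counted in the reference strain.
#' @return Fraction in `[0, 1]`.
#' @examples
#' aggregation_fraction(9, 100)  # 0.91
#' @export
aggregation_fraction <- function(free_count_engineered, free_count_reference) {
  stopifnot(free_count_reference > 0, free_count_engineered >= 0)
  clip((free_count_reference - free_count_engineered) / free_count_reference,
       0, 1)
}

#' Hydrocarbon-adherent fraction from a BATH assay
#'
#' Cell-surface hydrophobicity measured by bacterial adherence to
#' hydrocarbon: after phase separation, the chlorophyll fluorescence left in
#' the aqueous phase counts the cells that did not adhere, so the adherent
#' fraction is `1 - sample / control`.
#'
#' @param fluorescence_sample aqueous-phase fluorescence after hydrocarbon
#'   exposure.
#' @param fluorescence_control fluorescence of the untreated control.
#' @return Fraction in `[0, 1]`.
#' @export
bath_adherence <- function(fluorescence_sample, fluorescence_control) {
  stopifnot(fluorescence_control > 0, fluorescence_sample >= 0)
  clip(1 - fluorescence_sample / fluorescence_control, 0, 1)
}

#' Normalized product productivity
#'
#' Product formation rate per unit biomass: total titre divided by run
#' length and by the mean culture density over the run (time-averaged OD).
#'
#' @param total_mg_per_l total product titre, mg/L.
#' @param days run length in days (> 0).
#' @param mean_od time-averaged OD730 over the run (> 0).
#' @return Productivity in mg/L/day per OD730 unit.
#' @export
normalized_productivity <- function(total_mg_per_l, days, mean_od) {
  assert_scalar_num(days, "days", 0, allow_zero = FALSE)
  assert_scalar_num(mean_od, "mean_od", 0, allow_zero = FALSE)
  stopifnot(total_mg_per_l >= 0)
  total_mg_per_l / (days * mean_od)
}

#' Turbidity-to-OD calibration hook
#'
#' Inline turbidity probes report attenuation units (AU); growth analysis
#' needs OD730. The mapping is instrument-specific, so it is exposed as a
#' pluggable linear map with user-supplied constants.
#'
#' @param au turbidity readings in attenuation units.
#' @param slope,intercept calibration constants (OD730 per AU, and offset).
#' @return OD730 values.
#' @export
turbidity_to_od <- function(au, slope, intercept = 0) {
  slope * au + intercept
}
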