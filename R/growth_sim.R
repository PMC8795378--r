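#' Piecewise-constant light schedule
#'
#' A schedule is a set of contiguous, non-overlapping segments covering the
#' whole horizon, each with an intensity per light source and a number of
#' sources (1 or 2).
#'
#' @param start_h,end_h segment boundaries in hours.
#' @param intensity intensity per source for each segment, umol m-2 s-1.
#' @param n_sources 1 or 2 per segment (recycled).
#' @return A `light_schedule` data frame.
#' @export
light_schedule <- function(start_h, end_h, intensity, n_sources = 1L) {
  df <- data.frame(start_h = start_h, end_h = end_h, intensity = intensity,
                   n_sources = as.integer(n_sources))
  df <- df[order(df$start_h), , drop = FALSE]
  if (any(df$end_h <= df$start_h)) stop("empty or inverted segment", call. = FALSE)
  if (any(df$intensity < 0)) stop("negative intensity", call. = FALSE)
  if (!all(df$n_sources %in% c(1L, 2L))) stop("`n_sources` must be 1 or 2", call. = FALSE)
  if (nrow(df) > 1L && any(abs(df$start_h[-1] - df$end_h[-nrow(df)]) > 1e-9)) {
    stop("schedule segments must be contiguous (no gaps or overlaps)", call. = FALSE)
  }
  class(df) <- c("light_schedule", "data.frame")
  df
}

#' @rdname light_schedule
#' @param hours horizon of the constant schedule.
#' @export
constant_light <- function(intensity, hours = 24, n_sources = 1L) {
  light_schedule(0, hours, intensity, n_sources)
}

#' Texas-summer pond light program
#'
#' The stepped daylight program used to mimic a Texas summer day over a
#' pond: 400, 800, 1300 umol m-2 s-1 for 1 h each, 1500 for 10 h, then
#' 1300, 800, 400 for 1 h each (13 h of light plus a 3 h ramp = 16 h),
#' followed by darkness to the end of the `horizon`.
#'
#' @param horizon total schedule length in hours (default 24).
#' @return A `light_schedule`.
#' @export
texas_summer_schedule <- function(horizon = 24) {
  stopifnot(horizon >= 16)
  ints <- c(400, 800, 1300, 1500, 1300, 800, 400)
  durs <- c(1, 1, 1, 10, 1, 1, 1)
  ends <- cumsum(durs)
  starts <- c(0, ends[-length(ends)])
  if (horizon > 16) {
    starts <- c(starts, 16); ends <- c(ends, horizon); ints <- c(ints, 0)
  }
  light_schedule(starts, ends, ints, n_sources = 1L)
}

#' Schedule accessors
#'
#' `schedule_horizon()` is the total covered time; `schedule_intensity()`
#' the per-source intensity prevailing at time `t` (segments are closed on
#' the left, and the final segment includes its right endpoint).
#'
#' @param schedule a [light_schedule()].
#' @param t time in hours.
#' @export
schedule_horizon <- function(schedule) max(schedule$end_h)

#' @rdname schedule_horizon
#' @export
schedule_intensity <- function(schedule, t) {
  vapply(t, function(tt) schedule_segment(schedule, tt)$intensity, numeric(1))
}

# Segment active at time t (segments are [start, end); the final segment is
# closed on the right).
schedule_segment <- function(schedule, t) {
  i <- which(t >= schedule$start_h - 1e-9 & t < schedule$end_h - 1e-9)
  if (length(i) == 0L) {
    if (abs(t - schedule_horizon(schedule)) < 1e-9) i <- nrow(schedule)
    else stop(sprintf("time %g h outside schedule", t), call. = FALSE)
  }
  schedule[i[1], ]
}

#' Read / write light schedules as CSV
#'
#' Columns `start_h`, `end_h`, `intensity`, `n_sources`.
#'
#' @param schedule a [light_schedule()].
#' @param path CSV path.
#' @export
write_light_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_light_schedule
#' @export
read_light_schedule <- function(path) {
  df <- utils::read.csv(path)
  light_schedule(df$start_h, df$end_h, df$intensity, df$n_sources)
}

#' Coupled surrogate growth simulation
#'
#' The iterative simulator that couples the two surrogates: at every time
#' step the current OD fixes the cell concentration, the LDPM predicts the
#' LDP for the prevailing light, features are extracted, the GRM predicts
#' the instantaneous growth rate, and the OD advances one forward-Euler
#' step. Dark-area fraction and extrapolation flags are recorded at each
#' step.
#'
#' @param ldpm a trained [train_ldpm()] model.
#' @param grm a trained [train_grm()] model.
#' @param initial_od starting OD730 (> 0).
#' @param schedule a [light_schedule()]; `dt` must divide every segment
#'   boundary.
#' @param dt Euler step in hours (default 1).
#' @param calibration a [biomass_calibration()].
#' @return A `simulation_result` data frame with columns `time`, `od730`,
#'   `rate`, `dark_fraction`, `extrapolated`.
#' @export
simulate_growth <- function(ldpm, grm, initial_od, schedule, dt = 1,
                            calibration = biomass_calibration()) {
  stopifnot(inherits(ldpm, "ldpm"), inherits(grm, "grm"))
  assert_scalar_num(initial_od, "initial_od", 0, allow_zero = FALSE)
  assert_scalar_num(dt, "dt", 0, allow_zero = FALSE)
  bounds <- unique(c(schedule$start_h, schedule$end_h))
  if (any(abs(bounds / dt - round(bounds / dt)) > 1e-9)) {
    stop("`dt` must divide all schedule segment boundaries", call. = FALSE)
  }
  horizon <- schedule_horizon(schedule)
  times <- seq(0, horizon, by = dt)
  n <- length(times)
  od <- numeric(n); rate <- numeric(n); dark <- numeric(n); extra <- logical(n)
  od[1] <- initial_od
  for (i in seq_len(n)) {
    seg <- schedule_segment(schedule, times[i])
    conc <- od[i] * calibration$dcw_per_od
    ldp <- predict_ldp(ldpm, seg$intensity, conc, warn = FALSE)
    extra[i] <- attr(ldp, "extrapolated")
    dark[i] <- dark_area_fraction(ldp, grm$feature_config$dark_threshold)
    rate[i] <- as.numeric(predict_growth_rate(grm, ldp))
    if (i < n) od[i + 1] <- od[i] + rate[i] * dt
  }
  out <- data.frame(time = times, od730 = od, rate = rate,
                    dark_fraction = dark, extrapolated = extra)
  class(out) <- c("simulation_result", "data.frame")
  if (any(extra)) {
    attr(out, "extrapolation_warning") <-
      sprintf("%d of %d steps outside the LDPM training domain", sum(extra), n)
  }
  out
}

#' Semi-continuous cultivation plan
#'
#' @param harvest_interval hours between harvests (default 24).
#' @param reset_od OD730 the culture is reset to after each harvest
#'   (default 2.3, the photobioreactor optimum; use
#'   `dcw_to_od(0.4)` for the 0.4 g/L pond inoculum).
#' @param n_cycles number of harvest cycles.
#' @return A `sac_plan` object.
#' @export
sac_plan <- function(harvest_interval = 24, reset_od = 2.3, n_cycles = 7L) {
  assert_scalar_num(harvest_interval, "harvest_interval", 0, allow_zero = FALSE)
  assert_scalar_num(reset_od, "reset_od", 0, allow_zero = FALSE)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("`n_cycles` must be >= 1", call. = FALSE)
  structure(list(harvest_interval = harvest_interval, reset_od = reset_od,
                 n_cycles = n_cycles),
            class = "sac_plan")
}

#' Simulate semi-continuous cultivation
#'
#' Each cycle starts from `reset_od`, runs under `schedule` (which must
#' cover one harvest interval) for `harvest_interval` hours, and is then
#' harvested back down to `reset_od`, with feeding assumed to keep
#' nutrients non-limiting. Per-cycle volumetric productivity is
#' `(od_end - reset_od) * dcw_per_od * (24 / harvest_interval)` g/L/day;
#' in pond mode an areal productivity (g/m2/day) is reported as well.
#' Because every cycle restarts from the same state under the same
#' schedule, cycles are identical by construction.
#'
#' @param ldpm,grm trained surrogate models.
#' @param plan a [sac_plan()].
#' @param schedule a [light_schedule()] covering one harvest interval.
#' @param dt Euler step in hours.
#' @param calibration a [biomass_calibration()].
#' @param geometry optional pond geometry; when supplied, areal
#'   productivities are included.
#' @return A `productivity_report`: list with `per_cycle` (data frame:
#'   `cycle`, `od_end`, `productivity_g_l_day`, optionally
#'   `productivity_g_m2_day`), `cumulative_yield_g_l`, the `plan`, and the
#'   single-cycle `simulation` trace.
#' @export
simulate_sac <- function(ldpm, grm, plan, schedule, dt = 1,
                         calibration = biomass_calibration(),
                         geometry = NULL) {
  stopifnot(inherits(plan, "sac_plan"))
  if (abs(schedule_horizon(schedule) - plan$harvest_interval) > 1e-9) {
    stop("schedule must cover exactly one harvest interval", call. = FALSE)
  }
  sim <- simulate_growth(ldpm, grm, plan$reset_od, schedule, dt, calibration)
  od_end <- sim$od730[nrow(sim)]
  prod <- (od_end - plan$reset_od) * calibration$dcw_per_od *
    (24 / plan$harvest_interval)
  if (prod < 0) {
    warning("culture shrank below the reset OD; negative productivity reported",
            call. = FALSE)
  }
  per_cycle <- data.frame(cycle = seq_len(plan$n_cycles),
                          od_end = od_end,
                          productivity_g_l_day = prod)
  if (!is.null(geometry)) {
    per_cycle$productivity_g_m2_day <- volumetric_to_areal(prod, geometry)
  }
  cycle_days <- plan$harvest_interval / 24
  structure(
    list(per_cycle = per_cycle,
         cumulative_yield_g_l = cumulative_yield(per_cycle$productivity_g_l_day *
                                                   cycle_days),
         plan = plan,
         simulation = sim),
    class = "productivity_report")
}

#' @export
print.productivity_report <- function(x, ...) {
  cat(sprintf("productivity_report: %d cycles of %g h from OD %g\n",
              x$plan$n_cycles, x$plan$harvest_interval, x$plan$reset_od))
  cat(sprintf("  per-cycle productivity: %.3f g/L/day; cumulative yield: %.2f g/L\n",
              x$per_cycle$productivity_g_l_day[1], x$cumulative_yield_g_l))
  invisible(x)
}

#' Optimize the SAC inoculum concentration
#'
#' Evaluates one harvest cycle per candidate initial OD with the coupled
#' surrogate simulator and returns the candidate with the highest
#' volumetric productivity. Ties are broken toward the lower OD (a thinner
#' inoculum is cheaper and better lit).
#'
#' @param ldpm,grm trained surrogate models.
#' @param candidate_ods numeric vector of >= 3 candidate initial OD730
#'   values.
#' @param plan a [sac_plan()] (its `reset_od` is overridden per candidate).
#' @param schedule a [light_schedule()] covering one harvest interval.
#' @param dt,calibration passed to [simulate_growth()].
#' @return List with `best_od` and `productivity_curve` (data frame:
#'   `initial_od`, `productivity_g_l_day`).
#' @export
optimize_initial_od <- function(ldpm, grm, candidate_ods, plan, schedule,
                                dt = 1, calibration = biomass_calibration()) {
  if (length(candidate_ods) < 3L) stop("need at least 3 candidates", call. = FALSE)
  prods <- vapply(candidate_ods, function(od0) {
    p <- plan
    p$reset_od <- od0
    p$n_cycles <- 1L
    rep <- simulate_sac(ldpm, grm, p, schedule, dt, calibration)
    rep$per_cycle$productivity_g_l_day[1]
  }, numeric(1))
  curve <- data.frame(initial_od = candidate_ods,
                      productivity_g_l_day = prods)
  curve <- curve[order(curve$initial_od), , drop = FALSE]
  rownames(curve) <- NULL
  best <- curve$initial_od[curve$productivity_g_l_day >=
                             max(curve$productivity_g_l_day) - 1e-12]
  list(best_od = min(best), productivity_curve = curve)
}

#' Brute-force inoculum optimum of the generator truth
#'
#' Independent oracle for the optimizer: evaluates one harvest cycle per
#' candidate directly with [simulate_true_growth()] (no surrogates) and
#' returns the argmax, ties toward the lower OD.
#'
#' @param candidate_ods candidate initial OD730 values.
#' @param plan a [sac_plan()].
#' @param schedule a [light_schedule()] covering one interval.
#' @param model,geometry,optics generator truth settings.
#' @param dt Euler step for the truth integrator.
#' @param calibration a [biomass_calibration()].
#' @return List with `best_od` and `productivity_curve`.
#' @export
true_optimal_od <- function(candidate_ods, plan, schedule,
                            model = true_growth_model(),
                            geometry = pbr_geometry(),
                            optics = optical_params(),
                            dt = 0.5,
                            calibration = biomass_calibration()) {
  prods <- vapply(candidate_ods, function(od0) {
    curve <- simulate_true_growth(od0, schedule, model, geometry, optics, dt,
                                  calibration)
    (curve$od730[nrow(curve)] - od0) * calibration$dcw_per_od *
      (24 / plan$harvest_interval)
  }, numeric(1))
  curve <- data.frame(initial_od = candidate_ods,
                      productivity_g_l_day = prods)
  curve <- curve[order(curve$initial_od), , drop = FALSE]
  rownames(curve) <- NULL
  best <- curve$initial_od[curve$productivity_g_l_day >=
                             max(curve$productivity_g_l_day) - 1e-12]
  list(best_od = min(best), productivity_curve = curve)
}

#' Fed-batch simulation
#'
#' Runs the coupled simulator over a multi-day horizon with no harvest
#' resets (feeding only), and reports the daily productivity series. As the
#' culture thickens, the dark-area fraction grows and daily productivity
#' declines — the behaviour semi-continuous operation is designed to avoid.
#'
#' @param ldpm,grm trained surrogate models.
#' @param initial_od starting OD730.
#' @param schedule a [light_schedule()] covering one day; it is repeated
#'   for `days` days.
#' @param days horizon in days.
#' @param dt,calibration passed to [simulate_growth()].
#' @return List with `simulation` (the full `simulation_result`) and
#'   `daily` (data frame: `day`, `od_start`, `od_end`,
#'   `productivity_g_l_day`).
#' @export
simulate_fed_batch <- function(ldpm, grm, initial_od, schedule, days = 7,
                               dt = 1, calibration = biomass_calibration()) {
  day_len <- schedule_horizon(schedule)
  sims <- vector("list", days)
  od0 <- initial_od
  for (d in seq_len(days)) {
    sim <- simulate_growth(ldpm, grm, od0, schedule, dt, calibration)
    sim$time <- sim$time + (d - 1) * day_len
    sims[[d]] <- if (d == 1) sim else sim[-1, , drop = FALSE]
    od0 <- sim$od730[nrow(sim)]
  }
  full <- do.call(rbind, sims)
  class(full) <- c("simulation_result", "data.frame")
  marks <- seq(0, days) * day_len
  od_marks <- full$od730[round(marks / dt) + 1L]
  daily <- data.frame(day = seq_len(days),
                      od_start = od_marks[-length(od_marks)],
                      od_end = od_marks[-1])
  daily$productivity_g_l_day <- (daily$od_end - daily$od_start) *
    calibration$dcw_per_od * (24 / day_len)
  list(simulation = full, daily = daily)
}

#' Plot a growth simulation
#'
#' Writes (or draws) a two-panel figure: OD trajectory and dark-area
#' fraction over time.
#'
#' @param result a `simulation_result` or `growth_curve`.
#' @param path optional PNG path; when supplied the figure is written there.
#' @param width,height device size in pixels.
#' @return `path` (or `NULL`) invisibly.
#' @export
plot_simulation <- function(result, path = NULL, width = 900, height = 500) {
  draw <- function() {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    plot(result$time, result$od730, type = "l", lwd = 2, col = "forestgreen",
         xlab = "time (h)", ylab = "OD730", main = "growth")
    plot(result$time, result$dark_fraction, type = "l", lwd = 2,
         col = "gray30", ylim = c(0, 1),
         xlab = "time (h)", ylab = "dark-area fraction", main = "shading")
    graphics::abline(h = c(0.431, 0.65), lty = 2, col = "tomato")
  }
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
    return(invisible(path))
  }
  draw()
  invisible(NULL)
}
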