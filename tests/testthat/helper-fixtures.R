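# Shared fixtures, built once per test run and cached. The heavyweight
# surrogate pipelines (used by the acceptance checks and by the shape /
# consistency property tests) are built lazily so cheap test files stay
# cheap.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, builder(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

# Small noise-free dataset + untuned LDPM for fast unit tests.
tiny_ldpm_setup <- function() {
  fixture("tiny_ldpm", function() {
    optics <- optical_params(noise_sd = 0)
    ds <- generate_ldp_dataset(seq(100, 700, length.out = 8),
                               seq(0.1, 3.5, length.out = 8),
                               pbr_geometry(), optics, seed = 71)
    sp <- split_ldp_dataset(ds, 0.2, seed = 71)
    cfg <- ldpm_config(grid = NULL, cost = 100, epsilon = 0.01, seed = 71)
    list(dataset = ds, split = sp, model = train_ldpm(sp$train, cfg),
         optics = optics)
  })
}

# Full photobioreactor pipeline (double 574 umol m-2 s-1), default noise.
pbr_pipeline <- function() {
  fixture("pbr_pipeline", function() fit_surrogate_pipeline("pbr_double", seed = 1L))
}

# Full pond pipeline (Texas-summer program), default noise.
pond_pipeline <- function() {
  fixture("pond_pipeline", function() fit_surrogate_pipeline("pond", seed = 1L))
}

# Noise-free single-source benchmark: 20x20 condition grid for the LDP
# surrogate plus constant-light truth curves for the growth-rate surrogate.
noise_free_setup <- function() {
  fixture("noise_free", function() {
    optics <- optical_params(noise_sd = 0)
    geom <- pbr_geometry()
    ds <- generate_ldp_dataset(seq(80, 800, length.out = 20),
                               seq(0.1, 3.9, length.out = 20),
                               geom, optics, seed = 101)
    sp <- split_ldp_dataset(ds, 0.2, seed = 101)
    ldpm <- train_ldpm(sp$train, ldpm_config(seed = 101))
    grids <- expand.grid(intensity = c(107, 300, 500, 714),
                         init_od = c(0.5, 2, 4.5))
    schedules <- lapply(grids$intensity, constant_light, hours = 24)
    curves <- Map(function(od0, sched) {
      simulate_true_growth(od0, sched, geometry = geom, optics = optics)
    }, grids$init_od, schedules)
    td <- build_grm_training_data(ldpm, curves, schedules,
                                  geometry = geom, optics = optics)
    set.seed(101)
    test_idx <- sample(nrow(td$features), round(0.2 * nrow(td$features)))
    grm <- train_grm(td$features[-test_idx, ], td$rates[-test_idx],
                     grm_config(seed = 101))
    grm_r2 <- evaluate_grm(grm, td$features[test_idx, ], td$rates[test_idx])
    list(dataset = ds, split = sp, ldpm = ldpm, grm = grm,
         grm_r2 = as.numeric(grm_r2), training = td, geometry = geom,
         optics = optics)
  })
}

# A growth-rate model stub that always returns `k` OD/h, bypassing the SVR.
constant_rate_grm <- function(k) {
  structure(
    list(model = list(constant = k),
         feature_config = grm_feature_config(),
         hyperparameters = list(cost = NA, epsilon = NA, gamma = NA),
         rate_range = c(k, k), n_train = 0L),
    class = "grm")
}
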