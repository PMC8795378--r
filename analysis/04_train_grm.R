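#!/usr/bin/env Rscript
# Build the growth-rate model: finite-difference rate labels from
# ground-truth growth curves, features from LDPM-predicted LDPs at the
# same time points, then a held-out evaluation.

suppressPackageStartupMessages(library(ldpsim))
dir.create("results", showWarnings = FALSE)
seed <- 101L

optics <- optical_params(noise_sd = 0)
geom <- pbr_geometry()
ds <- generate_ldp_dataset(seq(80, 800, length.out = 20),
                           seq(0.1, 3.9, length.out = 20),
                           geom, optics, seed = seed)
ldpm <- train_ldpm(ds, ldpm_config(seed = seed))

grid <- expand.grid(intensity = c(107, 300, 500, 714),
                    init_od = c(0.5, 2, 4.5))
schedules <- lapply(grid$intensity, constant_light, hours = 24)
curves <- Map(function(od0, sched) {
  simulate_true_growth(od0, sched, geometry = geom, optics = optics)
}, grid$init_od, schedules)

td <- build_grm_training_data(ldpm, curves, schedules,
                              geometry = geom, optics = optics)
set.seed(seed)
test_idx <- sample(nrow(td$features), round(0.2 * nrow(td$features)))
grm <- train_grm(td$features[-test_idx, ], td$rates[-test_idx],
                 grm_config(seed = seed))
r2 <- evaluate_grm(grm, td$features[test_idx, ], td$rates[test_idx])
cat(sprintf("growth-rate model: %d training pairs, held-out R2 = %.4f\n",
            nrow(td$features) - length(test_idx), as.numeric(r2)))

pairs <- data.frame(curve = td$curve_id, time_h = td$times,
                    rate_od_per_h = td$rates,
                    mean_gsv = td$features[, 721],
                    dark_fraction = td$features[, 722])
write.csv(pairs, "results/grm_training_pairs.csv", row.names = FALSE)

# where does the rate peak sit, in dark-area terms?
peak <- pairs[which.max(pairs$rate_od_per_h), ]
cat(sprintf("peak training rate %.3f OD/h at dark fraction %.2f\n",
            peak$rate_od_per_h, peak$dark_fraction))
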