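#!/usr/bin/env Rscript
# Use the coupled surrogates to pick the optimal inoculum concentration for
# semi-continuous cultivation, for the double-lit photobioreactor and the
# Texas-summer pond, and check each against the brute-force ground truth.

suppressPackageStartupMessages(library(ldpsim))
dir.create("results", showWarnings = FALSE)

## photobioreactor
fx <- fit_surrogate_pipeline("pbr_double", seed = 1L)
ps <- fx$preset
cand <- seq(1, 6, by = 1)
opt <- optimize_initial_od(fx$ldpm, fx$grm, cand, ps$plan, ps$schedule)
tru <- true_optimal_od(seq(1, 6, by = 0.1), ps$plan, ps$schedule,
                       true_growth_model(), ps$geometry, ps$optics)
cat(sprintf("PBR: surrogate optimum OD %.1f, truth optimum OD %.1f\n",
            opt$best_od, tru$best_od))
write.csv(merge(opt$productivity_curve, tru$productivity_curve,
                by = "initial_od", all = TRUE,
                suffixes = c("_surrogate", "_truth")),
          "results/optimum_od_pbr.csv", row.names = FALSE)

## pond
fp <- fit_surrogate_pipeline("pond", seed = 1L)
pp <- fp$preset
cand_p <- dcw_to_od(seq(0.1, 1.2, by = 0.1))
opt_p <- optimize_initial_od(fp$ldpm, fp$grm, cand_p, pp$plan, pp$schedule)
tru_p <- true_optimal_od(dcw_to_od(seq(0.1, 1.2, by = 0.02)), pp$plan,
                         pp$schedule, true_growth_model(), pp$geometry,
                         pp$optics)
cat(sprintf("pond: surrogate optimum %.2f g/L, truth optimum %.2f g/L\n",
            od_to_dcw(opt_p$best_od), od_to_dcw(tru_p$best_od)))
best <- opt_p$productivity_curve$productivity_g_l_day[
  opt_p$productivity_curve$initial_od == opt_p$best_od]
cat(sprintf("pond productivity at the optimum: %.2f g/L/day = %.1f g/m2/day\n",
            best, volumetric_to_areal(best, pp$geometry)))
write.csv(merge(opt_p$productivity_curve, tru_p$productivity_curve,
                by = "initial_od", all = TRUE,
                suffixes = c("_surrogate", "_truth")),
          "results/optimum_od_pond.csv", row.names = FALSE)
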