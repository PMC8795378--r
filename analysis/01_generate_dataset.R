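#!/usr/bin/env Rscript
# Generate the synthetic LDP training corpora for both vessel presets and
# summarise their optical structure (depth decay, dark-area trends).

suppressPackageStartupMessages(library(ldpsim))
dir.create("results", showWarnings = FALSE)
seed <- 1L

ps <- pipeline_preset("pbr_double")
pbr_ds <- generate_ldp_dataset(ps$intensities, ps$concentrations,
                               ps$geometry, ps$optics, seed = seed)
write_ldp_dataset(pbr_ds, "results/ldp_dataset_pbr.csv")

pp <- pipeline_preset("pond")
pond_ds <- generate_ldp_dataset(pp$intensities, pp$concentrations,
                                pp$geometry, pp$optics, seed = seed)
write_ldp_dataset(pond_ds, "results/ldp_dataset_pond.csv")

# also the 23-concentration calibration-style corpus at five intensities
cal_ds <- generate_ldp_dataset(c(107, 250, 400, 574, 714),
                               calibration_concentrations(),
                               pbr_geometry(), optical_params(), seed = seed)
write_ldp_dataset(cal_ds, "results/ldp_dataset_calibration.csv")

dark <- data.frame(
  intensity = cal_ds$intensity,
  concentration = cal_ds$concentration,
  dark_fraction = vapply(cal_ds$ldps, dark_area_fraction, numeric(1)))
write.csv(dark, "results/dark_fraction_by_condition.csv", row.names = FALSE)

cat(sprintf("PBR corpus: %d LDPs; pond corpus: %d LDPs; calibration corpus: %d LDPs\n",
            length(pbr_ds$ldps), length(pond_ds$ldps), length(cal_ds$ldps)))
cat(sprintf("dark-area fraction at 574 umol: %.2f (0.12 g/L) -> %.2f (3.68 g/L)\n",
            dark$dark_fraction[dark$intensity == 574][1],
            tail(dark$dark_fraction[dark$intensity == 574], 1)))
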