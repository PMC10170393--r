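#!/usr/bin/env Rscript
# Stage 3: per-otter biotic and spatial covariates — scaled mass index
# (SMA exponent fitted on the simulated reference population), Jenks
# natural-breaks size classes per sex, meteorological season, river
# distance to the coast and primary water habitat.

library(spraintR)

seed <- 20260922L
dir.create("results", showWarnings = FALSE)
study <- simulate_study(sim_config(seed, n_otters = 300))
meta <- study$world$meta

params <- fit_smi_params(meta$mass_g, meta$length_mm)
cat("SMA scaling exponent b =", round(params$b_sma, 3),
    "; reference length L0 =", round(params$L0, 1), "mm\n")

breaks <- fit_size_breaks(meta$length_mm, meta$sex)
for (s in names(breaks))
  cat("Size breaks (", s, "): small < ", breaks[[s]][1],
      " mm <= medium <= ", breaks[[s]][2], " mm < large\n", sep = "")

cov <- build_covariates(meta, study$world$spatial)
print(table(cov$size_class, cov$sex))
print(table(cov$habitat))
cat("Coast distance: median", round(median(cov$coast_distance), 1),
    "km; coastal (0 km):", sum(cov$coast_distance == 0), "otters\n")

write.csv(cov, "results/covariates.csv", row.names = FALSE)
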