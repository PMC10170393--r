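#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — taxonomy, otter metadata, spatial
# inputs, per-marker read tables with controls, and morphological records —
# and write every input table under results/data/.
#
# The study conditions: 300 otters over a west-east longitudinal gradient,
# two markers with complementary coverage (16S vertebrate-leaning, COI
# invertebrate-leaning with family-level ceilings for some vertebrates),
# low-level contamination reaching negatives and unused tag combinations,
# and sparser, coarser morphological detections.

library(spraintR)

seed <- 20260922L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed, n_otters = 300)
study <- simulate_study(cfg)

write_taxonomy(study$world$tree, "results/data/taxonomy.tsv")
write.csv(study$world$meta, "results/data/otter_metadata.csv",
          row.names = FALSE)
write.csv(study$world$spatial, "results/data/spatial_inputs.csv",
          row.names = FALSE)
write_read_table(study$reads16S$table, "results/data/reads_16S.csv")
write_read_table(study$readsCOI$table, "results/data/reads_COI.csv")
write.csv(as.data.frame(study$morph), "results/data/morphology.csv",
          row.names = FALSE)
write.csv(study$truth$taxa, "results/data/truth_taxa.csv", row.names = FALSE)

cat("Simulated", nrow(study$world$meta), "otters;",
    nrow(study$truth$taxa), "true prey presences across",
    ncol(study$truth$group_matrix), "prey groups.\n")
cat("16S table:", nrow(study$reads16S$table$counts), "libraries,",
    sum(study$reads16S$table$counts), "reads;",
    nrow(study$reads16S$contamination_cells),
    "contamination-only fecal cells labelled in truth.\n")
cat("Morphological records:", nrow(study$morph), "\n")
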