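#!/usr/bin/env Rscript
# Stage 4: aggregate reconciled taxon presences into prey groups, drop
# rare groups (fewer than three samples), and summarise the diet:
# frequency of occurrence per group and mean prey groups per otter.

library(spraintR)

seed <- 20260922L
dir.create("results", showWarnings = FALSE)
study <- simulate_study(sim_config(seed, n_otters = 300))
tree <- study$world$tree

f16 <- filter_marker(study$reads16S$table)
fcoi <- filter_marker(study$readsCOI$table)
dna <- merge_marker_presences(
  presences_from_matrix(f16$presence, "marker16S"),
  presences_from_matrix(fcoi$presence, "markerCOI"), tree)
combined <- combine_methods(dna, remove_secondary(study$morph), tree,
                            study$categories)
food <- remove_nonfood(combined, tree, filter_config(),
                       categories = study$categories)

gmap <- default_group_map()
m <- records_to_matrix(food)
groups <- map_to_groups(m, gmap, attr(gmap, "unassigned"))
cat("Unassigned coarse presences dropped:",
    attr(groups, "n_unassigned_dropped"), "\n")
groups <- drop_rare_groups(groups, 3)
if (length(attr(groups, "dropped_groups")))
  cat("Rare groups removed:",
      paste(attr(groups, "dropped_groups"), collapse = ", "), "\n")
groups <- groups[rowSums(groups) > 0, , drop = FALSE]

fo <- sort(frequency_of_occurrence(groups), decreasing = TRUE)
cat(sum(groups), "occurrences of", ncol(groups), "prey groups across",
    nrow(groups), "otters; mean",
    round(mean_taxa_per_sample(groups), 2), "groups per otter.\n")
cat("Most frequent prey groups:\n")
print(round(fo, 1))

write.csv(data.frame(group = names(fo), fo_pct = round(unname(fo), 2)),
          "results/frequency_of_occurrence.csv", row.names = FALSE)
write.csv(as.data.frame(groups), "results/group_matrix.csv")
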