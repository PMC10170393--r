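test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_study(sim_config(101, n_otters = 40))
  s2 <- simulate_study(sim_config(101, n_otters = 40))
  expect_identical(s1$world$meta, s2$world$meta)
  expect_identical(s1$truth$group_matrix, s2$truth$group_matrix)
  expect_identical(s1$reads16S$table$counts, s2$reads16S$table$counts)
  expect_identical(s1$morph, s2$morph)
  s3 <- simulate_study(sim_config(102, n_otters = 40))
  expect_false(identical(s1$reads16S$table$counts, s3$reads16S$table$counts))
})

test_that("an empty study still produces well-formed tables", {
  s <- simulate_study(sim_config(5, n_otters = 0))
  expect_identical(nrow(s$world$meta), 0L)
  expect_identical(nrow(s$truth$taxa), 0L)
  expect_identical(sum(s$truth$group_matrix), 0L)
  expect_true(all(c("otter_id", "sex", "length_mm") %in% names(s$world$meta)))
})

test_that("covariate draws match their configured distributions", {
  cfg <- sim_config(7, n_otters = 1000)
  w <- generate_world(cfg)
  # longitude uniform on (-5.5, -0.5): mean within 3 standard errors
  se_lon <- (5 / sqrt(12)) / sqrt(1000)
  expect_lt(abs(mean(w$meta$lon) - (-3)), 3 * se_lon)
  m_len <- w$meta$length_mm[w$meta$sex == "M"]
  expect_lt(abs(mean(m_len) - 1090), 3 * 60 / sqrt(length(m_len)))
})

test_that("null-effect prevalences recover the cloglog intercepts", {
  gp <- spraintR:::default_group_params()
  zero <- setNames(rep(0, length(gp$alpha)), names(gp$alpha))
  cfg <- sim_config(23, n_otters = 2000, beta_lon = zero, beta_coast = zero)
  w <- generate_world(cfg)
  truth <- generate_true_diets(w, cfg)
  for (g in c("stickleback", "eel", "carp")) {
    p_target <- 1 - exp(-exp(gp$alpha[[g]]))
    ci <- qbinom(c(0.005, 0.995), 2000, p_target) / 2000
    expect_gte(mean(truth$group_matrix[, g]), ci[1])
    expect_lte(mean(truth$group_matrix[, g]), ci[2])
  }
})

test_that("a strong longitude effect makes prevalence monotone in quintiles", {
  cfg <- sim_config(29, n_otters = 2000,
                    beta_lon = c(perch = 2.0))
  w <- generate_world(cfg)
  truth <- generate_true_diets(w, cfg)
  qs <- cut(w$meta$lon, quantile(w$meta$lon, 0:5 / 5), include.lowest = TRUE)
  prev <- tapply(truth$group_matrix[, "perch"], qs, mean)
  expect_true(all(diff(prev) > 0))
})

test_that("a practically impossible group never occurs", {
  cfg <- sim_config(31, n_otters = 500, alpha = c(carp = -20))
  truth <- generate_true_diets(generate_world(cfg), cfg)
  expect_identical(sum(truth$group_matrix[, "carp"]), 0L)
})

test_that("zero contamination leaves all negative controls empty", {
  cfg <- sim_config(37, n_otters = 50, contamination_rate = 0,
                    tag_jump_rate = 0)
  w <- generate_world(cfg)
  truth <- generate_true_diets(w, cfg)
  r <- generate_reads(w, truth, cfg, "16S")
  ctrl <- r$table$counts[r$table$roles %in% c("extraction_negative",
                                              "pcr_negative", "unused_tag"), ]
  expect_true(all(ctrl == 0L))
  expect_identical(nrow(r$contamination_cells), 0L)
})

test_that("a lossless 16S channel reproduces the true prey support exactly", {
  cfg <- sim_config(41, n_otters = 60, contamination_rate = 0,
                    tag_jump_rate = 0, detect_16S_vert = 1,
                    detect_16S_invert = 1, host_prob_16S = 0,
                    diatom_prob = 0)
  w <- generate_world(cfg)
  truth <- generate_true_diets(w, cfg)
  r <- generate_reads(w, truth, cfg, "16S")
  pres <- to_presence(r$table)
  truth_pairs <- unique(paste(truth$taxa$otter_id, truth$taxa$taxon))
  got <- which(pres == 1, arr.ind = TRUE)
  got_pairs <- paste(rownames(pres)[got[, 1]], colnames(pres)[got[, 2]])
  expect_setequal(got_pairs, truth_pairs)
})

test_that("per-taxon 16S detection frequency matches the configured rate", {
  cfg <- sim_config(43, n_otters = 1000, contamination_rate = 0,
                    tag_jump_rate = 0, host_prob_16S = 0, diatom_prob = 0)
  w <- generate_world(cfg)
  truth <- generate_true_diets(w, cfg)
  r <- generate_reads(w, truth, cfg, "16S")
  pres <- to_presence(r$table)
  tx <- "Gasterosteus_aculeatus"
  trials <- truth$taxa[truth$taxa$taxon == tx, ]
  n_det <- sum(pres[trials$otter_id, tx])
  ci <- qbinom(c(0.005, 0.995), nrow(trials), cfg$detect[["16S_vert"]])
  expect_gte(n_det, ci[1])
  expect_lte(n_det, ci[2])
})

test_that("morphology honours hard-part probability and the coarsening map", {
  cfg0 <- sim_config(47, n_otters = 50, hard_part_prob = 0,
                     secondary_insect_prob = 0, secondary_mollusk_prob = 0)
  w <- generate_world(cfg0)
  truth <- generate_true_diets(w, cfg0)
  expect_identical(nrow(generate_morphology(w, truth, cfg0)), 0L)

  cfg1 <- sim_config(47, n_otters = 50, hard_part_prob = 1,
                     secondary_insect_prob = 0, secondary_mollusk_prob = 0)
  cfg1$morph_coarsening <- character(0)    # identity map
  m <- generate_morphology(w, truth, cfg1)
  expect_setequal(paste(m$sample_id, m$taxon),
                  unique(paste(truth$taxa$otter_id, truth$taxa$taxon)))
})

test_that("method combination never coarsens below morphology resolution", {
  study <- simulate_study(sim_config(53, n_otters = 80))
  tree <- study$world$tree
  f16 <- filter_marker(study$reads16S$table)
  fcoi <- filter_marker(study$readsCOI$table)
  dna <- merge_marker_presences(presences_from_matrix(f16$presence, "marker16S"),
                                presences_from_matrix(fcoi$presence, "markerCOI"),
                                tree)
  morph <- remove_secondary(study$morph)
  combined <- combine_methods(dna, morph, tree, study$categories)
  anchor <- function(t) {
    if (t %in% names(tree$idx)) t
    else lca(tree, study$categories$members[[t]])
  }
  related <- function(a, b)
    a == b || is_ancestor(a, b, tree) || is_ancestor(b, a, tree)
  # every morphological identification must surface in the combined set on
  # its own lineage at a resolution at least as fine as the morphology
  ok <- vapply(seq_len(nrow(morph)), function(i) {
    s <- morph$sample_id[i]
    m_anchor <- anchor(morph$taxon[i])
    outs <- combined$taxon[combined$sample_id == s]
    out_anchors <- vapply(outs, anchor, character(1))
    comparable <- out_anchors[vapply(out_anchors, related, logical(1),
                                     b = m_anchor)]
    length(comparable) > 0 &&
      max(vapply(comparable, taxon_depth, numeric(1), tree = tree)) >=
        taxon_depth(tree, m_anchor)
  }, logical(1))
  expect_true(all(ok))
})

test_that("read filtering removes almost all labelled contamination", {
  study <- simulate_study(sim_config(59, n_otters = 150))
  for (ch in c("reads16S", "readsCOI")) {
    contam <- study[[ch]]$contamination_cells
    filt <- filter_marker(study[[ch]]$table)
    survived <- filt$presence[cbind(contam$sample_id, contam$taxon)]
    expect_gte(1 - sum(survived) / nrow(contam), 0.95)
  }
})
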