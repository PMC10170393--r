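make_recs <- function(sets, channel) {
  rows <- do.call(rbind, lapply(names(sets), function(s)
    if (length(sets[[s]]))
      data.frame(sample_id = s, taxon = sets[[s]], stringsAsFactors = FALSE)))
  presence_records(rows$sample_id, rows$taxon, channel = channel)
}

test_that("marker merge keeps the finer of two lineage-related detections", {
  tree <- fixture_tree()
  a <- make_recs(list(S = "Salmo_trutta"), "marker16S")
  b <- make_recs(list(S = "Salmonidae"), "markerCOI")
  out <- merge_marker_presences(a, b, tree)
  expect_identical(out$taxon, "Salmo_trutta")
  expect_identical(out$provenance, "both_diff_rank")
  expect_identical(unique(out$channel), "combined")
})

test_that("marker merge is an idempotent union with same-rank provenance", {
  tree <- fixture_tree()
  a <- make_recs(list(S = c("Salmo_trutta", "Cottus_gobio")), "marker16S")
  b <- make_recs(list(S = c("Salmo_trutta", "Cottus_gobio")), "markerCOI")
  out <- merge_marker_presences(a, b, tree)
  expect_setequal(out$taxon, c("Salmo_trutta", "Cottus_gobio"))
  expect_true(all(out$provenance == "both_same_rank"))
  again <- merge_marker_presences(out, out, tree)
  expect_setequal(paste(again$sample_id, again$taxon),
                  paste(out$sample_id, out$taxon))
})

test_that("disjoint lineages in one sample are both kept", {
  tree <- fixture_tree()
  a <- make_recs(list(S = "Anguilla_anguilla"), "marker16S")
  b <- make_recs(list(S = "Gasterosteus_aculeatus"), "markerCOI")
  out <- merge_marker_presences(a, b, tree)
  expect_setequal(out$taxon, c("Anguilla_anguilla", "Gasterosteus_aculeatus"))
  expect_setequal(out$provenance, c("only_A", "only_B"))
})

test_that("marker merge matches the union-minus-dominated-ancestors oracle", {
  set.seed(7)
  for (rep in 1:25) {
    tree <- random_tree(30)
    ids <- tree$table$id
    samples <- paste0("s", 1:4)
    pick <- function() {
      sets <- lapply(samples, function(s) sample(ids, sample(0:6, 1)))
      names(sets) <- samples
      sets <- Filter(length, sets)
      if (!length(sets)) sets <- list(s1 = sample(ids, 1))
      make_recs(sets, "marker16S")
    }
    a <- pick(); b <- pick()
    out <- merge_marker_presences(a, b, tree)
    expect_true(same_presence_set(out, bf_merge(a, b, tree)))
    # invariant: no sample retains a taxon with a present descendant
    for (s in unique(out$sample_id)) {
      tx <- out$taxon[out$sample_id == s]
      for (x in tx) for (y in tx)
        expect_false(is_ancestor(x, y, tree))
    }
    # symmetry up to provenance relabelling
    swapped <- merge_marker_presences(b, a, tree)
    expect_true(same_presence_set(out, swapped))
  }
})

test_that("secondary-prey labels are removed with a logged count", {
  m <- presence_records(c("s1", "s1", "s2"),
                        c("insect", "Cottus_gobio", "mollusk"),
                        channel = "morphology")
  out <- remove_secondary(m)
  expect_identical(out$taxon, "Cottus_gobio")
  expect_identical(attr(out, "n_removed"), 2L)
  keep_all <- remove_secondary(m, blocklist = character(0))
  expect_identical(nrow(keep_all), nrow(m))
  set.seed(1)
  labs <- sample(c("insect", "snail", "Cottus_gobio", "Perca_fluviatilis"),
                 50, replace = TRUE)
  r <- presence_records(paste0("s", 1:50), labs, channel = "morphology")
  out2 <- remove_secondary(r)
  expect_identical(nrow(out2),
                   nrow(r) - sum(r$taxon %in% c("insect", "snail")))
})

test_that("method combination resolves composites toward the certain taxon", {
  tree <- fixture_tree()
  cats <- default_morph_categories(tree)

  # composite morph "rudd/roach" disambiguated by finer knowledge:
  # DNA member species wins over the composite
  dna <- make_recs(list(S = "Rutilus_rutilus"), "combined")
  morph <- make_recs(list(S = "rudd_roach_morph"), "morphology")
  out <- combine_methods(dna, morph, tree, cats)
  expect_identical(out$taxon, "Rutilus_rutilus")
  expect_identical(out$provenance, "both_diff_rank")

  # single-member morph identification finer than the DNA taxon wins
  dna2 <- make_recs(list(S = "Cyprinidae"), "combined")
  morph2 <- make_recs(list(S = "Scardinius_erythrophthalmus"), "morphology")
  out2 <- combine_methods(dna2, morph2, tree, cats)
  expect_identical(out2$taxon, "Scardinius_erythrophthalmus")
  expect_identical(out2$provenance, "both_diff_rank")

  # morph crayfish (ambiguous between species) vs two DNA crayfish
  # species: both species retained, composite absorbed
  dna3 <- make_recs(list(S = c("Austropotamobius_pallipes",
                               "Pacifastacus_leniusculus")), "combined")
  morph3 <- make_recs(list(S = "crayfish_morph"), "morphology")
  out3 <- combine_methods(dna3, morph3, tree, cats)
  expect_setequal(out3$taxon, c("Austropotamobius_pallipes",
                                "Pacifastacus_leniusculus"))
  expect_true(all(out3$provenance == "both_diff_rank"))
})

test_that("partial composite overlap falls back to the lowest common ancestor", {
  tree <- fixture_tree()
  # composite of two cyprinid species vs DNA at one member's genus:
  # genus is an ancestor of one member only -> ambiguous -> LCA
  cats <- morph_categories("cyp_pair",
                           list(c("Rutilus_rutilus", "Leuciscus_leuciscus")),
                           tree)
  dna <- make_recs(list(S = "Rutilus"), "combined")
  morph <- make_recs(list(S = "cyp_pair"), "morphology")
  out <- combine_methods(dna, morph, tree, cats)
  expect_identical(out$taxon, "Cyprinidae")
})

test_that("single-channel records pass through with channel provenance", {
  tree <- fixture_tree()
  cats <- default_morph_categories(tree)
  dna <- make_recs(list(S1 = "Salmo_trutta"), "combined")
  morph <- make_recs(list(S2 = "Cottus_gobio", S3 = "crayfish_morph"),
                     "morphology")
  out <- combine_methods(dna, morph, tree, cats)
  expect_identical(out$provenance[out$sample_id == "S1"], "only_A")
  expect_identical(out$taxon[out$sample_id == "S2"], "Cottus_gobio")
  expect_identical(out$provenance[out$sample_id == "S2"], "only_B")
  expect_identical(out$taxon[out$sample_id == "S3"], "crayfish_morph")
  expect_error(combine_methods(dna, make_recs(list(S = "ghost"),
                                              "morphology"), tree, cats),
               "ghost")
})

test_that("occurrence partitions are disjoint and conserve totals", {
  tree <- fixture_tree()
  a <- make_recs(list(S1 = "Salmo_trutta"), "marker16S")
  b <- make_recs(list(S1 = "Salmonidae"), "markerCOI")
  ps <- partition_stats(a, b, tree)
  expect_identical(unname(ps$occurrences[c("only_A", "only_B")]), c(0L, 0L))
  expect_identical(unname(ps$occurrences["both_diff_rank"]), 1L)

  a2 <- make_recs(list(S1 = c("Anguilla_anguilla", "Cottus_gobio")),
                  "marker16S")
  b2 <- make_recs(list(S2 = "Perca_fluviatilis"), "markerCOI")
  ps2 <- partition_stats(a2, b2, tree)
  expect_identical(unname(ps2$occurrences["only_A"]), 2L)
  expect_identical(unname(ps2$occurrences["only_B"]), 1L)

  set.seed(11)
  for (rep in 1:10) {
    tree_r <- random_tree(25)
    ids <- tree_r$table$id
    mk <- function(ch) {
      sets <- lapply(paste0("s", 1:5), function(s) sample(ids, sample(1:5, 1)))
      names(sets) <- paste0("s", 1:5)
      make_recs(sets, ch)
    }
    a3 <- mk("marker16S"); b3 <- mk("markerCOI")
    ps3 <- partition_stats(a3, b3, tree_r)
    expect_identical(sum(ps3$occurrences), ps3$total_occurrences)
    expect_identical(ps3$total_occurrences,
                     nrow(merge_marker_presences(a3, b3, tree_r)))
  }
})

test_that("method coverage counts samples by detection channel", {
  a <- make_recs(list(S1 = "x", S2 = "x"), "combined")
  b <- make_recs(list(S2 = "y", S3 = "y"), "morphology")
  cov <- method_coverage(a, b)
  expect_identical(unname(cov), c(1L, 1L, 1L, 3L))
})
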