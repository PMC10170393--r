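simple_table <- function(counts, roles, marker = "16S") {
  read_table(counts, roles, marker)
}

test_that("proportional filter uses a strict inequality on raw totals", {
  m <- matrix(c(4L, 5L, 991L), 1, 3,
              dimnames = list("s1", c("a", "b", "c")))
  tab <- simple_table(m, c(s1 = "fecal"))
  out <- apply_proportional_filter(tab, filter_config())
  # total 1000 at 0.5%: 4 reads (0.4%) removed, 5 reads (exactly 0.5%) kept
  expect_identical(unname(out$counts["s1", ]), c(0L, 5L, 991L))

  zero <- simple_table(matrix(0L, 1, 3, dimnames = list("s1", c("a", "b", "c"))),
                       c(s1 = "fecal"))
  expect_identical(apply_proportional_filter(zero)$counts, zero$counts)
})

test_that("proportional filter matches the per-cell oracle and spares controls", {
  set.seed(3)
  for (rep in 1:20) {
    tab <- random_read_table()
    cfg <- filter_config()
    out <- apply_proportional_filter(tab, cfg)
    theta <- cfg$proportional_threshold[[tab$marker]]
    for (s in rownames(tab$counts)) {
      raw <- tab$counts[s, ]
      if (tab$roles[[s]] == "fecal") {
        expected <- ifelse(raw < theta * sum(raw), 0L, raw)
        expect_identical(unname(out$counts[s, ]), unname(expected))
      } else {
        expect_identical(out$counts[s, ], raw)
      }
    }
  }
})

test_that("control thresholds are the per-taxon maximum over control roles", {
  m <- rbind(s1 = c(100L, 50L), neg = c(3L, 0L), tag = c(7L, 0L))
  colnames(m) <- c("x", "y")
  tab <- simple_table(m, c(s1 = "fecal", neg = "pcr_negative",
                           tag = "unused_tag"))
  thr <- compute_control_thresholds(tab)
  expect_identical(unname(thr["x"]), 7L)
  expect_identical(unname(thr["y"]), 0L)

  no_ctrl <- simple_table(m[1, , drop = FALSE], c(s1 = "fecal"))
  expect_identical(unname(compute_control_thresholds(no_ctrl)), c(0L, 0L))

  set.seed(5)
  for (rep in 1:20) {
    tab2 <- random_read_table()
    thr2 <- compute_control_thresholds(tab2)
    ctrl <- tab2$counts[tab2$roles %in% c("extraction_negative",
                                          "pcr_negative", "unused_tag"), ,
                        drop = FALSE]
    expect_identical(unname(thr2), unname(apply(ctrl, 2, max)))
  }
})

test_that("control filter removes counts at or below the threshold", {
  m <- rbind(s1 = c(7L, 8L), neg = c(7L, 7L))
  colnames(m) <- c("x", "y")
  tab <- simple_table(m, c(s1 = "fecal", neg = "pcr_negative"))
  out <- apply_control_filter(tab, compute_control_thresholds(tab))
  expect_identical(unname(out$counts["s1", ]), c(0L, 8L))

  # threshold 0 everywhere leaves positive counts intact
  tab0 <- simple_table(rbind(s1 = c(1L, 0L, 500L)), c(s1 = "fecal"))
  colnames(tab0$counts) <- c("a", "b", "c")
  thr0 <- setNames(c(0L, 0L, 0L), c("a", "b", "c"))
  expect_identical(apply_control_filter(tab0, thr0)$counts, tab0$counts)
})

test_that("filter cascade is monotone and composition-dominant", {
  set.seed(9)
  for (rep in 1:15) {
    tab <- random_read_table(n_fecal = 6, n_taxa = 5)
    res <- filter_marker(tab)
    expect_true(all(res$table$counts <= tab$counts))
    prop_only <- apply_proportional_filter(tab)
    ctrl_only <- apply_control_filter(tab, compute_control_thresholds(tab))
    removed_comp <- tab$counts > 0 & res$table$counts == 0
    removed_prop <- tab$counts > 0 & prop_only$counts == 0
    removed_ctrl <- tab$counts > 0 & ctrl_only$counts == 0
    expect_true(all(removed_comp[removed_prop | removed_ctrl]))
    # final presences are a subset of raw support
    pres <- to_presence(res$table)
    expect_true(all(tab$counts[rownames(pres), ][pres == 1] > 0))
  }
})

test_that("presence conversion thresholds at zero over fecal samples", {
  m <- rbind(s1 = c(0L, 1L, 500L), neg = c(2L, 2L, 2L))
  colnames(m) <- c("a", "b", "c")
  tab <- simple_table(m, c(s1 = "fecal", neg = "pcr_negative"))
  expect_identical(unname(to_presence(tab)["s1", ]), c(0L, 1L, 1L))
  all0 <- simple_table(matrix(0L, 2, 2, dimnames = list(c("s1", "s2"), c("a", "b"))),
                       c(s1 = "fecal", s2 = "fecal"))
  expect_true(all(to_presence(all0) == 0L))
})

test_that("non-food removal drops host, non-animals, coarse ids and small taxa", {
  tree <- fixture_tree()
  recs <- presence_records(rep("s1", 4),
                           c("Lutra_lutra", "Salmo_trutta", "Navicula_spp",
                             "Actinopterygii"),
                           channel = "combined")
  cfg <- filter_config(coarse_blocklist = "Actinopterygii")
  traits <- data.frame(taxon_id = "Navicula_spp", max_size_lt_min = TRUE)
  out <- suppressWarnings(remove_nonfood(recs, tree, cfg, traits))
  expect_identical(out$taxon, "Salmo_trutta")
  log <- attr(out, "removal_log")
  expect_identical(unname(log["consumer"]), 1L)
  expect_identical(unname(log["non_animal"]), 1L)
  expect_identical(unname(log["coarse"]), 1L)

  # diatom removed by kingdom even without a small-body flag
  out2 <- remove_nonfood(presence_records("s1", "Navicula_spp",
                                          channel = "combined"), tree)
  expect_identical(nrow(out2), 0L)

  # a small-bodied animal is removed by the trait flag
  traits3 <- data.frame(taxon_id = "Lymnaea_stagnalis",
                        max_size_lt_min = TRUE)
  out3 <- remove_nonfood(presence_records("s1", "Lymnaea_stagnalis",
                                          channel = "combined"),
                         tree, filter_config(), traits3)
  expect_identical(nrow(out3), 0L)

  # missing trait entries warn and are treated as not small
  expect_warning(
    out4 <- remove_nonfood(presence_records("s1", "Salmo_trutta",
                                            channel = "combined"),
                           tree, filter_config(), traits3),
    "Salmo_trutta")
  expect_identical(out4$taxon, "Salmo_trutta")
})

test_that("repeat libraries collapse by per-cell maximum before filtering", {
  m <- rbind(r1 = c(10L, 0L), r2 = c(3L, 8L))
  colnames(m) <- c("a", "b")
  tab <- simple_table(m, c(r1 = "fecal", r2 = "fecal"))
  out <- collapse_repeats(tab, c(r1 = "s1", r2 = "s1"))
  expect_identical(unname(out$counts["s1", ]), c(10L, 8L))
})

test_that("read tables reject malformed input and round-trip through CSV", {
  m <- matrix(1L, 1, 1, dimnames = list("s1", "a"))
  expect_error(read_table(m, c(s1 = "guest"), "16S"), "role")
  expect_error(read_table(matrix(-1L, 1, 1, dimnames = list("s1", "a")),
                          c(s1 = "fecal"), "16S"), "nonnegative")
  expect_error(filter_config(proportional_threshold = c("16S" = 1.2)),
               "\\(0, 1\\)")
  set.seed(21)
  tab <- random_read_table()
  path <- tempfile(fileext = ".csv")
  write_read_table(tab, path)
  back <- read_read_table(path, tab$marker)
  shared <- intersect(colnames(back$counts), colnames(tab$counts))
  expect_identical(back$counts[rownames(tab$counts), shared],
                   tab$counts[, shared])
  # columns absent after the round-trip held no reads
  expect_true(all(tab$counts[, setdiff(colnames(tab$counts), shared)] == 0L))
  expect_identical(back$roles[names(tab$roles)], tab$roles)
  unlink(path)
})
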