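#' Construct a per-marker read table
#'
#' Sample-by-taxon read counts together with the role of every sequencing
#' library: true fecal samples, extraction and PCR negative controls,
#' unused tag combinations (which catch tag jumping) and mock communities.
#'
#' @param counts integer matrix, samples in rows (named), taxa in columns
#' @param roles named character vector mapping every sample to one of
#'   `fecal`, `extraction_negative`, `pcr_negative`, `unused_tag`, `mock`
#' @param marker `"16S"` or `"COI"`
#' @return object of class `read_table`
#' @export
read_table <- function(counts, roles, marker = c("16S", "COI")) {
  marker <- match.arg(marker)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have sample rownames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  valid <- c("fecal", "extraction_negative", "pcr_negative", "unused_tag",
             "mock")
  if (!setequal(names(roles), rownames(counts)))
    stop("roles must name exactly the samples in counts")
  bad <- setdiff(unique(roles), valid)
  if (length(bad)) stop("unknown sample roles: ", paste(bad, collapse = ", "))
  roles <- roles[rownames(counts)]
  structure(list(counts = counts, roles = roles, marker = marker),
            class = "read_table")
}

#' @export
print.read_table <- function(x, ...) {
  cat("<read_table ", x$marker, "> ", nrow(x$counts), " samples (",
      sum(x$roles == "fecal"), " fecal) x ", ncol(x$counts), " taxa\n",
      sep = "")
  invisible(x)
}

control_roles <- c("extraction_negative", "pcr_negative", "unused_tag")

#' Filtering configuration
#'
#' @param proportional_threshold per-marker minimum within-sample read
#'   proportion; a fecal count strictly below `threshold * sample total`
#'   is zeroed. Defaults follow the conservative two-marker convention of
#'   0.5% for 16S and 0.3% for COI.
#' @param allowed_kingdom taxa outside this kingdom are non-food
#' @param consumer_taxon the predator's own taxon id (its reads are host
#'   carry-over, not diet)
#' @param coarse_blocklist taxon ids too poorly resolved to be informative
#' @param min_body_mm taxa whose maximum body size is below this are
#'   treated as secondary/accidental ingestion
#' @return list of class `filter_config`
#' @export
filter_config <- function(proportional_threshold = c("16S" = 0.005,
                                                     "COI" = 0.003),
                          allowed_kingdom = "Animalia",
                          consumer_taxon = "Lutra_lutra",
                          coarse_blocklist = character(0),
                          min_body_mm = 3) {
  if (any(proportional_threshold <= 0 | proportional_threshold >= 1))
    stop("proportional thresholds must lie in (0, 1)")
  structure(list(proportional_threshold = proportional_threshold,
                 allowed_kingdom = allowed_kingdom,
                 consumer_taxon = consumer_taxon,
                 coarse_blocklist = coarse_blocklist,
                 min_body_mm = min_body_mm),
            class = "filter_config")
}

#' Collapse repeat libraries of the same sample
#'
#' Repeats are collapsed before filtering by the per-cell maximum, which
#' preserves every detection made in any repeat.
#'
#' @param table a [read_table()]
#' @param sample_of named map from library name to biological sample id;
#'   libraries sharing a value are repeats (must share a role)
#' @return collapsed `read_table`
#' @export
collapse_repeats <- function(table, sample_of) {
  stopifnot(all(rownames(table$counts) %in% names(sample_of)))
  grp <- sample_of[rownames(table$counts)]
  ids <- sort(unique(grp))
  m <- t(vapply(ids, function(g) {
    apply(table$counts[grp == g, , drop = FALSE], 2, max)
  }, integer(ncol(table$counts))))
  dimnames(m) <- list(ids, colnames(table$counts))
  roles <- vapply(ids, function(g) unique(table$roles[grp == g])[1],
                  character(1))
  read_table(m, roles, table$marker)
}

#' Zero out low-proportion reads within each fecal sample
#'
#' Removes taxa contributing strictly less than the marker's proportional
#' threshold of a sample's total reads; the denominator is the raw
#' (pre-filtering) sample total. A count exactly at the threshold is kept.
#' Control samples are left untouched.
#'
#' @param table a [read_table()] with raw counts
#' @param cfg a [filter_config()]
#' @return filtered `read_table`
#' @export
apply_proportional_filter <- function(table, cfg = filter_config()) {
  theta <- cfg$proportional_threshold[[table$marker]]
  if (is.null(theta) || theta <= 0 || theta >= 1)
    stop("no valid proportional threshold for marker ", table$marker)
  m <- table$counts
  fecal <- table$roles == "fecal"
  tot <- rowSums(m[fecal, , drop = FALSE])
  cutoff <- theta * tot
  sub <- m[fecal, , drop = FALSE]
  sub[sub < cutoff] <- 0L   # strict inequality: "less than" the threshold
  m[fecal, ] <- sub
  read_table(m, table$roles, table$marker)
}

#' Per-taxon contamination thresholds from control libraries
#'
#' For every taxon, the maximum read count observed in any extraction
#' negative, PCR negative or unused tag combination. Taxa never seen in a
#' control map to 0.
#'
#' @param table a [read_table()]
#' @return named integer vector, one threshold per taxon
#' @export
compute_control_thresholds <- function(table) {
  ctrl <- table$counts[table$roles %in% control_roles, , drop = FALSE]
  if (nrow(ctrl) == 0)
    return(setNames(integer(ncol(table$counts)), colnames(table$counts)))
  apply(ctrl, 2, max)
}

#' Remove reads at or below the control-derived threshold
#'
#' In fecal samples, a count less than or equal to the taxon's control
#' threshold is zeroed (inclusive inequality — a fecal count merely tying
#' the worst control is not trusted); counts strictly above are retained.
#'
#' @param table a [read_table()]
#' @param thresholds from [compute_control_thresholds()]
#' @return filtered `read_table`
#' @export
apply_control_filter <- function(table, thresholds) {
  m <- table$counts
  stopifnot(all(colnames(m) %in% names(thresholds)))
  fecal <- table$roles == "fecal"
  sub <- m[fecal, , drop = FALSE]
  thr <- matrix(thresholds[colnames(m)], nrow(sub), ncol(m), byrow = TRUE)
  sub[sub <= thr] <- 0L
  m[fecal, ] <- sub
  read_table(m, table$roles, table$marker)
}

#' Reduce a filtered read table to presence-absence over fecal samples
#'
#' @param table a filtered [read_table()]
#' @return binary integer matrix (fecal samples x taxa)
#' @export
to_presence <- function(table) {
  m <- table$counts[table$roles == "fecal", , drop = FALSE]
  (m > 0) + 0L
}

#' Convert a binary presence matrix to long-form presence records
#' @param m binary sample-by-taxon matrix
#' @param channel channel label for the records
#' @return `presence_records`
#' @export
presences_from_matrix <- function(m, channel) {
  idx <- which(m > 0, arr.ind = TRUE)
  presence_records(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]],
                   channel = channel)
}

#' Remove non-food detections
#'
#' Drops presence records that cannot be diet: taxa outside the allowed
#' kingdom (e.g. fungi, diatoms' kingdom), the consumer's own reads, taxa
#' listed as too coarsely resolved to analyse, and taxa flagged as below
#' the minimum body size (secondary or accidental ingestion). Each removal
#' class is tallied in the `removal_log` attribute.
#'
#' @param presences `presence_records` with taxonomy-id taxa
#' @param tree a [taxonomy()]
#' @param cfg a [filter_config()]
#' @param traits data.frame with columns `taxon_id` and `max_size_lt_min`
#'   (logical: maximum body size below `cfg$min_body_mm`); taxa without an
#'   entry are treated as not small, with a warning
#' @param categories optional [morph_categories()]; composite labels are
#'   resolved to their members' lowest common ancestor for the kingdom
#'   check
#' @return filtered records with attribute `removal_log`
#' @export
remove_nonfood <- function(presences, tree, cfg = filter_config(),
                           traits = NULL, categories = NULL) {
  taxa <- presences$taxon
  resolve_for_check <- function(t) {
    if (t %in% names(tree$idx)) return(t)
    if (!is.null(categories) && t %in% categories$labels)
      return(lca(tree, categories$members[[t]]))
    stop("unknown taxon id: ", t)
  }
  check_ids <- vapply(taxa, resolve_for_check, character(1))
  kingdom_of <- vapply(check_ids, function(t) lineage(tree, t)[1],
                       character(1))
  kingdom_names <- tree$table$name[tree$idx[kingdom_of]]
  out_kingdom <- !(kingdom_names == cfg$allowed_kingdom |
                     kingdom_of == cfg$allowed_kingdom)
  consumer <- taxa == cfg$consumer_taxon
  coarse <- taxa %in% cfg$coarse_blocklist
  small <- rep(FALSE, length(taxa))
  if (!is.null(traits) && nrow(traits)) {
    hit <- match(taxa, traits$taxon_id)
    known <- !is.na(hit)
    small[known] <- traits$max_size_lt_min[hit[known]]
    unknown <- unique(taxa[!known])
    if (length(unknown))
      warning("no trait entry for: ", paste(unknown, collapse = ", "),
              "; treated as not small-bodied")
  }
  drop <- out_kingdom | consumer | coarse | small
  out <- as_presences(presences[!drop, , drop = FALSE])
  attr(out, "removal_log") <- c(non_animal = sum(out_kingdom),
                                consumer = sum(consumer & !out_kingdom),
                                coarse = sum(coarse & !out_kingdom & !consumer),
                                small_bodied = sum(small & !out_kingdom &
                                                     !consumer & !coarse))
  out
}

#' Run the full per-marker filtering cascade
#'
#' Proportional filter (on raw totals), then control filter; read counts
#' never increase, so the composition removes a superset of what either
#' filter removes alone.
#'
#' @param table raw [read_table()]
#' @param cfg a [filter_config()]
#' @return list: filtered `table`, control `thresholds`, binary `presence`
#'   matrix over fecal samples
#' @export
filter_marker <- function(table, cfg = filter_config()) {
  prop <- apply_proportional_filter(table, cfg)
  thr <- compute_control_thresholds(table)
  flt <- apply_control_filter(prop, thr)
  list(table = flt, thresholds = thr, presence = to_presence(flt))
}

#' Read a long-format read table (sample_id, role, taxon, count) from CSV
#' @param path file path
#' @param marker `"16S"` or `"COI"`
#' @export
read_read_table <- function(path, marker) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "role", "taxon", "count") %in% names(df)))
  samples <- unique(df$sample_id)
  taxa <- sort(unique(df$taxon))
  m <- matrix(0L, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  m[cbind(match(df$sample_id, samples), match(df$taxon, taxa))] <-
    as.integer(df$count)
  roles <- setNames(df$role[!duplicated(df$sample_id)], samples)
  read_table(m, roles, marker)
}

#' Write a read table in long CSV format
#' @param table a [read_table()]
#' @param path output path
#' @export
write_read_table <- function(table, path) {
  idx <- which(table$counts >= 0, arr.ind = TRUE)
  df <- data.frame(sample_id = rownames(table$counts)[idx[, 1]],
                   role = unname(table$roles[idx[, 1]]),
                   taxon = colnames(table$counts)[idx[, 2]],
                   count = table$counts[idx])
  df <- df[df$count > 0 | !duplicated(df$sample_id), ]
  write.csv(df[order(df$sample_id, df$taxon), ], path, row.names = FALSE)
}
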