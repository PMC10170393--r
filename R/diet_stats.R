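#' Aggregate a taxon presence matrix into prey groups
#'
#' A prey group is present in a sample iff any of its member taxa is
#' present (logical OR over member columns). Taxa that cannot be assigned
#' to a group must be listed in `unassigned`; they are dropped with a tally.
#'
#' @param m binary sample-by-taxon matrix
#' @param group_map data.frame with columns `taxon` and `group`
#' @param unassigned character vector of removable taxa without a group
#' @return binary sample-by-group matrix; attribute `n_unassigned_dropped`
#'   records the dropped presence count
#' @export
map_to_groups <- function(m, group_map, unassigned = character(0)) {
  taxa <- colnames(m)
  unknown <- setdiff(taxa, c(group_map$taxon, unassigned))
  if (length(unknown))
    stop("taxa neither mapped to a group nor listed unassigned: ",
         paste(unknown, collapse = ", "))
  dropped <- intersect(taxa, unassigned)
  n_dropped <- sum(m[, dropped, drop = FALSE])
  groups <- unique(group_map$group[group_map$taxon %in% taxa])
  out <- vapply(groups, function(g) {
    mem <- intersect(group_map$taxon[group_map$group == g], taxa)
    (rowSums(m[, mem, drop = FALSE]) > 0) + 0L
  }, integer(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), groups))
  attr(out, "n_unassigned_dropped") <- n_dropped
  out
}

#' Drop prey groups occurring in fewer than `min_samples` samples
#'
#' @param m binary sample-by-group matrix
#' @param min_samples rarity threshold; a group present in fewer samples
#'   than this is removed (strict inequality: present in exactly
#'   `min_samples` samples is kept)
#' @return filtered matrix; attribute `dropped_groups` lists removals
#' @export
drop_rare_groups <- function(m, min_samples = 3) {
  keep <- colSums(m) >= min_samples
  out <- m[, keep, drop = FALSE]
  attr(out, "dropped_groups") <- colnames(m)[!keep]
  out
}

#' Frequency of occurrence per column
#'
#' Percentage of samples in which each taxon or prey group occurs. The
#' denominator is the number of samples (rows) of the matrix under
#' analysis, i.e. samples with any dietary data; pass a matrix padded with
#' empty rows to use the all-screened-samples convention instead.
#'
#' @param m binary presence matrix
#' @return named numeric vector of percentages in `[0, 100]`
#' @export
frequency_of_occurrence <- function(m) {
  if (nrow(m) == 0) stop("zero samples")
  100 * colSums(m) / nrow(m)
}

#' Mean number of taxa (or prey groups) per sample
#'
#' @param m binary presence matrix
#' @return total presences divided by number of samples
#' @export
mean_taxa_per_sample <- function(m) {
  if (nrow(m) == 0) stop("zero samples")
  sum(m) / nrow(m)
}

#' Read a prey-group map from TSV (columns taxon, group)
#' @param path file path
#' @export
read_group_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "group") %in% names(df)))
  df
}
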