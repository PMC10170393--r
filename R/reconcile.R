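#' Construct a presence-record table
#'
#' Long-form binary detections: one row per (sample, taxon, channel). The
#' `taxon` column holds taxonomy ids for molecular channels and either ids
#' or morphological category labels for the morphology channel.
#'
#' @param sample_id,taxon character vectors (recycled to common length)
#' @param channel one of `"marker16S"`, `"markerCOI"`, `"morphology"`,
#'   `"combined"`
#' @param provenance optional; normally `NA` until channels are compared
#' @return data.frame of class `presence_records`
#' @export
presence_records <- function(sample_id, taxon,
                             channel = c("marker16S", "markerCOI",
                                         "morphology", "combined"),
                             provenance = NA_character_) {
  channel <- match.arg(channel)
  if (!length(sample_id)) {
    out <- empty_presences()
    out$channel <- character(0)
    return(out)
  }
  df <- data.frame(sample_id = as.character(sample_id),
                   taxon = as.character(taxon),
                   channel = channel,
                   provenance = provenance,
                   stringsAsFactors = FALSE)
  df <- unique(df)
  class(df) <- c("presence_records", "data.frame")
  df
}

as_presences <- function(df) {
  stopifnot(all(c("sample_id", "taxon", "channel", "provenance") %in% names(df)))
  rownames(df) <- NULL
  class(df) <- c("presence_records", "data.frame")
  df
}

empty_presences <- function() {
  as_presences(data.frame(sample_id = character(0), taxon = character(0),
                          channel = character(0), provenance = character(0),
                          stringsAsFactors = FALSE))
}

rbind_presences <- function(...) {
  parts <- Filter(function(d) nrow(d) > 0, list(...))
  if (!length(parts)) return(empty_presences())
  as_presences(do.call(rbind, lapply(parts, as.data.frame)))
}

# Drop every taxon that has a strict descendant present in the same set.
# Returns the surviving subset of ids.
drop_dominated <- function(ids, tree) {
  ids <- unique(ids)
  if (length(ids) < 2) return(ids)
  keep <- vapply(ids, function(a) {
    !any(vapply(ids, function(b) is_ancestor(a, b, tree), logical(1)))
  }, logical(1))
  ids[keep]
}

#' Merge presence records from two metabarcoding markers
#'
#' Per sample, takes the union of detections; when one marker detects a
#' taxon that is an ancestor of the other marker's detection (same prey,
#' coarser resolution), only the finer (deeper) taxon is kept. Detections
#' on disjoint lineages are both kept — multi-prey samples are real.
#'
#' Provenance labels output records relative to argument order:
#' `only_A`/`only_B` (detected by one marker), `both_same_rank` (same taxon
#' in both), `both_diff_rank` (the kept record subsumed a coarser detection
#' from the other channel).
#'
#' @param pa,pb `presence_records` for the two markers
#' @param tree a [taxonomy()]
#' @return combined `presence_records` with channel `"combined"`
#' @export
merge_marker_presences <- function(pa, pb, tree) {
  samples <- union(pa$sample_id, pb$sample_id)
  out <- lapply(samples, function(s) {
    A <- unique(pa$taxon[pa$sample_id == s])
    B <- unique(pb$taxon[pb$sample_id == s])
    for (id in c(A, B)) resolve_id(tree, id)
    kept <- drop_dominated(union(A, B), tree)
    prov <- vapply(kept, function(t) {
      inA <- t %in% A
      inB <- t %in% B
      if (inA && inB) return("both_same_rank")
      other <- if (inA) B else A
      if (any(vapply(other, function(o) is_ancestor(o, t, tree), logical(1))))
        return("both_diff_rank")
      if (inA) "only_A" else "only_B"
    }, character(1))
    data.frame(sample_id = s, taxon = kept, channel = "combined",
               provenance = unname(prov), stringsAsFactors = FALSE)
  })
  as_presences(do.call(rbind, c(out,
    list(data.frame(sample_id = character(0), taxon = character(0),
                    channel = character(0), provenance = character(0))))))
}

#' Remove suspected secondary-prey morphological identifications
#'
#' Coarse morphological labels that plausibly arise from prey-of-prey
#' material (hard parts of invertebrates consumed by fish) or from the
#' predator grooming itself are dropped before method comparison.
#'
#' @param morph `presence_records` from morphology
#' @param blocklist labels to drop; the default is the study's judgement
#'   call, kept as configuration
#' @return filtered records; attribute `n_removed` carries the tally
#' @export
remove_secondary <- function(morph,
                             blocklist = c("insect", "beetle", "mollusk",
                                           "snail", "mammal")) {
  drop <- morph$taxon %in% blocklist
  out <- as_presences(morph[!drop, , drop = FALSE])
  attr(out, "n_removed") <- sum(drop)
  out
}

# Resolve a morphology taxon string to its member id set: category labels
# expand to their members, anything else must be a taxonomy id.
morph_members <- function(taxon, tree, categories) {
  if (!is.null(categories) && taxon %in% categories$labels)
    return(categories$members[[taxon]])
  resolve_id(tree, taxon)
  taxon
}

#' Combine molecular and morphological prey detections
#'
#' Per sample, reconciles DNA detections (taxonomy ids) with morphological
#' identifications (ids or composite categories such as "rudd/roach"):
#'
#' * detections on one lineage keep the finer taxon;
#' * a composite category containing the DNA taxon resolves to the DNA
#'   taxon, unless the morphology side is strictly finer (a single member
#'   that is a descendant), in which case the morphological taxon wins;
#' * a partial, ambiguous overlap between a composite and the DNA taxon's
#'   subtree is recorded at the lowest common ancestor — the most specific
#'   taxon that is certainly correct;
#' * single-channel detections pass through.
#'
#' Provenance is relative to argument order (`only_A` = DNA-only,
#' `only_B` = morphology-only).
#'
#' @param dna combined metabarcoding `presence_records` (taxonomy ids)
#' @param morph morphological `presence_records`, secondary-prey labels
#'   already removed (see [remove_secondary()])
#' @param tree a [taxonomy()]
#' @param categories [morph_categories()] resolving composite labels;
#'   may be `NULL` if all morphology taxa are plain ids
#' @return combined `presence_records`
#' @export
combine_methods <- function(dna, morph, tree, categories = NULL) {
  samples <- union(dna$sample_id, morph$sample_id)
  res <- lapply(samples, function(s) {
    D <- unique(dna$taxon[dna$sample_id == s])
    for (d in D) resolve_id(tree, d)
    dprov <- setNames(rep("only_A", length(D)), D)
    extra_taxa <- character(0)
    extra_prov <- character(0)
    dropD <- character(0)

    for (lab in unique(morph$taxon[morph$sample_id == s])) {
      M <- morph_members(lab, tree, categories)
      matched <- FALSE
      for (d in D) {
        if (length(M) == 1) {
          m <- M
          if (m == d) {
            dprov[d] <- "both_same_rank"; matched <- TRUE
          } else if (is_ancestor(m, d, tree)) {       # DNA finer
            if (dprov[d] == "only_A") dprov[d] <- "both_diff_rank"
            matched <- TRUE
          } else if (is_ancestor(d, m, tree)) {       # morphology finer
            dropD <- c(dropD, d)
            extra_taxa <- c(extra_taxa, m)
            extra_prov <- c(extra_prov, "both_diff_rank")
            matched <- TRUE
          }
        } else {
          contains <- d %in% M ||
            any(vapply(M, function(m) is_ancestor(m, d, tree), logical(1)))
          below <- vapply(M, function(m) is_ancestor(d, m, tree), logical(1))
          if (contains) {                              # DNA at least as fine
            if (dprov[d] == "only_A") dprov[d] <- "both_diff_rank"
            matched <- TRUE
          } else if (any(below)) {                     # ambiguous overlap
            anc <- lca(tree, c(M, d))
            dropD <- c(dropD, d)
            extra_taxa <- c(extra_taxa, anc)
            extra_prov <- c(extra_prov, "both_diff_rank")
            matched <- TRUE
          }
        }
      }
      if (!matched) {
        extra_taxa <- c(extra_taxa, if (length(M) == 1) M else lab)
        extra_prov <- c(extra_prov, "only_B")
      }
    }

    keepD <- setdiff(D, dropD)
    taxa <- c(keepD, extra_taxa)
    prov <- c(unname(dprov[keepD]), extra_prov)
    dup <- duplicated(taxa)
    taxa <- taxa[!dup]; prov <- prov[!dup]

    # final domination cleanup among resolvable ids
    resolvable <- vapply(taxa, function(t) t %in% names(tree$idx), logical(1))
    kept_ids <- drop_dominated(taxa[resolvable], tree)
    keep <- !resolvable | taxa %in% kept_ids
    data.frame(sample_id = s, taxon = taxa[keep], channel = "combined",
               provenance = prov[keep], stringsAsFactors = FALSE)
  })
  as_presences(do.call(rbind, c(res,
    list(data.frame(sample_id = character(0), taxon = character(0),
                    channel = character(0), provenance = character(0))))))
}

#' Partition occurrences of two detection channels
#'
#' Combines two channels and tabulates occurrence records and distinct taxa
#' by provenance (`only_A`, `only_B`, `both_same_rank`, `both_diff_rank`).
#' Occurrence categories are disjoint and sum to the combined total.
#'
#' @param a,b `presence_records` over the same sample universe
#' @param tree a [taxonomy()]
#' @param categories optional [morph_categories()]; when supplied the
#'   channels are reconciled with [combine_methods()] (method comparison),
#'   otherwise with [merge_marker_presences()] (marker comparison)
#' @return list with `occurrences` and `taxa` named count vectors plus
#'   `total_occurrences` and `total_taxa` of the combined set
#' @export
partition_stats <- function(a, b, tree, categories = NULL) {
  combined <- if (is.null(categories)) merge_marker_presences(a, b, tree)
              else combine_methods(a, b, tree, categories)
  cats <- c("only_A", "only_B", "both_same_rank", "both_diff_rank")
  occ <- vapply(cats, function(k) sum(combined$provenance == k), integer(1))
  tax <- vapply(cats, function(k)
    length(unique(combined$taxon[combined$provenance == k])), integer(1))
  list(occurrences = occ, taxa = tax,
       total_occurrences = nrow(combined),
       total_taxa = length(unique(combined$taxon)))
}

#' Count samples by which detection method yielded dietary data
#'
#' @param a,b `presence_records` for two methods
#' @return named integer vector: `only_A`, `only_B`, `both`, `total`
#' @export
method_coverage <- function(a, b) {
  sa <- unique(a$sample_id)
  sb <- unique(b$sample_id)
  c(only_A = length(setdiff(sa, sb)),
    only_B = length(setdiff(sb, sa)),
    both = length(intersect(sa, sb)),
    total = length(union(sa, sb)))
}

#' Convert presence records to a binary sample-by-taxon matrix
#' @param records `presence_records`
#' @param samples optional sample universe for rows (defaults to samples
#'   with at least one record)
#' @return binary integer matrix
#' @export
records_to_matrix <- function(records, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(records$sample_id))
  taxa <- sort(unique(records$taxon))
  m <- matrix(0L, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  keep <- records$sample_id %in% samples
  m[cbind(records$sample_id[keep], records$taxon[keep])] <- 1L
  m
}
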