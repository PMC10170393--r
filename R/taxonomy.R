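#' @useDynLib spraintR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate as.formula coef cor model.matrix optim rbinom
#'   rlnorm rnorm rpois runif sd setNames var
#' @importFrom utils head read.csv write.csv read.delim write.table
"_PACKAGE"

#' The Linnaean rank ladder used throughout the pipeline
#'
#' Ranks ordered coarse to fine. Intermediate ranks in source taxonomies
#' (e.g. infraclass) must be attached at the nearest coarser ladder rank
#' before import.
#' @export
RANK_LADDER <- c("kingdom", "phylum", "class", "order", "family",
                 "genus", "species")

#' Build a taxonomy from a lineage table
#'
#' The taxonomy is a rank-labelled forest stored as a parent-pointer table,
#' the natural container for reconciling prey detections made at different
#' taxonomic resolutions (species vs family vs class).
#'
#' @param df data.frame with columns `id`, `name`, `rank`, `parent_id`
#'   (`NA` for roots). Ranks must come from [RANK_LADDER] and each child's
#'   rank must be strictly finer than its parent's.
#' @return An object of class `taxonomy`: the validated table plus an
#'   id -> row index lookup.
#' @export
taxonomy <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("id", "name", "rank", "parent_id") %in% names(df)))
  df <- df[, c("id", "name", "rank", "parent_id")]
  df$id <- as.character(df$id)
  df$name <- as.character(df$name)
  df$rank <- as.character(df$rank)
  df$parent_id <- as.character(df$parent_id)
  if (anyDuplicated(df$id))
    stop("duplicate taxon ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad_rank <- setdiff(unique(df$rank), RANK_LADDER)
  if (length(bad_rank))
    stop("ranks outside the ladder: ", paste(bad_rank, collapse = ", "))
  has_parent <- !is.na(df$parent_id)
  missing_parent <- setdiff(df$parent_id[has_parent], df$id)
  if (length(missing_parent))
    stop("unknown parent ids: ", paste(missing_parent, collapse = ", "))
  idx <- setNames(seq_len(nrow(df)), df$id)
  rank_num <- match(df$rank, RANK_LADDER)
  parent_rank_num <- rank_num[idx[df$parent_id]]
  bad <- has_parent & !(parent_rank_num < rank_num)
  if (any(bad))
    stop("parent rank not coarser than child for: ",
         paste(df$id[bad], collapse = ", "))
  obj <- structure(list(table = df, idx = idx, rank_num = rank_num),
                   class = "taxonomy")
  # cycle / reachability check: walking to a root must terminate
  for (id in df$id) lineage(obj, id)
  obj
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$table), " taxa, ",
      sum(is.na(x$table$parent_id)), " root(s)\n", sep = "")
  invisible(x)
}

#' Read a taxonomy lineage table from TSV
#'
#' Expects columns `id`, `name`, `rank`, `parent_id`; empty `parent_id`
#' marks a root.
#' @param path file path
#' @return a [taxonomy()] object
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  taxonomy(df)
}

#' Write a taxonomy lineage table to TSV
#' @param tree a taxonomy
#' @param path output path
#' @export
write_taxonomy <- function(tree, path) {
  write.table(tree$table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

resolve_id <- function(tree, id) {
  i <- tree$idx[id]
  if (is.na(i)) stop("unknown taxon id: ", id)
  unname(i)
}

#' Root-path lineage of a taxon
#'
#' @param tree a taxonomy
#' @param id taxon id
#' @return character vector of ids from root down to (and including) `id`
#' @export
lineage <- function(tree, id) {
  i <- resolve_id(tree, id)
  path <- character(0)
  seen <- character(0)
  cur <- id
  while (!is.na(cur)) {
    if (cur %in% seen) stop("cycle in taxonomy at id: ", cur)
    seen <- c(seen, cur)
    path <- c(cur, path)
    cur <- tree$table$parent_id[resolve_id(tree, cur)]
  }
  path
}

#' Depth of a taxon on its root path
#'
#' Root nodes have depth 1. "Finer" resolution throughout the pipeline means
#' strictly greater depth, which is robust to ragged trees where rank labels
#' are skipped.
#' @inheritParams lineage
#' @return integer depth
#' @export
taxon_depth <- function(tree, id) length(lineage(tree, id))

#' Is taxon `a` a strict ancestor of taxon `b`?
#'
#' @param a,b taxon ids
#' @param tree a taxonomy
#' @return `TRUE` iff `a` lies on `b`'s root path and `a != b`
#' @export
is_ancestor <- function(a, b, tree) {
  resolve_id(tree, a)
  a != b && a %in% lineage(tree, b)
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree a taxonomy
#' @param ids character vector of taxon ids (>= 1)
#' @return the LCA id, or `NA_character_` if the taxa span disjoint trees
#'   of the forest
#' @export
lca <- function(tree, ids) {
  stopifnot(length(ids) >= 1)
  paths <- lapply(unique(ids), function(id) lineage(tree, id))
  common <- Reduce(intersect, paths)
  if (!length(common)) return(NA_character_)
  common[length(common)]
}

#' Rank of a taxon
#' @inheritParams lineage
#' @export
taxon_rank <- function(tree, id) tree$table$rank[resolve_id(tree, id)]

#' Morphological identification categories
#'
#' Morphological prey identifications are often coarser than molecular ones
#' and sometimes ambiguous between close relatives (composites such as
#' "rudd/roach"). A category maps one label to one or more taxonomy leaves.
#'
#' @param labels character vector of category labels
#' @param members list of character vectors of member taxon ids, parallel to
#'   `labels`; a single member means an unambiguous identification
#' @param tree a taxonomy used to validate members
#' @return object of class `morph_categories`
#' @export
morph_categories <- function(labels, members, tree) {
  stopifnot(length(labels) == length(members), !anyDuplicated(labels))
  for (k in seq_along(labels)) {
    mem <- members[[k]]
    if (!length(mem)) stop("category with no members: ", labels[k])
    for (m in mem) resolve_id(tree, m)
    if (length(mem) > 1) {
      anc <- lca(tree, mem)
      if (is.na(anc) || taxon_rank(tree, anc) == "kingdom")
        stop("composite members of '", labels[k],
             "' share no common ancestor below kingdom")
    }
  }
  structure(list(labels = labels, members = setNames(members, labels)),
            class = "morph_categories")
}

#' Read morphological categories from TSV (label, comma-separated member ids)
#' @param path file path
#' @param tree taxonomy used for validation
#' @export
read_morph_categories <- function(path, tree) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  morph_categories(df$label,
                   strsplit(df$members, ","),
                   tree)
}
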