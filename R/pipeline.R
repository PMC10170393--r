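#' Default end-to-end pipeline configuration
#'
#' One nested list drives the whole run: simulation, filtering,
#' secondary-prey blocklist, grouping, rarity threshold, model terms and
#' resampling effort. Every stage is also runnable standalone through the
#' module functions.
#'
#' @param seed master seed (flows into simulation and inference)
#' @param n_otters number of fecal samples to simulate
#' @param terms model terms tested sequentially by the multivariate model
#' @param B bootstrap resamples per tested term
#' @param min_samples prey-group rarity threshold
#' @param stepwise logical: run sum-AIC stepwise selection over
#'   `candidate_terms` before the anova stage
#' @param candidate_terms candidate set for stepwise selection
#' @return nested configuration list
#' @export
pipeline_config <- function(seed, n_otters = 300,
                            terms = c("longitude", "coast_distance"),
                            B = 199,
                            min_samples = 3,
                            stepwise = FALSE,
                            candidate_terms = c("sex", "size_class", "smi",
                                                "year", "season",
                                                "coast_distance", "habitat",
                                                "pct_urban", "latitude",
                                                "longitude")) {
  list(seed = as.integer(seed),
       sim = sim_config(seed, n_otters = n_otters),
       filter = filter_config(),
       blocklist = c("insect", "beetle", "mollusk", "snail", "mammal"),
       min_samples = min_samples,
       terms = terms, B = B,
       stepwise = stepwise, candidate_terms = candidate_terms)
}

#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Stage sequence: simulate (unless `study` is supplied) -> per-marker
#' read filtering -> marker merge -> secondary-prey removal -> method
#' combination -> non-food removal -> prey grouping -> rare-group drop ->
#' covariate construction -> multivariate cloglog GLM with resampling
#' inference. Every stage's input/output counts land in the run manifest;
#' rerunning with the same configuration reproduces the manifest hash
#' bit for bit.
#'
#' @param config from [pipeline_config()]
#' @param study optional pre-generated study (as from [simulate_study()]);
#'   when supplied the simulate stage is skipped
#' @return list of class `pipeline_result`: `manifest`, `combined`
#'   (presence records), `group_matrix`, `covariates`, `anova`,
#'   `fo` (frequency of occurrence), `stepwise` (if enabled)
#' @export
run_pipeline <- function(config, study = NULL) {
  manifest <- list(config_hash = rlang::hash(config),
                   seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  if (is.null(study)) study <- simulate_study(config$sim)
  tree <- study$world$tree
  note("simulate", n_otters = nrow(study$world$meta),
       n_true_presences = nrow(study$truth$taxa))

  f16 <- filter_marker(study$reads16S$table, config$filter)
  fcoi <- filter_marker(study$readsCOI$table, config$filter)
  note("filter",
       reads_in_16S = sum(study$reads16S$table$counts),
       reads_out_16S = sum(f16$table$counts),
       reads_in_COI = sum(study$readsCOI$table$counts),
       reads_out_COI = sum(fcoi$table$counts),
       presences_16S = sum(f16$presence), presences_COI = sum(fcoi$presence))

  p16 <- presences_from_matrix(f16$presence, "marker16S")
  pcoi <- presences_from_matrix(fcoi$presence, "markerCOI")
  dna <- merge_marker_presences(p16, pcoi, tree)
  marker_partition <- partition_stats(p16, pcoi, tree)
  note("merge_markers", occurrences = nrow(dna),
       partition = as.list(marker_partition$occurrences))

  morph <- remove_secondary(study$morph, config$blocklist)
  note("remove_secondary", n_in = nrow(study$morph), n_out = nrow(morph),
       n_removed = attr(morph, "n_removed"))

  combined <- combine_methods(dna, morph, tree, study$categories)
  coverage <- method_coverage(dna, morph)
  note("combine_methods", occurrences = nrow(combined),
       coverage = as.list(coverage))

  food <- remove_nonfood(combined, tree, config$filter,
                         categories = study$categories)
  note("remove_nonfood", n_in = nrow(combined), n_out = nrow(food),
       removal_log = as.list(attr(food, "removal_log")))

  gmap <- default_group_map()
  taxa_matrix <- records_to_matrix(food)
  groups <- map_to_groups(taxa_matrix, gmap, attr(gmap, "unassigned"))
  groups <- drop_rare_groups(groups, config$min_samples)
  dropped <- attr(groups, "dropped_groups")
  # samples left with no group after rarity filtering carry no information
  groups <- groups[rowSums(groups) > 0, , drop = FALSE]
  note("group", n_samples = nrow(groups), n_groups = ncol(groups),
       occurrences = sum(groups), dropped_groups = dropped)

  covars <- build_covariates(study$world$meta, study$world$spatial)
  covars$longitude <- covars$lon
  covars$latitude <- covars$lat
  note("covariates", n = nrow(covars))

  dat <- covars[match(rownames(groups), covars$otter_id), ]
  sel <- NULL
  terms <- config$terms
  if (isTRUE(config$stepwise)) {
    set.seed(config$seed)
    sel <- stepwise_aic(groups, dat, config$candidate_terms)
    terms <- intersect(config$terms, sel$terms)
    if (!length(terms)) terms <- config$terms
  }
  anova <- mglm_anova(groups, dat, terms, B = config$B, seed = config$seed)
  note("mglm", terms = terms, B = config$B,
       deviance = as.list(setNames(anova$table$deviance, terms)),
       p = as.list(setNames(anova$table$p, terms)),
       n_dropped_rows = anova$n_dropped)

  fo <- frequency_of_occurrence(groups)
  manifest$mean_groups_per_sample <- mean_taxa_per_sample(groups)
  manifest$hash <- rlang::hash(manifest)
  structure(list(manifest = manifest, combined = combined,
                 group_matrix = groups, covariates = covars,
                 anova = anova, fo = fo, stepwise = sel,
                 marker_partition = marker_partition,
                 method_coverage = coverage),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$group_matrix), " samples x ",
      ncol(x$group_matrix), " prey groups; mean ",
      round(x$manifest$mean_groups_per_sample, 2),
      " groups per sample\n", sep = "")
  print(x$anova)
  invisible(x)
}

#' Write a run manifest as JSON
#' @param manifest from a `pipeline_result`
#' @param path output path
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Write a pipeline configuration as YAML
#'
#' The simulation section is stored as the scalar arguments of
#' [sim_config()] (seed, sample size and any effect overrides are
#' reconstructed on read), so the file round-trips through
#' [read_pipeline_config()].
#' @param config from [pipeline_config()]
#' @param path output path
#' @export
write_pipeline_config <- function(config, path) {
  flat <- config
  flat$sim <- list(seed = config$sim$seed, n_otters = config$sim$n_otters,
                   alpha = as.list(config$sim$group_params$alpha),
                   beta_lon = as.list(config$sim$group_params$beta_lon),
                   beta_coast = as.list(config$sim$group_params$beta_coast))
  flat$filter <- list(
    proportional_threshold = as.list(config$filter$proportional_threshold),
    allowed_kingdom = config$filter$allowed_kingdom,
    consumer_taxon = config$filter$consumer_taxon,
    coarse_blocklist = config$filter$coarse_blocklist,
    min_body_mm = config$filter$min_body_mm)
  yaml::write_yaml(flat, path)
}

#' Read a pipeline configuration from YAML
#' @param path file written by [write_pipeline_config()]
#' @return a configuration list as from [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  config <- pipeline_config(seed = y$seed, n_otters = y$sim$n_otters,
                            terms = unlist(y$terms), B = y$B,
                            min_samples = y$min_samples,
                            stepwise = isTRUE(y$stepwise),
                            candidate_terms = unlist(y$candidate_terms))
  config$blocklist <- unlist(y$blocklist)
  config$sim <- sim_config(y$sim$seed, n_otters = y$sim$n_otters,
                           alpha = unlist(y$sim$alpha),
                           beta_lon = unlist(y$sim$beta_lon),
                           beta_coast = unlist(y$sim$beta_coast))
  config$filter <- filter_config(
    proportional_threshold = unlist(y$filter$proportional_threshold),
    allowed_kingdom = y$filter$allowed_kingdom,
    consumer_taxon = y$filter$consumer_taxon,
    coarse_blocklist = as.character(unlist(y$filter$coarse_blocklist)),
    min_body_mm = y$filter$min_body_mm)
  config
}
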