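#' Default synthetic prey taxonomy
#'
#' A compact forest emulating the taxonomic structure of a riverine otter
#' diet study: fish clades resolved to species below family, amphibians,
#' waterfowl, crayfish and a mollusc, the consumer itself (Lutra lutra),
#' plus non-animal taxa (a diatom, a fungus) and marine mock-community
#' species that should never appear as diet.
#'
#' @return a [taxonomy()]
#' @export
default_taxonomy <- function() {
  n <- function(id, name, rank, parent)
    data.frame(id = id, name = name, rank = rank, parent_id = parent,
               stringsAsFactors = FALSE)
  df <- rbind(
    n("Animalia", "Animalia", "kingdom", NA),
    n("Chromista", "Chromista", "kingdom", NA),
    n("Fungi", "Fungi", "kingdom", NA),
    n("Chordata", "Chordata", "phylum", "Animalia"),
    n("Arthropoda", "Arthropoda", "phylum", "Animalia"),
    n("Mollusca", "Mollusca", "phylum", "Animalia"),
    n("Actinopterygii", "Actinopterygii", "class", "Chordata"),
    n("Amphibia", "Amphibia", "class", "Chordata"),
    n("Aves", "Aves", "class", "Chordata"),
    n("Mammalia", "Mammalia", "class", "Chordata"),
    n("Malacostraca", "Malacostraca", "class", "Arthropoda"),
    n("Gastropoda", "Gastropoda", "class", "Mollusca"),
    n("Salmoniformes", "Salmoniformes", "order", "Actinopterygii"),
    n("Cypriniformes", "Cypriniformes", "order", "Actinopterygii"),
    n("Perciformes", "Perciformes", "order", "Actinopterygii"),
    n("Scorpaeniformes", "Scorpaeniformes", "order", "Actinopterygii"),
    n("Anguilliformes", "Anguilliformes", "order", "Actinopterygii"),
    n("Gasterosteiformes", "Gasterosteiformes", "order", "Actinopterygii"),
    n("Pleuronectiformes", "Pleuronectiformes", "order", "Actinopterygii"),
    n("Gobiiformes", "Gobiiformes", "order", "Actinopterygii"),
    n("Anura", "Anura", "order", "Amphibia"),
    n("Anseriformes", "Anseriformes", "order", "Aves"),
    n("Carnivora", "Carnivora", "order", "Mammalia"),
    n("Decapoda", "Decapoda", "order", "Malacostraca"),
    n("Salmonidae", "Salmonidae", "family", "Salmoniformes"),
    n("Cyprinidae", "Cyprinidae", "family", "Cypriniformes"),
    n("Percidae", "Percidae", "family", "Perciformes"),
    n("Cottidae", "Cottidae", "family", "Scorpaeniformes"),
    n("Anguillidae", "Anguillidae", "family", "Anguilliformes"),
    n("Gasterosteidae", "Gasterosteidae", "family", "Gasterosteiformes"),
    n("Pleuronectidae", "Pleuronectidae", "family", "Pleuronectiformes"),
    n("Gobiidae", "Gobiidae", "family", "Gobiiformes"),
    n("Scombridae", "Scombridae", "family", "Perciformes"),
    n("Ranidae", "Ranidae", "family", "Anura"),
    n("Bufonidae", "Bufonidae", "family", "Anura"),
    n("Anatidae", "Anatidae", "family", "Anseriformes"),
    n("Mustelidae", "Mustelidae", "family", "Carnivora"),
    n("Astacidae", "Astacidae", "family", "Decapoda"),
    n("Salmo", "Salmo", "genus", "Salmonidae"),
    n("Scardinius", "Scardinius", "genus", "Cyprinidae"),
    n("Rutilus", "Rutilus", "genus", "Cyprinidae"),
    n("Leuciscus", "Leuciscus", "genus", "Cyprinidae"),
    n("Cyprinus", "Cyprinus", "genus", "Cyprinidae"),
    n("Perca", "Perca", "genus", "Percidae"),
    n("Cottus", "Cottus", "genus", "Cottidae"),
    n("Anguilla", "Anguilla", "genus", "Anguillidae"),
    n("Gasterosteus", "Gasterosteus", "genus", "Gasterosteidae"),
    n("Platichthys", "Platichthys", "genus", "Pleuronectidae"),
    n("Pomatoschistus", "Pomatoschistus", "genus", "Gobiidae"),
    n("Thunnus", "Thunnus", "genus", "Scombridae"),
    n("Rana", "Rana", "genus", "Ranidae"),
    n("Bufo", "Bufo", "genus", "Bufonidae"),
    n("Anas", "Anas", "genus", "Anatidae"),
    n("Lutra", "Lutra", "genus", "Mustelidae"),
    n("Austropotamobius", "Austropotamobius", "genus", "Astacidae"),
    n("Pacifastacus", "Pacifastacus", "genus", "Astacidae"),
    n("Lymnaea", "Lymnaea", "genus", "Gastropoda"),
    n("Salmo_trutta", "Salmo trutta", "species", "Salmo"),
    n("Salmo_salar", "Salmo salar", "species", "Salmo"),
    n("Scardinius_erythrophthalmus", "Scardinius erythrophthalmus",
      "species", "Scardinius"),
    n("Rutilus_rutilus", "Rutilus rutilus", "species", "Rutilus"),
    n("Leuciscus_leuciscus", "Leuciscus leuciscus", "species", "Leuciscus"),
    n("Cyprinus_carpio", "Cyprinus carpio", "species", "Cyprinus"),
    n("Perca_fluviatilis", "Perca fluviatilis", "species", "Perca"),
    n("Cottus_gobio", "Cottus gobio", "species", "Cottus"),
    n("Anguilla_anguilla", "Anguilla anguilla", "species", "Anguilla"),
    n("Gasterosteus_aculeatus", "Gasterosteus aculeatus", "species",
      "Gasterosteus"),
    n("Platichthys_flesus", "Platichthys flesus", "species", "Platichthys"),
    n("Pomatoschistus_microps", "Pomatoschistus microps", "species",
      "Pomatoschistus"),
    n("Thunnus_thynnus", "Thunnus thynnus", "species", "Thunnus"),
    n("Rana_temporaria", "Rana temporaria", "species", "Rana"),
    n("Bufo_bufo", "Bufo bufo", "species", "Bufo"),
    n("Anas_platyrhynchos", "Anas platyrhynchos", "species", "Anas"),
    n("Lutra_lutra", "Lutra lutra", "species", "Lutra"),
    n("Austropotamobius_pallipes", "Austropotamobius pallipes", "species",
      "Austropotamobius"),
    n("Pacifastacus_leniusculus", "Pacifastacus leniusculus", "species",
      "Pacifastacus"),
    n("Lymnaea_stagnalis", "Lymnaea stagnalis", "species", "Lymnaea"),
    n("Navicula_spp", "Navicula (diatom)", "species", "Chromista"),
    n("Candida_spp", "Candida (yeast)", "species", "Fungi"))
  taxonomy(df)
}

#' Default prey groups and their member taxa
#'
#' Groups aggregate taxa by taxonomy, morphology and ecological niche;
#' family-level ids map to a group only where the family is unambiguous.
#' Ambiguous coarse ids (Salmonidae, Salmo, Cyprinidae) are listed in the
#' `unassigned` attribute and dropped at grouping time.
#'
#' @return data.frame (taxon, group) with attribute `unassigned`
#' @export
default_group_map <- function() {
  gm <- rbind(
    c("Salmo_trutta", "brown_trout"),
    c("Salmo_salar", "salmon"),
    c("Scardinius_erythrophthalmus", "rudd_roach"),
    c("Rutilus_rutilus", "rudd_roach"),
    c("Leuciscus_leuciscus", "dace"),
    c("Cyprinus_carpio", "carp"),
    c("Perca_fluviatilis", "perch"), c("Percidae", "perch"),
    c("Cottus_gobio", "bullhead"), c("Cottidae", "bullhead"),
    c("Anguilla_anguilla", "eel"), c("Anguillidae", "eel"),
    c("Gasterosteus_aculeatus", "stickleback"),
    c("Gasterosteidae", "stickleback"),
    c("Platichthys_flesus", "flatfish"), c("Pleuronectidae", "flatfish"),
    c("Pomatoschistus_microps", "goby"), c("Gobiidae", "goby"),
    c("Rana_temporaria", "amphibian"), c("Bufo_bufo", "amphibian"),
    c("Ranidae", "amphibian"), c("Bufonidae", "amphibian"),
    c("Anura", "amphibian"),
    c("Anas_platyrhynchos", "waterfowl"), c("Anatidae", "waterfowl"),
    c("Austropotamobius_pallipes", "crayfish"),
    c("Pacifastacus_leniusculus", "crayfish"), c("Astacidae", "crayfish"),
    c("Lymnaea_stagnalis", "mollusc"), c("Gastropoda", "mollusc"),
    c("rudd_roach_morph", "rudd_roach"),
    c("crayfish_morph", "crayfish"))
  df <- data.frame(taxon = gm[, 1], group = gm[, 2], stringsAsFactors = FALSE)
  attr(df, "unassigned") <- c("Salmonidae", "Salmo", "Cyprinidae", "Aves",
                              "Actinopterygii", "Thunnus_thynnus",
                              "Scombridae")
  df
}

#' Default morphological identification categories
#' @param tree a [taxonomy()]
#' @return [morph_categories()] with the composite "rudd/roach" label and a
#'   composite crayfish label (morphology cannot separate the two species)
#' @export
default_morph_categories <- function(tree = default_taxonomy()) {
  morph_categories(
    labels = c("rudd_roach_morph", "crayfish_morph"),
    members = list(c("Scardinius_erythrophthalmus", "Rutilus_rutilus"),
                   c("Austropotamobius_pallipes", "Pacifastacus_leniusculus")),
    tree = tree)
}

# Per-group cloglog intercepts chosen so that baseline prevalences span
# the realistic range for a generalist otter diet (a few dominant fish
# groups near 0.25-0.40, a long tail of rarer groups).
default_group_params <- function() {
  prev <- c(stickleback = 0.39, brown_trout = 0.37, eel = 0.26,
            bullhead = 0.24, amphibian = 0.15, rudd_roach = 0.12,
            perch = 0.10, salmon = 0.08, crayfish = 0.08, dace = 0.06,
            waterfowl = 0.06, flatfish = 0.05, goby = 0.05, carp = 0.04,
            mollusc = 0.04)
  alpha <- log(-log(1 - prev))
  beta_lon <- c(stickleback = 0, brown_trout = -0.5, eel = 0,
                bullhead = 0, amphibian = -0.4, rudd_roach = 0.5,
                perch = 0.4, salmon = -0.5, crayfish = 0, dace = 0.4,
                waterfowl = 0, flatfish = -0.4, goby = -0.4, carp = 0.3,
                mollusc = 0)
  beta_coast <- c(stickleback = 0, brown_trout = 0, eel = -0.5,
                  bullhead = 0.4, amphibian = 0, rudd_roach = 0,
                  perch = 0, salmon = 0, crayfish = 0, dace = 0,
                  waterfowl = 0, flatfish = -0.5, goby = -0.5, carp = 0,
                  mollusc = 0)
  list(alpha = alpha, beta_lon = beta_lon[names(prev)],
       beta_coast = beta_coast[names(prev)])
}

# Member taxa per group with within-group draw weights (first member is
# the common one).
default_group_members <- function() {
  list(stickleback = c(Gasterosteus_aculeatus = 0.9),
       brown_trout = c(Salmo_trutta = 0.9),
       eel = c(Anguilla_anguilla = 0.9),
       bullhead = c(Cottus_gobio = 0.9),
       amphibian = c(Rana_temporaria = 0.7, Bufo_bufo = 0.3),
       rudd_roach = c(Rutilus_rutilus = 0.6,
                      Scardinius_erythrophthalmus = 0.4),
       perch = c(Perca_fluviatilis = 0.9),
       salmon = c(Salmo_salar = 0.9),
       crayfish = c(Austropotamobius_pallipes = 0.55,
                    Pacifastacus_leniusculus = 0.45),
       dace = c(Leuciscus_leuciscus = 0.9),
       waterfowl = c(Anas_platyrhynchos = 0.9),
       flatfish = c(Platichthys_flesus = 0.9),
       goby = c(Pomatoschistus_microps = 0.9),
       carp = c(Cyprinus_carpio = 0.9),
       mollusc = c(Lymnaea_stagnalis = 0.9))
}

# COI resolution ceilings: some vertebrates are only recoverable at family
# level with an invertebrate-targeted marker.
default_coi_ceiling <- function() {
  c(Rana_temporaria = "Ranidae", Bufo_bufo = "Bufonidae",
    Anas_platyrhynchos = "Anatidae",
    Scardinius_erythrophthalmus = "Cyprinidae",
    Rutilus_rutilus = "Cyprinidae")
}

# Morphological coarsening: hard parts identify some taxa only to a
# composite category or family.
default_morph_coarsening <- function() {
  c(Scardinius_erythrophthalmus = "rudd_roach_morph",
    Rutilus_rutilus = "rudd_roach_morph",
    Austropotamobius_pallipes = "crayfish_morph",
    Pacifastacus_leniusculus = "crayfish_morph",
    Salmo_salar = "Salmonidae",
    Rana_temporaria = "Ranidae", Bufo_bufo = "Bufonidae",
    Anas_platyrhynchos = "Anatidae",
    Leuciscus_leuciscus = "Cyprinidae")
}

#' Generator configuration for the synthetic study
#'
#' Defaults emulate the study conditions: ~300 individuals spread over a
#' west-east longitudinal gradient and a coastal-distance gradient, two
#' markers with complementary taxonomic coverage and resolution ceilings,
#' log-normal read depths, low-level contamination and tag jumping that
#' also reach negative controls and unused tag combinations, and sparser,
#' coarser morphological detections. Effect sizes are link-scale
#' coefficients applied to z-standardised longitude and coast distance.
#'
#' @param seed integer seed; all stage randomness derives from it
#' @param n_otters number of fecal samples
#' @param beta_lon,beta_coast named numeric overrides of per-group
#'   link-scale effects (defaults carry west-leaning salmonids/amphibians,
#'   east-leaning cyprinids/percids, coastal eels/flatfish/gobies)
#' @param alpha named numeric overrides of per-group intercepts
#' @param detect_16S_vert,detect_16S_invert,detect_COI_vert,detect_COI_invert
#'   per-detection probabilities by marker and clade
#' @param depth_meanlog,depth_sdlog log-normal read-depth parameters
#' @param contamination_rate expected stray reads per cell (Poisson mean),
#'   applied to fecal and control libraries alike
#' @param tag_jump_rate fraction of a taxon's mean fecal read count leaking
#'   into each unused-tag library
#' @param hard_part_prob probability a true prey leaves identifiable hard
#'   parts
#' @param secondary_insect_prob,secondary_mollusk_prob per-sample rates of
#'   secondary-prey morphological labels
#' @param n_controls libraries per control role (extraction negative, PCR
#'   negative, unused tag); plus 2 mock libraries
#' @param host_prob_16S,host_prob_COI per-sample probability of the
#'   consumer's own reads appearing (host carry-over)
#' @param diatom_prob per-sample probability of incidental diatom reads
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed,
                       n_otters = 300,
                       beta_lon = NULL,
                       beta_coast = NULL,
                       alpha = NULL,
                       detect_16S_vert = 0.85, detect_16S_invert = 0.15,
                       detect_COI_vert = 0.45, detect_COI_invert = 0.8,
                       depth_meanlog = 8, depth_sdlog = 1,
                       contamination_rate = 0.3,
                       tag_jump_rate = 5e-4,
                       hard_part_prob = 0.45,
                       secondary_insect_prob = 0.10,
                       secondary_mollusk_prob = 0.05,
                       n_controls = 4,
                       host_prob_16S = 0.95, host_prob_COI = 0.4,
                       diatom_prob = 0.08) {
  if (missing(seed)) stop("seed is mandatory")
  gp <- default_group_params()
  if (!is.null(alpha)) gp$alpha[names(alpha)] <- alpha
  if (!is.null(beta_lon)) gp$beta_lon[names(beta_lon)] <- beta_lon
  if (!is.null(beta_coast)) gp$beta_coast[names(beta_coast)] <- beta_coast
  probs <- c(detect_16S_vert, detect_16S_invert, detect_COI_vert,
             detect_COI_invert, hard_part_prob, secondary_insect_prob,
             secondary_mollusk_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (contamination_rate < 0 || tag_jump_rate < 0)
    stop("rates must be nonnegative")
  structure(list(seed = as.integer(seed), n_otters = n_otters,
                 group_params = gp,
                 group_members = default_group_members(),
                 coi_ceiling = default_coi_ceiling(),
                 morph_coarsening = default_morph_coarsening(),
                 detect = c("16S_vert" = detect_16S_vert,
                            "16S_invert" = detect_16S_invert,
                            "COI_vert" = detect_COI_vert,
                            "COI_invert" = detect_COI_invert),
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 contamination_rate = contamination_rate,
                 tag_jump_rate = tag_jump_rate,
                 hard_part_prob = hard_part_prob,
                 secondary_insect_prob = secondary_insect_prob,
                 secondary_mollusk_prob = secondary_mollusk_prob,
                 n_controls = n_controls,
                 host_prob_16S = host_prob_16S,
                 host_prob_COI = host_prob_COI,
                 diatom_prob = diatom_prob),
            class = "sim_config")
}

stage_seed <- function(cfg, stage) {
  offsets <- c(world = 0L, diets = 1000003L, reads16S = 2000003L,
               readsCOI = 3000017L, morph = 4000037L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Generate the synthetic world: taxonomy, otter metadata, spatial inputs
#'
#' Morphometrics follow a mass-length power law with log-normal noise;
#' locations span a west-east longitude gradient; river-network spatial
#' inputs (candidate coast distances, transitional/lake proximity, channel
#' lengths) are drawn so that all four habitat classes occur.
#'
#' @param cfg a [sim_config()]
#' @return list: `tree`, `meta`, `spatial`
#' @export
generate_world <- function(cfg) {
  set.seed(stage_seed(cfg, "world"))
  tree <- default_taxonomy()
  n <- cfg$n_otters
  id <- sprintf("otter_%03d", seq_len(n))
  sex <- ifelse(runif(n) < 0.5, "M", "F")
  length_mm <- ifelse(sex == "M", rnorm(n, 1090, 60), rnorm(n, 985, 55))
  length_mm <- round(pmax(length_mm, 600) / 5) * 5   # measured to 5 mm
  mass_g <- round(exp(-10.49 + 2.8 * log(length_mm) + rnorm(n, 0, 0.08)))
  meta <- data.frame(otter_id = id, sex = sex, length_mm = length_mm,
                     mass_g = mass_g,
                     year = sample(2007:2016, n, replace = TRUE),
                     month = sample(1:12, n, replace = TRUE),
                     lat = runif(n, 50.5, 54.5),
                     lon = runif(n, -5.5, -0.5),
                     pct_urban = stats::rbeta(n, 1.5, 10),
                     stringsAsFactors = FALSE)
  true_coast <- pmin(stats::rexp(n, 1 / 25), 120)
  coastal <- true_coast < 1
  n_cand <- sample(1:3, n, replace = TRUE)
  cand <- lapply(seq_len(n), function(i)
    pmax(true_coast[i] + rnorm(n_cand[i], 0, 0.5), 0.05))
  spatial <- data.frame(otter_id = id,
                        within_1km_coast = coastal,
                        closer_to_coast_than_river = coastal,
                        dist_transitional = ifelse(coastal,
                                                   runif(n, 0, 2.4),
                                                   runif(n, 2.6, 80)),
                        dist_lake = runif(n, 0.5, 60),
                        main_channel_length = runif(n, 0, 12),
                        tributary_length = runif(n, 5, 60),
                        stringsAsFactors = FALSE)
  spatial$candidate_river_distances <-
    vapply(cand, function(v) paste(round(v, 3), collapse = ";"), character(1))
  list(tree = tree, meta = meta, spatial = spatial)
}

#' Generate true diets under a cloglog model on longitude and coast distance
#'
#' Each prey group is present in each individual with probability
#' `1 - exp(-exp(eta))`, `eta = alpha_g + beta_lon_g * z(lon) +
#' beta_coast_g * z(coast)` — the same link the analysis model fits, so
#' parameter recovery is well-posed. Member taxa of a present group are
#' drawn by their configured weights (at least one).
#'
#' @param world from [generate_world()]
#' @param cfg a [sim_config()]
#' @return list of class `truth`: `group_matrix` (otter x group),
#'   `taxa` (long data.frame otter_id/taxon/group), `coast_distance`,
#'   standardisation constants, `cfg`
#' @export
generate_true_diets <- function(world, cfg) {
  set.seed(stage_seed(cfg, "diets"))
  meta <- world$meta
  sp <- world$spatial
  cand <- lapply(strsplit(sp$candidate_river_distances, ";"), as.numeric)
  coast <- vapply(seq_len(nrow(sp)), function(i)
    river_distance(cand[[i]], sp$within_1km_coast[i],
                   sp$closer_to_coast_than_river[i]), numeric(1))
  z <- function(x) {
    s <- sd(x)
    if (length(x) < 2 || is.na(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  zlon <- z(meta$lon); zcoast <- z(coast)
  gp <- cfg$group_params
  groups <- names(gp$alpha)
  G <- length(groups)
  n <- nrow(meta)
  gm <- matrix(0L, n, G, dimnames = list(meta$otter_id, groups))
  rows <- list()
  for (g in seq_len(G)) {
    eta <- gp$alpha[g] + gp$beta_lon[g] * zlon + gp$beta_coast[g] * zcoast
    p <- 1 - exp(-exp(pmin(eta, 3)))
    gm[, g] <- rbinom(n, 1, p)
    mem <- cfg$group_members[[groups[g]]]
    for (i in which(gm[, g] == 1)) {
      pick <- names(mem)[runif(length(mem)) < mem]
      if (!length(pick))
        pick <- sample(names(mem), 1, prob = mem)
      rows[[length(rows) + 1]] <-
        data.frame(otter_id = meta$otter_id[i], taxon = pick,
                   group = groups[g], stringsAsFactors = FALSE)
    }
  }
  taxa <- if (length(rows)) do.call(rbind, rows) else
    data.frame(otter_id = character(0), taxon = character(0),
               group = character(0))
  structure(list(group_matrix = gm, taxa = taxa, coast_distance = coast,
                 lon_mean = mean(meta$lon), lon_sd = sd(meta$lon),
                 coast_mean = mean(coast), coast_sd = sd(coast),
                 cfg = cfg),
            class = "truth")
}

is_vertebrate <- function(tree, ids) {
  vapply(ids, function(t) "Chordata" %in% lineage(tree, t), logical(1))
}

#' Generate a per-marker read table from the true diets
#'
#' True prey taxa are detected with marker- and clade-specific
#' probabilities; COI emits some vertebrates only at its family-level
#' resolution ceiling. Detected taxa receive log-normal read depths; host
#' (otter) reads and occasional diatom reads are added as realistic
#' non-food signal. Contamination adds independent low-mean Poisson counts
#' to every cell — fecal and control libraries alike — and tag jumping
#' adds donor-proportional counts to unused-tag libraries. Cells whose
#' reads are purely contamination are recorded for truth-aware filter
#' validation.
#'
#' @param world from [generate_world()]
#' @param truth from [generate_true_diets()]
#' @param cfg a [sim_config()]
#' @param marker `"16S"` or `"COI"`
#' @return list: `table` (a [read_table()]), `contamination_cells`
#'   (data.frame sample_id/taxon of contamination-only fecal cells)
#' @export
generate_reads <- function(world, truth, cfg, marker = c("16S", "COI")) {
  marker <- match.arg(marker)
  set.seed(stage_seed(cfg, if (marker == "16S") "reads16S" else "readsCOI"))
  tree <- world$tree
  otters <- world$meta$otter_id
  nc <- cfg$n_controls
  ctrl <- c(sprintf("extneg_%s_%d", marker, seq_len(nc)),
            sprintf("pcrneg_%s_%d", marker, seq_len(nc)),
            sprintf("unused_%s_%d", marker, seq_len(nc)),
            sprintf("mock_%s_%d", marker, 1:2))
  roles <- c(setNames(rep("fecal", length(otters)), otters),
             setNames(rep(c("extraction_negative", "pcr_negative",
                            "unused_tag", "mock"), c(nc, nc, nc, 2)), ctrl))
  pool <- sort(unique(unlist(lapply(cfg$group_members, names))))
  all_taxa <- sort(unique(c(pool, unname(cfg$coi_ceiling), "Lutra_lutra",
                            "Navicula_spp", "Thunnus_thynnus")))
  m <- matrix(0L, length(roles), length(all_taxa),
              dimnames = list(names(roles), all_taxa))

  vert <- is_vertebrate(tree, pool)
  names(vert) <- pool
  pdet <- if (marker == "16S")
    ifelse(vert, cfg$detect[["16S_vert"]], cfg$detect[["16S_invert"]])
  else ifelse(vert, cfg$detect[["COI_vert"]], cfg$detect[["COI_invert"]])
  names(pdet) <- pool

  depth <- function(k) as.integer(round(rlnorm(k, cfg$depth_meanlog,
                                               cfg$depth_sdlog))) + 1L
  tt <- truth$taxa
  for (i in seq_len(nrow(tt))) {
    tx <- tt$taxon[i]
    if (runif(1) < pdet[[tx]]) {
      emit <- tx
      if (marker == "COI" && tx %in% names(cfg$coi_ceiling))
        emit <- cfg$coi_ceiling[[tx]]
      m[tt$otter_id[i], emit] <- m[tt$otter_id[i], emit] + depth(1)
    }
  }
  true_support <- m > 0
  # host reads dominate most fecal libraries (16S especially)
  host_p <- if (marker == "16S") cfg$host_prob_16S else cfg$host_prob_COI
  host <- otters[runif(length(otters)) < host_p]
  m[host, "Lutra_lutra"] <- m[host, "Lutra_lutra"] +
    as.integer(round(rlnorm(length(host), cfg$depth_meanlog + 1,
                            cfg$depth_sdlog)))
  diat <- otters[runif(length(otters)) < cfg$diatom_prob]
  if (length(diat)) m[diat, "Navicula_spp"] <- m[diat, "Navicula_spp"] +
    depth(length(diat))
  # mock community: marine species at high depth
  mock_rows <- names(roles)[roles == "mock"]
  m[mock_rows, "Thunnus_thynnus"] <- depth(length(mock_rows)) * 3L
  # contamination: independent low-mean counts per cell, all roles
  if (cfg$contamination_rate > 0) {
    contam <- matrix(rpois(length(m), cfg$contamination_rate), nrow(m))
    m <- m + contam
  }
  # tag jumping into unused-tag libraries, proportional to donor abundance
  if (cfg$tag_jump_rate > 0) {
    unused <- names(roles)[roles == "unused_tag"]
    donor_mean <- colMeans(m[otters, , drop = FALSE])
    donor_mean[!is.finite(donor_mean)] <- 0
    for (u in unused)
      m[u, ] <- m[u, ] + rpois(ncol(m), cfg$tag_jump_rate * donor_mean)
  }
  storage.mode(m) <- "integer"
  contam_cells <- which(m[otters, , drop = FALSE] > 0 &
                          !true_support[otters, , drop = FALSE] &
                          !(col(m[otters, , drop = FALSE]) ==
                              match("Lutra_lutra", all_taxa) &
                              rownames(m[otters, , drop = FALSE]) %in% host),
                        arr.ind = TRUE)
  contamination_cells <- data.frame(
    sample_id = otters[contam_cells[, 1]],
    taxon = all_taxa[contam_cells[, 2]], stringsAsFactors = FALSE)
  # exclude the deliberate non-food signal (host, diatoms) from the label
  keep <- !(contamination_cells$taxon == "Navicula_spp" &
              contamination_cells$sample_id %in% diat)
  contamination_cells <- contamination_cells[keep, , drop = FALSE]
  list(table = read_table(m, roles, marker),
       contamination_cells = contamination_cells)
}

#' Generate morphological detections from the true diets
#'
#' Each true prey leaves identifiable hard parts with probability
#' `hard_part_prob`; identified taxa pass through the coarsening map
#' (species to family or composite category), and secondary-prey labels
#' (insect, mollusk) are injected at configured per-sample rates for
#' blocklist testing.
#'
#' @inheritParams generate_reads
#' @return `presence_records` with channel `"morphology"`
#' @export
generate_morphology <- function(world, truth, cfg) {
  set.seed(stage_seed(cfg, "morph"))
  tt <- truth$taxa
  det <- tt[runif(nrow(tt)) < cfg$hard_part_prob, , drop = FALSE]
  emit <- det$taxon
  hit <- emit %in% names(cfg$morph_coarsening)
  emit[hit] <- cfg$morph_coarsening[emit[hit]]
  recs <- data.frame(sample_id = det$otter_id, taxon = emit,
                     stringsAsFactors = FALSE)
  otters <- world$meta$otter_id
  inject <- function(p, label) {
    hit <- otters[runif(length(otters)) < p]
    if (!length(hit))
      return(data.frame(sample_id = character(0), taxon = character(0),
                        stringsAsFactors = FALSE))
    data.frame(sample_id = hit, taxon = label, stringsAsFactors = FALSE)
  }
  all <- rbind(recs,
               inject(cfg$secondary_insect_prob, "insect"),
               inject(cfg$secondary_mollusk_prob, "mollusk"))
  presence_records(all$sample_id, all$taxon, channel = "morphology")
}

#' Generate the complete synthetic study in one call
#'
#' @param cfg a [sim_config()]
#' @return list: `world`, `truth`, `reads16S`, `readsCOI`, `morph`,
#'   `categories`
#' @export
simulate_study <- function(cfg) {
  world <- generate_world(cfg)
  truth <- generate_true_diets(world, cfg)
  r16 <- generate_reads(world, truth, cfg, "16S")
  rcoi <- generate_reads(world, truth, cfg, "COI")
  morph <- generate_morphology(world, truth, cfg)
  list(world = world, truth = truth, reads16S = r16, readsCOI = rcoi,
       morph = morph, categories = default_morph_categories(world$tree))
}
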