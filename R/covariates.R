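#' Standardised major axis scaling exponent of mass on length
#'
#' Slope of the SMA regression of log(mass) on log(length):
#' `b = sign(r) * sd(log M) / sd(log L)` with `r` the Pearson correlation.
#' SMA is the appropriate line when both variables carry measurement error,
#' as in field morphometrics.
#'
#' @param masses,lengths positive numeric vectors of equal length (n >= 3)
#' @return the scaling exponent
#' @export
fit_sma_exponent <- function(masses, lengths) {
  stopifnot(length(masses) == length(lengths), length(masses) >= 3,
            all(masses > 0), all(lengths > 0))
  lm_ <- log(masses); ll <- log(lengths)
  if (sd(ll) == 0) stop("zero variance in lengths")
  r <- cor(lm_, ll)
  sign_r <- if (r < 0) -1 else 1
  sign_r * sd(lm_) / sd(ll)
}

#' Fit scaled-mass-index parameters from a population table
#'
#' @param masses,lengths population morphometrics (ideally the full
#'   reference population, not just the analysis subset)
#' @return list with `L0` (mean length) and `b_sma`
#' @export
fit_smi_params <- function(masses, lengths) {
  list(L0 = mean(lengths), b_sma = fit_sma_exponent(masses, lengths))
}

#' Scaled mass index
#'
#' Length-standardised body condition: `SMI = M * (L0 / L)^b`, the mass the
#' individual would have at the population mean length assuming the fitted
#' mass-length scaling.
#'
#' @param mass body mass (g)
#' @param length body length (mm)
#' @param params list with `L0` and `b_sma` (see [fit_smi_params()])
#' @return SMI in grams
#' @export
smi <- function(mass, length, params) {
  if (any(length <= 0)) stop("nonpositive length")
  mass * (params$L0 / length)^params$b_sma
}

#' Jenks natural breaks (Fisher optimal 1-D partition)
#'
#' Partitions sorted values into `k` contiguous classes minimising the total
#' within-class sum of squared deviations, by dynamic programming. The
#' solution is deterministic; ties between equal-cost partitions are broken
#' by preferring the lowest feasible break.
#'
#' @param values numeric vector
#' @param k number of classes (1 <= k <= number of distinct values)
#' @return list: `classes` (per-value class index, 1 = lowest), `breaks`
#'   (the k-1 internal break points, each the minimum value of the next
#'   class), `withinss` (total within-class SS)
#' @export
jenks_breaks <- function(values, k) {
  stopifnot(k >= 1)
  n_distinct <- length(unique(values))
  if (k > n_distinct) stop("k exceeds the number of distinct values")
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # ss(i, j): within-SS of x[i..j], via prefix sums
  ss <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # D[m, j]: minimal cost of splitting x[1..j] into m classes
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)   # start index of the last class in the optimum
  D[1, ] <- vapply(seq_len(n), function(j) ss(1, j), numeric(1))
  B[1, ] <- 1L
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        starts <- m:j
        costs <- D[m - 1, starts - 1] +
          vapply(starts, function(i) ss(i, j), numeric(1))
        best <- which(costs <= min(costs) + 1e-12)[1]  # lowest break on ties
        D[m, j] <- costs[best]
        B[m, j] <- starts[best]
      }
    }
  }
  cls_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- B[m, j]
    cls_sorted[i:j] <- m
    j <- i - 1
  }
  classes <- integer(n)
  classes[ord] <- cls_sorted
  breaks <- if (k > 1)
    vapply(2:k, function(m) min(x[cls_sorted == m]), numeric(1))
  else numeric(0)
  list(classes = classes, breaks = breaks, withinss = D[k, n])
}

#' Sex-specific body-length size classes from Jenks clustering
#'
#' @param lengths,sexes vectors over the reference population
#' @return named list mapping sex to its two internal break values
#'   (`c(b1, b2)`: small below `b1`, medium in `[b1, b2]`, large above)
#' @export
fit_size_breaks <- function(lengths, sexes) {
  out <- lapply(split(lengths, sexes), function(l) {
    jb <- jenks_breaks(l, 3)
    c(jb$breaks[1], max(l[jb$classes == 2]))
  })
  out
}

#' Assign a size class from length and sex-specific breaks
#'
#' Boundary convention: the medium interval is closed (`b1 <= L <= b2`), so
#' an individual exactly at a break falls in the class whose printed
#' interval includes it.
#'
#' @param length body length (mm)
#' @param sex `"M"` or `"F"`
#' @param breaks_by_sex named list of `c(b1, b2)` per sex (see
#'   [fit_size_breaks()])
#' @return `"small"`, `"medium"` or `"large"`
#' @export
size_class <- function(length, sex, breaks_by_sex) {
  br <- breaks_by_sex[[sex]]
  if (is.null(br)) stop("unknown sex: ", sex)
  ifelse(length < br[1], "small", ifelse(length <= br[2], "medium", "large"))
}

#' Distance from the coast along the river network
#'
#' Individuals found within 1 km of the coastline and closer to the coast
#' than to any river are assigned distance zero; otherwise the mean of the
#' candidate river distances is used (several candidates arise when the
#' carcass location does not pin down the river travelled).
#'
#' @param candidates numeric vector of river distances (km)
#' @param within_1km_coast,closer_to_coast_than_river logicals
#' @return distance in km
#' @export
river_distance <- function(candidates, within_1km_coast,
                           closer_to_coast_than_river) {
  if (within_1km_coast && closer_to_coast_than_river) return(0)
  if (!length(candidates)) stop("no candidate river distances")
  mean(candidates)
}

#' Assign the primary water habitat of an individual
#'
#' Transitional (coastal/estuarine) or lake habitat applies when the
#' individual lies within 2.5 km (half a 10-km buffer's radius) of such a
#' waterbody, transitional taking precedence; otherwise the buffer's river
#' network decides: main channel lengths are weighted 10x relative to
#' tributaries (greater channel cross-section supports more prey) and the
#' habitat is main channel iff the weighted main share strictly exceeds
#' 50% (ties go to tributary).
#'
#' @param dist_transitional,dist_lake distances (km)
#' @param main_channel_length,tributary_length channel lengths within the
#'   10-km buffer (km)
#' @param main_weight weighting of main channel length
#' @return one of `"transitional"`, `"lake"`, `"main"`, `"tributary"`
#' @export
assign_habitat <- function(dist_transitional, dist_lake,
                           main_channel_length, tributary_length,
                           main_weight = 10) {
  if (dist_transitional <= 2.5) return("transitional")
  if (dist_lake <= 2.5) return("lake")
  if (main_channel_length == 0 && tributary_length == 0)
    stop("no river network in buffer")
  share <- main_weight * main_channel_length /
    (main_weight * main_channel_length + tributary_length)
  if (share > 0.5) "main" else "tributary"
}

#' Meteorological season from month
#' @param month integer 1..12
#' @return `"winter"`, `"spring"`, `"summer"` or `"autumn"`
#' @export
season_from_month <- function(month) {
  stopifnot(all(month %in% 1:12))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[month]
}

#' Build the per-individual covariate table
#'
#' Augments metadata with SMI (parameters fitted on the reference
#' population), Jenks size class, season, river distance to the coast and
#' primary water habitat.
#'
#' @param meta data.frame: `otter_id`, `sex`, `length_mm`, `mass_g`,
#'   `year`, `month`, `lat`, `lon`, `pct_urban`
#' @param spatial data.frame: `otter_id`, `candidate_river_distances`
#'   (list column or semicolon-separated string, km), `within_1km_coast`,
#'   `closer_to_coast_than_river`, `dist_transitional`, `dist_lake`,
#'   `main_channel_length`, `tributary_length`
#' @param reference optional data.frame with `mass_g`, `length_mm`, `sex`
#'   for fitting SMI and size breaks; defaults to `meta`
#' @return `meta` with `smi`, `size_class`, `season`, `coast_distance`,
#'   `habitat` columns appended
#' @export
build_covariates <- function(meta, spatial, reference = meta) {
  params <- fit_smi_params(reference$mass_g, reference$length_mm)
  breaks <- fit_size_breaks(reference$length_mm, reference$sex)
  meta$smi <- smi(meta$mass_g, meta$length_mm, params)
  meta$size_class <- vapply(seq_len(nrow(meta)), function(i)
    size_class(meta$length_mm[i], meta$sex[i], breaks), character(1))
  meta$season <- season_from_month(meta$month)
  sp <- spatial[match(meta$otter_id, spatial$otter_id), ]
  cand <- sp$candidate_river_distances
  if (!is.list(cand))
    cand <- lapply(strsplit(as.character(cand), ";"), as.numeric)
  meta$coast_distance <- vapply(seq_len(nrow(meta)), function(i)
    river_distance(cand[[i]], sp$within_1km_coast[i],
                   sp$closer_to_coast_than_river[i]), numeric(1))
  meta$habitat <- vapply(seq_len(nrow(meta)), function(i)
    assign_habitat(sp$dist_transitional[i], sp$dist_lake[i],
                   sp$main_channel_length[i], sp$tributary_length[i]),
    character(1))
  meta
}
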