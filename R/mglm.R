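#' Fit a binomial GLM with complementary log-log link
#'
#' Iteratively reweighted least squares to the binomial likelihood with
#' link `g(p) = log(-log(1 - p))`, converged when the deviance changes by
#' less than `tol` (default 1e-8) within 100 iterations. Fitted
#' probabilities are clamped to `[1e-10, 1 - 1e-10]`. A separated response
#' (all zeros or all ones) returns a flagged non-convergent fit rather
#' than an error, so resampling loops never die on a degenerate draw.
#'
#' @param y binary response vector
#' @param X design matrix, full column rank on the modelled rows
#' @return list of class `cloglog_fit`: `coefficients`, `fitted`,
#'   `deviance`, `aic` (`deviance + 2 * n coefficients`), `converged`,
#'   `iter`
#' @export
fit_binomial_cloglog <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  f <- cloglog_fit_cpp(as.numeric(y), X)
  structure(list(coefficients = setNames(drop(f$coefficients), colnames(X)),
                 fitted = drop(f$fitted),
                 deviance = f$deviance,
                 aic = f$deviance + 2 * ncol(X),
                 converged = f$converged,
                 iter = f$iter),
            class = "cloglog_fit")
}

# Build a treatment-coded design matrix from a term list. Character
# columns become factors with lexically sorted levels so coding is
# deterministic. Empty term set -> intercept only.
build_design <- function(data, terms) {
  data <- as.data.frame(data)
  for (j in names(data))
    if (is.character(data[[j]]))
      data[[j]] <- factor(data[[j]], levels = sort(unique(data[[j]])))
  fml <- if (length(terms)) stats::reformulate(terms) else ~1
  model.matrix(fml, data)
}

#' Drop rows with missing covariates
#'
#' @param response binary matrix
#' @param data covariate data.frame
#' @param vars covariate columns actually used
#' @return list `response`, `data`, `n_dropped`
#' @export
drop_incomplete <- function(response, data, vars) {
  vars <- intersect(unique(unlist(strsplit(vars, ":"))), names(data))
  ok <- stats::complete.cases(data[, vars, drop = FALSE])
  list(response = response[ok, , drop = FALSE],
       data = data[ok, , drop = FALSE],
       n_dropped = sum(!ok))
}

#' Fit independent cloglog GLMs to every column of a binary response
#'
#' The multivariate model is a stack of per-prey-group binomial GLMs over
#' one shared design matrix; the community-level statistic of any
#' comparison is the sum of the per-group likelihood-ratio deviances.
#'
#' @param Y binary sample-by-group matrix
#' @param X design matrix
#' @return object of class `mglm`: per-group `fits`, `deviance` vector,
#'   `aic` (sum of per-group AICs), the design
#' @export
manyglm_fit <- function(Y, X) {
  Y <- as.matrix(Y)
  fits <- lapply(seq_len(ncol(Y)), function(g) fit_binomial_cloglog(Y[, g], X))
  names(fits) <- colnames(Y)
  structure(list(fits = fits,
                 deviance = vapply(fits, `[[`, numeric(1), "deviance"),
                 aic = sum(vapply(fits, `[[`, numeric(1), "aic")),
                 X = X, Y = Y),
            class = "mglm")
}

#' @export
print.mglm <- function(x, ...) {
  cat("<mglm> ", ncol(x$Y), " response columns, ", nrow(x$Y), " samples, ",
      ncol(x$X), " design columns; sum-AIC ", round(x$aic, 2), "\n", sep = "")
  invisible(x)
}

# Free step-down (Westfall-Young) adjustment of per-group p-values from a
# matrix of simulated statistics (B x G) against observed statistics.
westfall_young <- function(obs, sims) {
  G <- length(obs)
  B <- nrow(sims)
  ord <- order(obs, decreasing = TRUE)     # most significant first
  q <- matrix(0, B, G)                     # successive maxima, least first
  rev_ord <- rev(ord)
  q[, 1] <- sims[, rev_ord[1]]
  if (G > 1)
    for (j in 2:G) q[, j] <- pmax(q[, j - 1], sims[, rev_ord[j]])
  p <- numeric(G)
  for (j in seq_len(G)) {
    pos <- G - j + 1                        # column of q for ord[j]
    p[ord[j]] <- (1 + sum(q[, pos] >= obs[ord[j]] - 1e-10)) / (B + 1)
  }
  # enforce step-down monotonicity along decreasing significance
  p[ord] <- cummax(p[ord])
  p
}

#' Likelihood-ratio test of one model comparison with resampling inference
#'
#' Community statistic: the sum over prey groups of the per-group deviance
#' difference between the reduced and full model. Inference is by
#' parametric bootstrap from the reduced model: each response column is
#' simulated from its reduced-model fitted probabilities, both models are
#' refitted and the statistic recomputed. The multivariate p-value uses
#' the add-one convention `(1 + #\{sim >= obs\}) / (B + 1)`. Per-group
#' p-values are adjusted by free step-down resampling over the same
#' simulated statistics.
#'
#' @param Y binary response matrix
#' @param X_full,X_reduced nested design matrices
#' @param B number of resamples (>= 99 advised; fewer warns)
#' @param seed optional integer; set for reproducible p-values
#' @return list: `deviance` (community statistic), `p` (multivariate),
#'   `group_deviance`, `group_p_adj`, `B`, `seed`
#' @export
mglm_lr_test <- function(Y, X_full, X_reduced, B = 999, seed = NULL) {
  if (B < 99) warning("B < 99 gives coarse p-value resolution")
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  full <- manyglm_fit(Y, X_full)
  red <- manyglm_fit(Y, X_reduced)
  obs <- pmax(red$deviance - full$deviance, 0)
  mu_red <- vapply(red$fits, `[[`, numeric(nrow(Y)), "fitted")
  sims <- lr_boot_cpp(mu_red, X_full, X_reduced, B)
  p_multi <- (1 + sum(rowSums(sims) >= sum(obs) - 1e-10)) / (B + 1)
  list(deviance = sum(obs), p = p_multi,
       group_deviance = setNames(obs, colnames(Y)),
       group_p_adj = setNames(westfall_young(obs, sims), colnames(Y)),
       B = B, seed = seed)
}

# droppable: no other current term contains this term's variables as a
# strict superset (marginality); addable: all main effects of an
# interaction already present.
term_vars <- function(t) strsplit(t, ":", fixed = TRUE)[[1]]

droppable_terms <- function(current) {
  vapply(current, function(t) {
    v <- term_vars(t)
    !any(vapply(setdiff(current, t), function(o) all(v %in% term_vars(o)) &&
                  length(term_vars(o)) > length(v), logical(1)))
  }, logical(1))
}

addable_terms <- function(current, candidates) {
  vapply(candidates, function(t) {
    v <- term_vars(t)
    length(v) == 1 || all(v %in% unlist(lapply(current, term_vars)))
  }, logical(1))
}

#' Stepwise term selection on the multivariate AIC
#'
#' Greedy add/drop moves on the sum over prey groups of the per-group AIC
#' (`deviance + 2 * n coefficients`), starting from the global model and
#' stopping when no single move lowers the total. Interaction terms are
#' only allowed alongside their main effects and block dropping them.
#'
#' @param Y binary response matrix
#' @param data covariate data.frame
#' @param candidates character vector of candidate terms (interactions as
#'   `"a:b"`)
#' @param start initial term set; defaults to the full candidate list
#'   (backward-leaning stepwise from the global model)
#' @return list: `terms` (selected), `aic`, `trace` (data.frame of moves)
#' @export
stepwise_aic <- function(Y, data, candidates, start = candidates) {
  Y <- as.matrix(Y)
  aic_of <- function(terms) {
    X <- build_design(data, terms)
    if (qr(X)$rank < ncol(X)) return(Inf)
    sum(many_dev_cpp(Y, X)) + 2 * ncol(X) * ncol(Y)
  }
  current <- start
  cur_aic <- aic_of(current)
  trace <- data.frame(move = "<start>",
                      aic = cur_aic, stringsAsFactors = FALSE)
  repeat {
    moves <- character(0); aics <- numeric(0); sets <- list()
    if (length(current)) {
      for (t in current[droppable_terms(current)]) {
        sets[[length(sets) + 1]] <- setdiff(current, t)
        moves <- c(moves, paste("-", t)); aics <- c(aics, NA)
      }
    }
    rem <- setdiff(candidates, current)
    if (length(rem)) {
      for (t in rem[addable_terms(current, rem)]) {
        sets[[length(sets) + 1]] <- c(current, t)
        moves <- c(moves, paste("+", t)); aics <- c(aics, NA)
      }
    }
    if (!length(sets)) break
    aics <- vapply(sets, aic_of, numeric(1))
    best <- which.min(aics)
    if (!length(best) || aics[best] >= cur_aic - 1e-8) break
    current <- sets[[best]]
    cur_aic <- aics[best]
    trace <- rbind(trace, data.frame(move = moves[best], aic = cur_aic))
  }
  list(terms = current, aic = cur_aic, trace = trace)
}

#' Sequential analysis-of-deviance table with resampling p-values
#'
#' Terms are added in the order listed; each row tests the term against
#' the model containing the preceding terms only, with [mglm_lr_test()]'s
#' parametric bootstrap. Per-group deviances and free step-down adjusted
#' p-values accompany each community test.
#'
#' @param Y binary response matrix
#' @param data covariate data.frame
#' @param terms character vector of terms, in testing order
#' @param B resamples per term
#' @param seed integer; per-term streams are derived deterministically
#' @return list of class `mglm_anova`: `table` (term, deviance, p),
#'   `group_deviance` and `group_p_adj` matrices (terms x groups),
#'   `B`, `seed`, `n_dropped` incomplete rows
#' @export
mglm_anova <- function(Y, data, terms, B = 999, seed = 1) {
  cc <- drop_incomplete(as.matrix(Y), data, terms)
  Y <- cc$response; data <- cc$data
  devs <- numeric(length(terms))
  ps <- numeric(length(terms))
  gd <- matrix(NA_real_, length(terms), ncol(Y),
               dimnames = list(terms, colnames(Y)))
  gp <- gd
  for (k in seq_along(terms)) {
    Xr <- build_design(data, terms[seq_len(k - 1)])
    Xf <- build_design(data, terms[seq_len(k)])
    res <- mglm_lr_test(Y, Xf, Xr, B = B, seed = seed + 7919L * k)
    devs[k] <- res$deviance
    ps[k] <- res$p
    gd[k, ] <- res$group_deviance
    gp[k, ] <- res$group_p_adj
  }
  structure(list(table = data.frame(term = terms, deviance = devs, p = ps,
                                    stringsAsFactors = FALSE),
                 group_deviance = gd, group_p_adj = gp,
                 B = B, seed = seed, n_dropped = cc$n_dropped),
            class = "mglm_anova")
}

#' @export
print.mglm_anova <- function(x, ...) {
  cat("Sequential multivariate analysis of deviance (",
      x$B, " resamples)\n", sep = "")
  print(transform(x$table, deviance = round(deviance, 2)))
  invisible(x)
}
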