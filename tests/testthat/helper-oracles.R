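# Fixtures built in code and brute-force oracles, independent of the
# implementation paths they check.

fixture_tree <- function() default_taxonomy()

# Random rank-ladder forest: `n` nodes attached one by one to a random
# existing node at a strictly finer rank (or as a new root).
random_tree <- function(n = 30) {
  ranks <- spraintR::RANK_LADDER
  ids <- paste0("t", seq_len(n))
  rank <- character(n); parent <- rep(NA_character_, n)
  rank[1] <- "kingdom"
  for (i in seq_len(n)[-1]) {
    if (runif(1) < 0.05) { rank[i] <- "kingdom"; next }
    cand <- which(match(rank[1:(i - 1)], ranks) < length(ranks))
    p <- cand[sample.int(length(cand), 1)]
    pr <- match(rank[p], ranks)
    finer <- (pr + 1):length(ranks)
    rank[i] <- ranks[finer[sample.int(length(finer), 1)]]
    parent[i] <- ids[p]
  }
  taxonomy(data.frame(id = ids, name = ids, rank = rank, parent_id = parent,
                      stringsAsFactors = FALSE))
}

# ancestor test by scanning the root path built directly from the table
bf_is_ancestor <- function(a, b, tree) {
  tab <- tree$table
  cur <- b
  repeat {
    p <- tab$parent_id[tab$id == cur]
    if (is.na(p)) return(FALSE)
    if (p == a) return(TRUE)
    cur <- p
  }
}

# merge oracle: union of per-sample taxa, then delete any taxon that has a
# present strict descendant in the same sample
bf_merge <- function(pa, pb, tree) {
  samples <- union(pa$sample_id, pb$sample_id)
  out <- lapply(samples, function(s) {
    u <- union(pa$taxon[pa$sample_id == s], pb$taxon[pb$sample_id == s])
    keep <- vapply(u, function(a)
      !any(vapply(u, function(b) bf_is_ancestor(a, b, tree), logical(1))),
      logical(1))
    data.frame(sample_id = s, taxon = u[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

same_presence_set <- function(recs, df) {
  a <- unique(paste(recs$sample_id, recs$taxon))
  b <- unique(paste(df$sample_id, df$taxon))
  setequal(a, b)
}

# exhaustive minimum within-class SS contiguous partition of sorted values
bf_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(list(withinss = ss(x), classes_sorted = rep(1L, n)))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; best_cls <- NULL
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    cls <- rep(seq_len(k), diff(bounds))
    tot <- sum(vapply(seq_len(k), function(m) ss(x[cls == m]), numeric(1)))
    if (tot < best - 1e-12) { best <- tot; best_cls <- cls }
  }
  list(withinss = best, classes_sorted = best_cls)
}

# negative log-likelihood of the binomial cloglog model, for the
# general-purpose optimizer oracle
nll_cloglog <- function(beta, y, X) {
  eta <- pmin(pmax(drop(X %*% beta), -30), 3)
  p <- pmin(pmax(-expm1(-exp(eta)), 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

optim_cloglog_deviance <- function(y, X) {
  fit0 <- rep(0, ncol(X))
  fit0[1] <- log(-log(1 - min(max(mean(y), 0.05), 0.95)))
  o <- optim(fit0, nll_cloglog, y = y, X = X, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  2 * o$value
}

random_read_table <- function(n_fecal = 8, n_taxa = 6, marker = "16S",
                              n_ctrl = 3, max_count = 2000) {
  taxa <- fixture_tree()$table$id[seq_len(n_taxa)]
  samples <- c(sprintf("s%02d", seq_len(n_fecal)),
               sprintf("c%02d", seq_len(n_ctrl)))
  roles <- setNames(c(rep("fecal", n_fecal),
                      sample(c("extraction_negative", "pcr_negative",
                               "unused_tag"), n_ctrl, replace = TRUE)),
                    samples)
  m <- matrix(rpois(length(samples) * n_taxa, max_count / 10) *
                rbinom(length(samples) * n_taxa, 1, 0.6),
              length(samples), n_taxa, dimnames = list(samples, taxa))
  read_table(m, roles, marker)
}
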