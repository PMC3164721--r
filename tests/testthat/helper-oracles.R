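# Independent reference implementations used as oracles. These are written
# from first principles (loops, enumeration, closed forms) and must stay
# independent of the package code paths they check.

# Type-7 quantile by direct order-statistic interpolation.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_iqr <- function(x) {
  oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25)
}

# Pooled-variance two-sample t from the textbook formula.
oracle_pooled_t <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  t <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Brute-force admission pipeline on an expression_dataset: per-reporter IQR
# filter, per-gene max-IQR reporter (ties: smallest id), annotation
# restriction, set pruning. Everything done with explicit loops.
oracle_preprocess <- function(dataset, collection, iqr_min = 0.5,
                              min_set_size = 10) {
  vals <- dataset$values
  keep <- rep(FALSE, nrow(vals))
  for (i in seq_len(nrow(vals))) {
    if (oracle_iqr(vals[i, ]) >= iqr_min) keep[i] <- TRUE
  }
  rep_ids <- dataset$reporters[keep]
  genes <- dataset$genes[keep]
  vals <- vals[keep, , drop = FALSE]
  chosen <- character(0)
  for (g in unique(genes)) {
    rows <- which(genes == g)
    iqrs <- vapply(rows, function(i) oracle_iqr(vals[i, ]), numeric(1))
    best <- rows[iqrs == max(iqrs)]
    best <- best[order(rep_ids[best])][1]
    chosen <- c(chosen, rep_ids[best])
  }
  keep2 <- rep_ids %in% chosen
  rep_ids <- rep_ids[keep2]; genes <- genes[keep2]
  vals <- vals[keep2, , drop = FALSE]
  annotated <- unique(unlist(collection$sets, use.names = FALSE))
  keep3 <- genes %in% annotated
  rep_ids <- rep_ids[keep3]; genes <- genes[keep3]
  vals <- vals[keep3, , drop = FALSE]
  sets <- setNames(list(), character(0))
  for (id in names(collection$sets)) {
    m <- collection$sets[[id]][collection$sets[[id]] %in% genes]
    if (length(m) >= min_set_size) sets[[id]] <- m
  }
  list(reporters = rep_ids, genes = genes, values = unname(vals),
       sets = sets)
}

# Exhaustive permutation P-value for a set score: every way to assign
# n_tumor of the samples as tumors, per-gene t via oracle_pooled_t.
oracle_perm_pvalue <- function(values, n_tumor, members_rows) {
  n <- ncol(values)
  obs <- oracle_set_score(values, seq_len(n_tumor), members_rows)
  combos <- combn(n, n_tumor)
  hits <- 0
  for (j in seq_len(ncol(combos))) {
    s <- oracle_set_score(values, combos[, j], members_rows)
    if (abs(s) >= abs(obs) - 1e-12) hits <- hits + 1
  }
  hits / ncol(combos)
}

oracle_set_score <- function(values, tumor_cols, members_rows) {
  ts <- vapply(members_rows, function(i) {
    oracle_pooled_t(values[i, tumor_cols],
                    values[i, -tumor_cols])$t
  }, numeric(1))
  sum(ts) / sqrt(length(ts))
}

# Exact two-sided MWW P by enumeration of all group assignments: the
# achieved rank sum's two tails under the permutation null, smaller tail
# doubled and capped at 1. Handles ties through midranks.
oracle_mww_p <- function(g1, g2) {
  n1 <- length(g1); n <- n1 + length(g2)
  r <- rank(c(g1, g2))
  w_obs <- sum(r[seq_len(n1)])
  combos <- combn(n, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Kruskal-Wallis H with tie correction, computed by hand.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(groups), function(i) {
      sum(r[idx == i])^2 / sum(idx == i)
    }, numeric(1))) - 3 * (n + 1)
  tie_sizes <- table(x)
  h / (1 - sum(tie_sizes^3 - tie_sizes) / (n^3 - n))
}

# Small random dataset builder for property-style tests.
random_dataset <- function(n_reporters = 20, n_tumor = 5, n_normal = 4,
                           n_genes = NULL, platform = "A") {
  n_genes <- n_genes %||% max(2, n_reporters %/% 2)
  genes <- sprintf("G%03d",
                   sample.int(n_genes, n_reporters,
                              replace = n_genes < n_reporters))
  vals <- matrix(rnorm(n_reporters * (n_tumor + n_normal), 8, 1.2),
                 nrow = n_reporters)
  expression_dataset(
    vals,
    sprintf("r%03d", seq_len(n_reporters)),
    genes,
    c(sprintf("T%02d", seq_len(n_tumor)), sprintf("N%02d", seq_len(n_normal))),
    c(rep("tumor", n_tumor), rep("normal", n_normal)),
    platform)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
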