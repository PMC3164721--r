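#' Pooled-variance two-class t-test
#'
#' Classical equal-variance two-sample t-test of tumor versus normal
#' values, two-sided, with `n1 + n2 - 2` degrees of freedom. Degenerate
#' inputs (zero pooled variance) do not error: with unequal group means
#' the statistic is reported as signed infinity with `p = 0`, with equal
#' means as `t = 0`, `p = 1`; both set the `zero_variance` flag.
#'
#' @param tumor,normal Numeric vectors with at least two values each.
#' @return A list: `t`, `p`, `zero_variance`.
#' @examples
#' two_class_ttest(c(1, 2, 3), c(4, 5, 6))
#' @export
two_class_ttest <- function(tumor, normal) {
  if (length(tumor) < 2 || length(normal) < 2) {
    stop("each group needs at least 2 values")
  }
  if (any(!is.finite(tumor)) || any(!is.finite(normal))) {
    stop("non-finite values in input")
  }
  sp2 <- ((length(tumor) - 1) * stats::var(tumor) +
            (length(normal) - 1) * stats::var(normal)) /
    (length(tumor) + length(normal) - 2)
  if (sp2 == 0) {
    d <- mean(tumor) - mean(normal)
    if (d == 0) return(list(t = 0, p = 1, zero_variance = TRUE))
    return(list(t = sign(d) * Inf, p = 0, zero_variance = TRUE))
  }
  ht <- stats::t.test(tumor, normal, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, zero_variance = FALSE)
}

#' Log fold change
#'
#' Difference of group means on the (already log-scale) intensity axis,
#' tumor minus normal. With log2 input this is the log2 fold change.
#'
#' @param tumor,normal Numeric vectors.
#' @return Scalar, log units of the input.
#' @examples
#' log_fold_change(c(3, 3), c(1, 1))  # +2
#' @export
log_fold_change <- function(tumor, normal) {
  mean(tumor) - mean(normal)
}

#' Set enrichment score
#'
#' The parametric set-level statistic: the sum of the member genes'
#' t-statistics divided by the square root of the number of genes in the
#' set. Under independent null t-statistics it is approximately standard
#' normal; a positive score means the set is upregulated in tumors.
#'
#' @param t_values Finite numeric vector of per-gene t-statistics, one per
#'   member gene (length >= 1).
#' @return Scalar score.
#' @examples
#' enrichment_score(c(1, 2, 3))  # 6 / sqrt(3)
#' @export
enrichment_score <- function(t_values) {
  if (length(t_values) == 0) stop("empty set: no t-statistics")
  if (any(!is.finite(t_values))) {
    stop("non-finite t-statistics in set; zero-variance genes cannot be scored")
  }
  sum(t_values) / sqrt(length(t_values))
}

# --- vectorized machinery -------------------------------------------------

# Pooled-variance t for every row of X (genes x samples) under each column
# of `tumor_idx` (a matrix of tumor sample indices, one label assignment
# per column). Returns a genes x assignments matrix. Zero-variance rows
# yield 0 when the group means agree, signed Inf otherwise.
row_t_matrix <- function(X, tumor_idx, n_tumor, n_normal) {
  n <- n_tumor + n_normal
  stopifnot(ncol(X) == n, nrow(tumor_idx) == n_tumor)
  B <- ncol(tumor_idx)
  Z <- matrix(0, nrow = n, ncol = B)
  Z[cbind(as.vector(tumor_idx), rep(seq_len(B), each = n_tumor))] <- 1
  S <- rowSums(X); Q <- rowSums(X^2)
  S1 <- X %*% Z; Q1 <- X^2 %*% Z
  m1 <- S1 / n_tumor
  m2 <- (S - S1) / n_normal
  ss1 <- pmax(Q1 - S1^2 / n_tumor, 0)
  ss2 <- pmax((Q - Q1) - (S - S1)^2 / n_normal, 0)
  sp2 <- (ss1 + ss2) / (n - 2)
  d <- m1 - m2
  t <- d / sqrt(sp2 * (1 / n_tumor + 1 / n_normal))
  degenerate <- sp2 == 0
  if (any(degenerate)) {
    t[degenerate] <- ifelse(d[degenerate] == 0, 0,
                            sign(d[degenerate]) * Inf)
  }
  t
}

# Label assignments for the permutation null. When all choose(n, n_tumor)
# assignments number at most n_permutations, every one is enumerated
# (exhaustive = TRUE) and P-values are exact tail fractions; otherwise
# n_permutations random assignments are drawn.
label_assignments <- function(n, n_tumor, n_permutations, seed) {
  total <- choose(n, n_tumor)
  if (total <= n_permutations) {
    list(idx = utils::combn(n, n_tumor), exhaustive = TRUE)
  } else {
    idx <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) sort(sample.int(n, n_tumor)),
             integer(n_tumor))
    })
    if (n_tumor == 1) idx <- matrix(idx, nrow = 1)
    list(idx = idx, exhaustive = FALSE)
  }
}

# Comparison tolerance for |perm score| >= |observed score|: absorbs
# last-ulp differences between algebraically identical assignments
# (e.g. complementary subsets in balanced designs).
PERM_TOL <- 1e-12

#' Set-level P-value
#'
#' Two routes to a two-sided set P-value for an enrichment score:
#'
#' * `"normal"`: the score is referred to a standard normal distribution,
#'   `p = 2 * pnorm(-|score|)`. This is the fast parametric reading; it is
#'   slightly anticonservative because t-statistics have variance
#'   `df/(df-2) > 1`.
#' * `"permutation"`: sample class labels are permuted, the full per-gene
#'   t vector and the set score are recomputed for each assignment, and
#'   `p = (1 + #\{|score_perm| >= |score|\}) / (n_permutations + 1)`. When
#'   the total number of distinct label assignments is at most
#'   `n_permutations` they are enumerated exhaustively instead and `p` is
#'   the exact tail fraction (the observed labeling is one of the
#'   assignments, so `p > 0`).
#'
#' @param score The observed enrichment score.
#' @param dataset Gene-level [expression_dataset()] (permutation method).
#' @param members Gene symbols of the set (permutation method).
#' @param config An [analysis_config()]; `set_pvalue_method`,
#'   `n_permutations` and `seed` are used.
#' @return P-value in `[0, 1]`.
#' @examples
#' set_pvalue(qnorm(0.975))  # 0.05
#' @export
set_pvalue <- function(score, dataset = NULL, members = NULL,
                       config = analysis_config()) {
  if (config$set_pvalue_method == "normal") {
    return(2 * stats::pnorm(-abs(score)))
  }
  stopifnot(inherits(dataset, "expression_dataset"), length(members) >= 1)
  is_tumor <- dataset$classes == "tumor"
  n_tumor <- sum(is_tumor); n_normal <- sum(!is_tumor)
  if (n_tumor < 2 || n_normal < 2) {
    stop("permutation method needs at least 2 samples per class")
  }
  rows <- which(dataset$genes %in% members)
  if (length(rows) == 0) stop("no set members measured in the dataset")
  X <- dataset$values[rows, c(which(is_tumor), which(!is_tumor)),
                      drop = FALSE]
  asg <- label_assignments(n_tumor + n_normal, n_tumor,
                           config$n_permutations, config$seed)
  Tm <- row_t_matrix(X, asg$idx, n_tumor, n_normal)
  perm_scores <- colSums(Tm) / sqrt(nrow(Tm))
  hits <- sum(abs(perm_scores) >= abs(score) - PERM_TOL)
  if (asg$exhaustive) hits / ncol(asg$idx)
  else (1 + hits) / (ncol(asg$idx) + 1)
}

#' Run the set enrichment analysis on one dataset
#'
#' Computes, for every gene of a preprocessed (gene-level) dataset, the
#' pooled-variance t-statistic, its two-sided P-value and the log fold
#' change; then, for every set, the sum-of-t / sqrt(n) enrichment score
#' and a set-level P-value by the configured method. Genes belonging to
#' several sets contribute their single t-statistic to each.
#'
#' @param dataset A gene-level [expression_dataset()] (one row per gene)
#'   with at least two tumor and two normal samples.
#' @param collection A [gene_set_collection()] whose members are measured
#'   in the dataset (sets without any measured member are dropped with a
#'   warning).
#' @param config An [analysis_config()].
#' @return A list with two data.frames: `gene_stats` (`gene`, `t`, `p`,
#'   `lfc`, `direction`, `zero_variance`) and `pathway_results` (`set_id`,
#'   `n_genes`, `score`, `p`, `direction`; direction is `"up"` for a
#'   positive score, `"down"` for negative, `"none"` for exactly zero).
#' @examples
#' d <- simulation_design(n_genes = 60, n_sets = 5, set_size_range = c(8, 12),
#'                        samples_a = c(8, 4), samples_b = c(8, 4))
#' gc <- generate_collection(d)
#' pre <- preprocess_dataset(generate_expression(d, gc$truth, "A"),
#'                           gc$collection, analysis_config(min_set_size = 5))
#' res <- run_enrichment(pre$dataset, pre$collection,
#'                       analysis_config(min_set_size = 5))
#' head(res$pathway_results)
#' @export
run_enrichment <- function(dataset, collection,
                           config = analysis_config()) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(collection, "gene_set_collection"))
  is_tumor <- dataset$classes == "tumor"
  n_tumor <- sum(is_tumor); n_normal <- sum(!is_tumor)
  if (n_tumor < 2 || n_normal < 2) {
    stop("need at least 2 tumor and 2 normal samples")
  }
  if (anyDuplicated(dataset$genes)) {
    stop("dataset is not gene-level: collapse reporters first")
  }
  ord <- c(which(is_tumor), which(!is_tumor))
  X <- dataset$values[, ord, drop = FALSE]
  df <- n_tumor + n_normal - 2

  t_obs <- drop(row_t_matrix(X, matrix(seq_len(n_tumor), ncol = 1),
                             n_tumor, n_normal))
  p_gene <- ifelse(is.finite(t_obs), 2 * stats::pt(-abs(t_obs), df), 0)
  lfc <- rowMeans(X[, seq_len(n_tumor), drop = FALSE]) -
    rowMeans(X[, n_tumor + seq_len(n_normal), drop = FALSE])
  s1 <- rowSums(X[, seq_len(n_tumor), drop = FALSE])
  s2 <- rowSums(X[, n_tumor + seq_len(n_normal), drop = FALSE])
  ss <- rowSums(X^2) - s1^2 / n_tumor - s2^2 / n_normal
  gene_stats <- data.frame(
    gene = dataset$genes,
    t = t_obs,
    p = p_gene,
    lfc = lfc,
    direction = ifelse(t_obs > 0, "up", ifelse(t_obs < 0, "down", "none")),
    zero_variance = ss <= 0,
    stringsAsFactors = FALSE, row.names = NULL)

  measured <- lapply(collection$sets, function(m) m[m %in% dataset$genes])
  empty <- lengths(measured) == 0
  if (any(empty)) {
    warning(sum(empty), " set(s) without measured members dropped")
    measured <- measured[!empty]
  }
  ids <- names(measured)
  n_sets <- length(measured)
  sizes <- lengths(measured)

  gene_index <- stats::setNames(seq_along(dataset$genes), dataset$genes)
  M <- matrix(0, nrow = n_sets, ncol = nrow(X))
  for (i in seq_len(n_sets)) M[i, gene_index[measured[[i]]]] <- 1

  if (any(!is.finite(t_obs))) {
    stop("zero-variance gene with unequal means: cannot score sets ",
         "containing infinite t-statistics")
  }
  scores <- drop(M %*% t_obs) / sqrt(sizes)

  if (config$set_pvalue_method == "normal") {
    p_set <- 2 * stats::pnorm(-abs(scores))
  } else {
    asg <- label_assignments(n_tumor + n_normal, n_tumor,
                             config$n_permutations, config$seed)
    Tm <- row_t_matrix(X, asg$idx, n_tumor, n_normal)
    Sm <- (M %*% Tm) / sqrt(sizes)  # sets x assignments
    hits <- rowSums(abs(Sm) >= abs(scores) - PERM_TOL)
    p_set <- if (asg$exhaustive) hits / ncol(asg$idx)
    else (1 + hits) / (ncol(asg$idx) + 1)
  }

  pathway_results <- data.frame(
    set_id = ids,
    n_genes = as.integer(sizes),
    score = scores,
    p = p_set,
    direction = ifelse(scores > 0, "up",
                       ifelse(scores < 0, "down", "none")),
    stringsAsFactors = FALSE, row.names = NULL)
  list(gene_stats = gene_stats, pathway_results = pathway_results)
}
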