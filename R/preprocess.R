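#' Analysis configuration
#'
#' Collects the thresholds and options of the enrichment workflow.
#'
#' @param iqr_min Variability filter threshold in log-intensity units;
#'   reporters with interquartile range strictly below it are excluded
#'   (default 0.5).
#' @param min_set_size Minimum number of measured genes a set must retain
#'   to be tested (default 10; sets with fewer are removed).
#' @param alpha Significance level; significance is inclusive, `p <= alpha`
#'   (default 0.05).
#' @param set_pvalue_method `"normal"`: two-sided tail of the enrichment
#'   score under a standard normal reference; `"permutation"`: sample-label
#'   permutation null (exhaustive over all label assignments when feasible,
#'   see [set_pvalue()]).
#' @param n_permutations Number of label permutations for the permutation
#'   method.
#' @param lfc_base Base of the log scale the intensities are on (2 for
#'   log2 data; informational).
#' @param filter_before_collapse If `TRUE` (default) the IQR filter runs
#'   per reporter before probe-to-gene collapse, so a gene survives if any
#'   of its reporters does; `FALSE` collapses first and filters the chosen
#'   reporter.
#' @param seed RNG seed for the permutation null.
#' @return An object of class `analysis_config`.
#' @examples
#' analysis_config(set_pvalue_method = "permutation", n_permutations = 1000)
#' @export
analysis_config <- function(iqr_min = 0.5, min_set_size = 10, alpha = 0.05,
                            set_pvalue_method = c("normal", "permutation"),
                            n_permutations = 1000, lfc_base = 2,
                            filter_before_collapse = TRUE, seed = 1L) {
  set_pvalue_method <- match.arg(set_pvalue_method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (min_set_size < 1) stop("min_set_size must be >= 1")
  if (iqr_min < 0) stop("iqr_min must be >= 0")
  if (set_pvalue_method == "permutation" && n_permutations < 1) {
    stop("n_permutations must be >= 1 for the permutation method")
  }
  structure(list(iqr_min = iqr_min, min_set_size = as.integer(min_set_size),
                 alpha = alpha, set_pvalue_method = set_pvalue_method,
                 n_permutations = as.integer(n_permutations),
                 lfc_base = lfc_base,
                 filter_before_collapse = isTRUE(filter_before_collapse),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Interquartile range of a log-intensity vector
#'
#' The variability measure used both by the admission filter and by the
#' probe-to-gene collapse: Q3 minus Q1 with linear interpolation between
#' order statistics (quantile type 7, the mainstream default convention).
#'
#' @param values Numeric vector with at least one finite value.
#' @return Non-negative scalar.
#' @examples
#' compute_iqr(1:8)  # 3.5
#' @export
compute_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("compute_iqr: no finite values")
  stats::IQR(values, type = 7)
}

row_iqrs <- function(dataset) {
  apply(dataset$values, 1, compute_iqr)
}

#' Remove low-variability reporters
#'
#' Drops reporters whose IQR across samples is strictly below
#' `config$iqr_min`; a reporter whose IQR equals the threshold is retained.
#'
#' @param dataset An [expression_dataset()].
#' @param config An [analysis_config()].
#' @return A list: `dataset` (filtered) and `removed` (reporter ids).
#' @export
filter_low_variability <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  iqr <- row_iqrs(dataset)
  keep <- iqr >= config$iqr_min
  list(dataset = subset_reporters(dataset, keep),
       removed = dataset$reporters[!keep])
}

#' Collapse reporters to genes by maximal variability
#'
#' For genes measured by several reporters, keeps the single reporter with
#' the largest IQR (the same variability measure the filter uses); exact
#' ties are broken by the lexicographically smallest reporter id so the
#' result is deterministic. Single-reporter genes pass through unchanged.
#' Row order of the surviving reporters is preserved.
#'
#' @param dataset An [expression_dataset()].
#' @return An [expression_dataset()] with one row per gene symbol.
#' @export
collapse_to_genes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (nrow(dataset$values) == 0) return(dataset)
  iqr <- row_iqrs(dataset)
  keep <- logical(nrow(dataset$values))
  for (rows in split(seq_along(iqr), dataset$genes)) {
    best <- rows[iqr[rows] == max(iqr[rows])]
    if (length(best) > 1) best <- best[order(dataset$reporters[best])][1]
    keep[best] <- TRUE
  }
  subset_reporters(dataset, keep)
}

#' Drop genes not annotated to any set
#'
#' @param dataset An [expression_dataset()] (normally gene-collapsed).
#' @param collection A [gene_set_collection()].
#' @return The dataset restricted to genes appearing in at least one set.
#' @export
restrict_to_annotated <- function(dataset, collection) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(collection, "gene_set_collection"))
  annotated <- unique(unlist(collection$sets, use.names = FALSE))
  subset_reporters(dataset, dataset$genes %in% annotated)
}

#' Remove sets with too few measured genes
#'
#' A set's effective size is the number of its members present in the
#' (collapsed, filtered) dataset. Sets with effective size strictly below
#' `config$min_set_size` are dropped; surviving sets keep only their
#' measured members.
#'
#' @param collection A [gene_set_collection()].
#' @param dataset The analysis-ready [expression_dataset()].
#' @param config An [analysis_config()].
#' @return A pruned [gene_set_collection()].
#' @export
prune_small_sets <- function(collection, dataset,
                             config = analysis_config()) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(dataset, "expression_dataset"))
  measured <- unique(dataset$genes)
  pruned <- lapply(collection$sets, function(m) m[m %in% measured])
  keep <- lengths(pruned) >= config$min_set_size
  gene_set_collection(pruned[keep],
                      descriptions = unname(collection$descriptions[keep]),
                      source_tag = collection$source_tag)
}

#' Run the full admission pipeline
#'
#' Applies, in order: the per-reporter IQR filter, probe-to-gene collapse
#' by maximal IQR, removal of genes not annotated to any set, and pruning
#' of sets with fewer measured genes than `min_set_size`. (With
#' `config$filter_before_collapse = FALSE` the first two stages swap.)
#' The accompanying report reconciles the counts at every stage.
#'
#' @param dataset An [expression_dataset()].
#' @param collection A [gene_set_collection()].
#' @param config An [analysis_config()].
#' @return A list: `dataset` (gene-level, analysis-ready), `collection`
#'   (pruned, members restricted to measured genes) and `report`, a
#'   `filter_report` with fields `n_reporters_in`, `n_removed_iqr`,
#'   `n_collapsed`, `n_removed_unannotated`, `n_genes_out`, `n_sets_in`,
#'   `n_sets_removed_small`, `n_sets_out`.
#' @examples
#' d <- simulation_design(n_genes = 60, n_sets = 5, set_size_range = c(8, 12),
#'                        samples_a = c(8, 4), samples_b = c(8, 4))
#' gc <- generate_collection(d)
#' ds <- generate_expression(d, gc$truth, "A")
#' preprocess_dataset(ds, gc$collection, analysis_config(min_set_size = 5))$report
#' @export
preprocess_dataset <- function(dataset, collection,
                               config = analysis_config()) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(collection, "gene_set_collection"))
  n_in <- nrow(dataset$values)
  if (config$filter_before_collapse) {
    filt <- filter_low_variability(dataset, config)
    n_removed_iqr <- length(filt$removed)
    collapsed <- collapse_to_genes(filt$dataset)
    n_collapsed <- nrow(filt$dataset$values) - nrow(collapsed$values)
  } else {
    collapsed0 <- collapse_to_genes(dataset)
    n_collapsed <- n_in - nrow(collapsed0$values)
    filt <- filter_low_variability(collapsed0, config)
    n_removed_iqr <- length(filt$removed)
    collapsed <- filt$dataset
  }
  annotated <- restrict_to_annotated(collapsed, collection)
  n_removed_unannotated <- nrow(collapsed$values) - nrow(annotated$values)
  pruned <- prune_small_sets(collection, annotated, config)
  report <- structure(list(
    n_reporters_in = n_in,
    n_removed_iqr = n_removed_iqr,
    n_collapsed = n_collapsed,
    n_removed_unannotated = n_removed_unannotated,
    n_genes_out = nrow(annotated$values),
    n_sets_in = length(collection$sets),
    n_sets_removed_small = length(collection$sets) - length(pruned$sets),
    n_sets_out = length(pruned$sets)),
    class = "filter_report")
  list(dataset = annotated, collection = pruned, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  cat(sprintf("  reporters in:            %d\n", x$n_reporters_in))
  cat(sprintf("  removed (IQR filter):    %d\n", x$n_removed_iqr))
  cat(sprintf("  removed (probe collapse):%d\n", x$n_collapsed))
  cat(sprintf("  removed (unannotated):   %d\n", x$n_removed_unannotated))
  cat(sprintf("  genes out:               %d\n", x$n_genes_out))
  cat(sprintf("  sets in: %d, removed (< min size): %d, out: %d\n",
              x$n_sets_in, x$n_sets_removed_small, x$n_sets_out))
  invisible(x)
}
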