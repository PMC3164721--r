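CONSENSUS_CATEGORIES <- c("concordant-up", "concordant-down", "opposite",
                          "single-A", "single-B", "neither",
                          "unmeasured-A", "unmeasured-B")

#' Classify one item's cross-dataset concordance
#'
#' Given an item's (pathway's or gene's) P-value and direction in each of
#' two independently analyzed datasets, assigns one of eight categories.
#' Significance is inclusive (`p <= alpha`). Both significant with the
#' same direction gives `concordant-up` / `concordant-down`; both
#' significant with different directions gives `opposite`; exactly one
#' significant gives `single-A` / `single-B`; neither significant gives
#' `neither`. An absent P-value (`NA`) means the item was not measured on
#' that platform and yields `unmeasured-A` / `unmeasured-B` regardless of
#' the other dataset.
#'
#' @param p_a,p_b P-values in `[0, 1]`, or `NA` when unmeasured.
#' @param dir_a,dir_b Directions, `"up"`, `"down"` or `"none"` (ignored
#'   for an unmeasured dataset).
#' @param alpha Significance level (inclusive).
#' @return One of `"concordant-up"`, `"concordant-down"`, `"opposite"`,
#'   `"single-A"`, `"single-B"`, `"neither"`, `"unmeasured-A"`,
#'   `"unmeasured-B"`.
#' @examples
#' classify_item(0.01, "up", 0.02, "up")        # concordant-up
#' classify_item(0.01, "up", 0.01, "down")      # opposite
#' classify_item(0.05, "up", 0.05, "up")        # inclusive threshold
#' @export
classify_item <- function(p_a, dir_a, p_b, dir_b, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  for (p in c(p_a, p_b)) {
    if (!is.na(p) && (p < 0 || p > 1)) stop("P-values must lie in [0, 1]")
  }
  measured_a <- !is.na(p_a); measured_b <- !is.na(p_b)
  if (!measured_a && !measured_b) {
    stop("item measured in neither dataset")
  }
  if (!measured_a) return("unmeasured-A")
  if (!measured_b) return("unmeasured-B")
  check_dir <- function(d) {
    if (!d %in% c("up", "down", "none")) {
      stop("direction must be 'up', 'down' or 'none'")
    }
  }
  check_dir(dir_a); check_dir(dir_b)
  sig_a <- p_a <= alpha; sig_b <- p_b <= alpha
  if (sig_a && dir_a == "none") {
    stop("invalid input: significant P-value with direction 'none'")
  }
  if (sig_b && dir_b == "none") {
    stop("invalid input: significant P-value with direction 'none'")
  }
  if (sig_a && sig_b) {
    if (dir_a == dir_b) return(paste0("concordant-", dir_a))
    return("opposite")
  }
  if (sig_a) return("single-A")
  if (sig_b) return("single-B")
  "neither"
}

#' Chance risk of joint significance across independent datasets
#'
#' The probability that a null item reaches significance at level `alpha`
#' in all of `k` independent datasets: `alpha^k`. At the conventional
#' `alpha = 0.05` and two datasets this is `0.0025 = 1/400`, the
#' justification for not applying an additional multiple-testing
#' correction to jointly significant items.
#'
#' @param alpha Per-dataset significance level, in (0, 1).
#' @param k_datasets Number of independent datasets, >= 1.
#' @return Probability `alpha ^ k_datasets`.
#' @examples
#' joint_chance_risk(0.05, 2)  # 1/400
#' @export
joint_chance_risk <- function(alpha, k_datasets) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (k_datasets < 1 || k_datasets != round(k_datasets)) {
    stop("k_datasets must be a positive integer")
  }
  alpha ^ k_datasets
}

#' Combine two datasets' pathway results into consensus records
#'
#' Aligns the `pathway_results` tables of two [run_enrichment()] runs on
#' the union of their set ids and classifies every set with
#' [classify_item()]. Sets measured in neither dataset cannot appear.
#'
#' @param results_a,results_b `pathway_results` data.frames (or the full
#'   [run_enrichment()] return lists) from datasets A and B.
#' @param alpha Significance level (inclusive).
#' @return A data.frame: `item_id`, `p_a`, `direction_a`, `p_b`,
#'   `direction_b`, `category`.
#' @export
cross_dataset_consensus <- function(results_a, results_b, alpha = 0.05) {
  get_tab <- function(r) {
    if (is.list(r) && !is.data.frame(r) && "pathway_results" %in% names(r)) {
      r <- r$pathway_results
    }
    stopifnot(is.data.frame(r),
              all(c("set_id", "p", "direction") %in% names(r)))
    r
  }
  a <- get_tab(results_a); b <- get_tab(results_b)
  ids <- union(a$set_id, b$set_id)
  ia <- match(ids, a$set_id); ib <- match(ids, b$set_id)
  p_a <- a$p[ia]; dir_a <- a$direction[ia]
  p_b <- b$p[ib]; dir_b <- b$direction[ib]
  category <- vapply(seq_along(ids), function(i) {
    classify_item(p_a[i], dir_a[i], p_b[i], dir_b[i], alpha)
  }, character(1))
  data.frame(item_id = ids, p_a = p_a, direction_a = dir_a,
             p_b = p_b, direction_b = dir_b, category = category,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize consensus records
#'
#' Counts records per concordance category and reports the joint chance
#' risk `alpha^2` alongside.
#'
#' @param records Data.frame from [cross_dataset_consensus()] (needs a
#'   `category` column).
#' @param alpha The significance level the records were classified at.
#' @return An object of class `venn_summary`: list with `counts` (named
#'   integer vector over all eight categories), `n_items`, `alpha`,
#'   `joint_risk`.
#' @export
summarize_consensus <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records) || is.null(records))
  cats <- if (is.null(records) || nrow(records) == 0) character(0)
  else records$category
  bad <- setdiff(unique(cats), CONSENSUS_CATEGORIES)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  counts <- vapply(CONSENSUS_CATEGORIES, function(k) sum(cats == k),
                   integer(1))
  structure(list(counts = counts, n_items = length(cats), alpha = alpha,
                 joint_risk = joint_chance_risk(alpha, 2)),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("venn_summary: %d items at alpha = %g (joint chance risk %g)\n",
              x$n_items, x$alpha, x$joint_risk))
  for (k in names(x$counts)) {
    cat(sprintf("  %-16s %d\n", k, x$counts[[k]]))
  }
  invisible(x)
}

#' Per-gene concordance table for one pathway
#'
#' Builds the gene-level companion of the pathway consensus: for every
#' member gene of a set, the P-value and log fold change in each dataset
#' and a partition label — `"both"` (significant in both datasets, same
#' direction), `"opposite"`, `"one"` (significant in exactly one) or
#' `"neither"`. Genes absent from one platform keep `NA` entries for it
#' (the "-" convention of printed tables) and are classified from the
#' other platform alone; genes measured in neither dataset are omitted.
#'
#' @param gene_stats_a,gene_stats_b `gene_stats` data.frames from
#'   [run_enrichment()] on datasets A and B (shared symbol namespace).
#' @param members Character vector of the set's member gene symbols.
#' @param alpha Significance level (inclusive).
#' @return A data.frame: `gene`, `p_a`, `lfc_a`, `p_b`, `lfc_b`,
#'   `category` (the [classify_item()] category), `partition`; rows sorted
#'   by partition (`both`, `one`, `opposite`, `neither`) then gene.
#' @export
gene_concordance_table <- function(gene_stats_a, gene_stats_b, members,
                                   alpha = 0.05) {
  stopifnot(is.data.frame(gene_stats_a), is.data.frame(gene_stats_b),
            length(members) >= 1)
  ia <- match(members, gene_stats_a$gene)
  ib <- match(members, gene_stats_b$gene)
  keep <- !(is.na(ia) & is.na(ib))
  members <- members[keep]; ia <- ia[keep]; ib <- ib[keep]
  dir_of <- function(stats, idx) {
    ifelse(is.na(idx), NA_character_, stats$direction[idx])
  }
  p_a <- gene_stats_a$p[ia]; lfc_a <- gene_stats_a$lfc[ia]
  p_b <- gene_stats_b$p[ib]; lfc_b <- gene_stats_b$lfc[ib]
  dir_a <- dir_of(gene_stats_a, ia); dir_b <- dir_of(gene_stats_b, ib)
  category <- vapply(seq_along(members), function(i) {
    classify_item(p_a[i], dir_a[i], p_b[i], dir_b[i], alpha)
  }, character(1))
  # an unmeasured gene partitions by the platform it was measured on
  sig_other <- ifelse(category == "unmeasured-A",
                      !is.na(p_b) & p_b <= alpha,
                      ifelse(category == "unmeasured-B",
                             !is.na(p_a) & p_a <= alpha, NA))
  partition <- ifelse(category %in% c("concordant-up", "concordant-down"),
                      "both",
                      ifelse(category %in% c("single-A", "single-B"), "one",
                             ifelse(category == "opposite", "opposite",
                                    ifelse(category == "neither", "neither",
                                           ifelse(sig_other, "one",
                                                  "neither")))))
  out <- data.frame(gene = members, p_a = p_a, lfc_a = lfc_a,
                    p_b = p_b, lfc_b = lfc_b, category = category,
                    partition = partition, stringsAsFactors = FALSE,
                    row.names = NULL)
  ord <- order(match(out$partition, c("both", "one", "opposite", "neither")),
               out$gene)
  out[ord, , drop = FALSE]
}
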