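#' Construct an expression dataset
#'
#' The basic container for one platform's measurements: a reporter-by-sample
#' matrix of log2-scale intensities, the gene symbol each reporter is
#' annotated to (many reporters may map to one gene), and a tumor/normal
#' class label per sample.
#'
#' Non-finite intensities are rejected: the downstream filters and tests
#' assume complete matrices and no missing-data rule is defined.
#'
#' @param values Numeric matrix, reporters in rows, samples in columns.
#' @param reporter_ids Character vector of unique reporter (probe) ids,
#'   one per row.
#' @param gene_symbols Character vector of gene symbols, one per row;
#'   symbols are compared case-sensitively and never alias-resolved.
#' @param sample_ids Character vector of unique sample ids, one per column.
#' @param class_labels Character vector, `"tumor"` or `"normal"`, one per
#'   sample.
#' @param platform Free-text platform identifier.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (matrix with reporter/sample dimnames), `reporters`, `genes`,
#'   `samples`, `classes`, `platform`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3)
#' expression_dataset(m, c("r1", "r2"), c("G1", "G2"),
#'                    c("s1", "s2", "s3"), c("tumor", "tumor", "normal"))
#' @export
expression_dataset <- function(values, reporter_ids, gene_symbols,
                               sample_ids, class_labels,
                               platform = "unknown") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (length(reporter_ids) != nrow(values)) {
    stop("`reporter_ids` length must equal nrow(values)")
  }
  if (length(gene_symbols) != nrow(values)) {
    stop("`gene_symbols` length must equal nrow(values)")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("`sample_ids` length must equal ncol(values)")
  }
  if (length(class_labels) != ncol(values)) {
    stop("`class_labels` length must equal ncol(values)")
  }
  if (anyDuplicated(reporter_ids)) {
    stop("duplicate reporter id: ",
         paste(unique(reporter_ids[duplicated(reporter_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!all(class_labels %in% c("tumor", "normal"))) {
    stop("class labels must be 'tumor' or 'normal'")
  }
  if (nrow(values) > 0 && ncol(values) > 0 && any(!is.finite(values))) {
    stop("non-finite values in expression matrix; missing data are not supported")
  }
  dimnames(values) <- list(reporter_ids, sample_ids)
  structure(
    list(values = values,
         reporters = as.character(reporter_ids),
         genes = as.character(gene_symbols),
         samples = as.character(sample_ids),
         classes = as.character(class_labels),
         platform = as.character(platform)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset [platform %s]: %d reporters (%d genes) x %d samples (%d tumor / %d normal)\n",
    x$platform, nrow(x$values), length(unique(x$genes)), ncol(x$values),
    sum(x$classes == "tumor"), sum(x$classes == "normal")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# Row-subset keeping all bookkeeping aligned.
subset_reporters <- function(dataset, keep) {
  expression_dataset(dataset$values[keep, , drop = FALSE],
                     dataset$reporters[keep],
                     dataset$genes[keep],
                     dataset$samples,
                     dataset$classes,
                     dataset$platform)
}

#' Construct a gene set collection
#'
#' Named gene sets (for example the pathways of a KEGG-style collection).
#' Each set has an id, a free-text description and an ordered vector of
#' unique member gene symbols.
#'
#' @param sets Named list of character vectors; names are set ids, elements
#'   the member gene symbols.
#' @param descriptions Optional character vector of descriptions, one per
#'   set (recycled from `""` when absent).
#' @param source_tag Free text recording provenance (e.g. a database
#'   release).
#'
#' @return An object of class `gene_set_collection` with elements `sets`,
#'   `descriptions` (named like `sets`) and `source_tag`.
#' @examples
#' gene_set_collection(list(S1 = c("G1", "G2"), S2 = c("G2", "G3", "G4")))
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source_tag = "") {
  if (!is.list(sets)) stop("`sets` must be a list of character vectors")
  n <- length(sets)
  ids <- names(sets) %||% character(0)
  if (n > 0 && (is.null(names(sets)) || any(!nzchar(ids)))) {
    stop("every set must have a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate set id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (i in seq_len(n)) {
    m <- sets[[i]]
    if (!is.character(m) || length(m) == 0) {
      stop("set '", ids[i], "' must have at least one member gene symbol")
    }
    if (anyDuplicated(m)) {
      stop("set '", ids[i], "' contains duplicate gene symbols")
    }
  }
  if (is.null(descriptions)) {
    descriptions <- rep("", n)
  }
  if (length(descriptions) != n) {
    stop("`descriptions` must have one entry per set")
  }
  names(descriptions) <- ids
  structure(list(sets = sets,
                 descriptions = descriptions,
                 source_tag = as.character(source_tag)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets", length(x$sets)))
  if (length(sizes)) {
    cat(sprintf(" (sizes %d-%d, median %g)",
                min(sizes), max(sizes), stats::median(sizes)))
  }
  if (nzchar(x$source_tag)) cat(" [", x$source_tag, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)
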