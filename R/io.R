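#' Read a gene-set collection from a GMT file
#'
#' Parses the tab-separated GMT dialect used by Broad/MSigDB-style
#' collections: one set per line, `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate gene symbols within a set are dropped keeping the first
#' occurrence, with a warning; duplicate set ids or malformed lines are
#' errors.
#'
#' @param path Path to a GMT file.
#' @param source_tag Provenance text stored on the collection (defaults to
#'   the file name).
#' @return A [gene_set_collection()].
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  line_no <- which(keep)
  sets <- list(); descs <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      stop("GMT parse error at line ", line_no[i],
           ": expected at least 3 tab-separated fields, found ", length(f))
    }
    id <- f[1]
    if (id %in% names(sets)) {
      stop("GMT parse error at line ", line_no[i], ": duplicate set id '",
           id, "'")
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("set '", id, "': duplicate gene symbols removed ",
              "(first occurrence kept)")
      members <- members[!duplicated(members)]
    }
    sets[[id]] <- members
    descs <- c(descs, f[2])
  }
  gene_set_collection(sets, descriptions = descs, source_tag = source_tag)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_gmt()]
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$sets)
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], collection$descriptions[[i]], collection$sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Full-precision numeric formatting so the expression TSV round-trips
# exactly (17 significant digits recover the double).
fmt_num <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' Write an expression dataset as TSV
#'
#' The layout is: a `#platform` line, a `#class` line giving the
#' tumor/normal label of each sample column, a header row
#' (`reporter_id`, `gene_symbol`, then sample ids), and one data row per
#' reporter. Values are written with enough digits to round-trip doubles
#' exactly.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_expression()]
#' @export
write_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  header <- paste(c("reporter_id", "gene_symbol", dataset$samples),
                  collapse = "\t")
  class_line <- paste(c("#class", "", dataset$classes), collapse = "\t")
  platform_line <- paste(c("#platform", dataset$platform), collapse = "\t")
  rows <- vapply(seq_len(nrow(dataset$values)), function(i) {
    paste(c(dataset$reporters[i], dataset$genes[i],
            fmt_num(dataset$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(platform_line, class_line, header, rows), path)
  invisible(path)
}

#' Read an expression dataset from TSV
#'
#' Parses the format written by [write_expression()]: optional `#platform`
#' line, mandatory `#class` line, a header row, then one reporter per row.
#' Non-numeric cells are reported with their row/column coordinates;
#' duplicate reporter ids and a missing `#class` line are errors.
#'
#' @param path Path to the TSV file.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  platform <- "unknown"; classes <- NULL
  while (length(lines) && startsWith(lines[1], "#")) {
    f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (f[1] == "#platform") {
      platform <- f[2]
    } else if (f[1] == "#class") {
      classes <- f[-(1:2)]
    } else {
      stop("unknown header line: ", f[1])
    }
    lines <- lines[-1]
  }
  if (is.null(classes)) stop("missing '#class' header row")
  if (!length(lines)) stop("missing column header row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("header row must contain at least 2 columns")
  samples <- header[-(1:2)]
  if (length(samples) != length(classes)) {
    stop("'#class' row has ", length(classes), " labels but header has ",
         length(samples), " sample columns")
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  n <- length(body)
  reporters <- character(n); genes <- character(n)
  values <- matrix(NA_real_, nrow = n, ncol = length(samples))
  for (i in seq_len(n)) {
    f <- body[[i]]
    if (length(f) != length(header)) {
      stop("data row ", i, " has ", length(f), " fields, expected ",
           length(header))
    }
    reporters[i] <- f[1]; genes[i] <- f[2]
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric value at data row ", i, ", sample column ", j,
           " ('", f[j + 2], "')")
    }
    values[i, ] <- v
  }
  expression_dataset(values, reporters, genes, samples, classes, platform)
}

#' Write / read a clinical label table
#'
#' Plain TSV with a `sample_id` column and one column per covariate.
#'
#' @param clinical A data.frame as returned by [generate_clinical()].
#' @param path File path.
#' @return `write_clinical()` returns `path` invisibly; `read_clinical()`
#'   returns a data.frame.
#' @export
write_clinical <- function(clinical, path) {
  stopifnot(is.data.frame(clinical), "sample_id" %in% names(clinical))
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Write / read simulation truth as a plain-text key-value file
#'
#' Three record kinds, one per line: `set_direction<TAB>id<TAB>direction`,
#' `de_gene<TAB>symbol`, and `gene_direction<TAB>symbol<TAB>direction`.
#'
#' @param truth A `synthetic_truth` from [generate_collection()].
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   a `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  lines <- c(
    paste("set_direction", names(truth$set_direction), truth$set_direction,
          sep = "\t"),
    paste("de_gene", truth$de_genes, sep = "\t"),
    paste("gene_direction", names(truth$gene_direction),
          truth$gene_direction, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(f, `[`, character(1), 1)
  pick <- function(k, idx) vapply(f[kind == k], `[`, character(1), idx)
  structure(list(
    set_direction = stats::setNames(pick("set_direction", 3),
                                    pick("set_direction", 2)),
    de_genes = unname(pick("de_gene", 2)),
    gene_direction = stats::setNames(pick("gene_direction", 3),
                                     pick("gene_direction", 2))),
    class = "synthetic_truth")
}
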