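#' A qPCR measurement
#'
#' Replicate standard-curve-interpolated quantities for one assay on one
#' sample. Runs are typically done in triplicate; the median replicate is
#' the value used downstream.
#'
#' @param sample_id Sample identifier.
#' @param assay Assay (gene) name, target or endogenous control.
#' @param quantities Numeric vector of 1-3 non-negative replicate
#'   quantities.
#' @return An object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(sample_id, assay, quantities) {
  if (length(quantities) < 1) stop("need at least one replicate quantity")
  if (any(!is.finite(quantities)) || any(quantities < 0)) {
    stop("replicate quantities must be finite and non-negative")
  }
  structure(list(sample_id = as.character(sample_id),
                 assay = as.character(assay),
                 quantities = as.numeric(quantities)),
            class = "qpcr_measurement")
}

#' Quantify Ct values against a standard curve
#'
#' Fits the least-squares line `Ct = a + b * log10(quantity)` through the
#' points of a serial-dilution standard curve and inverts it:
#' `quantity = 10^((Ct - a) / b)`.
#'
#' @param ct_values Numeric vector of observed Ct values.
#' @param curve_points Data.frame with columns `log10_quantity` and `ct`;
#'   at least two distinct `log10_quantity` values.
#' @param tol Minimum admissible |slope|; a flatter curve is an error.
#' @return Numeric vector of quantities, one per Ct.
#' @examples
#' curve <- data.frame(log10_quantity = 0:3, ct = 30 - 3.32 * (0:3))
#' standard_curve_quantify(30 - 3.32 * 2, curve)  # 100
#' @export
standard_curve_quantify <- function(ct_values, curve_points, tol = 1e-8) {
  stopifnot(is.data.frame(curve_points),
            all(c("log10_quantity", "ct") %in% names(curve_points)))
  if (length(unique(curve_points$log10_quantity)) < 2) {
    stop("standard curve needs at least 2 distinct quantities")
  }
  if (any(!is.finite(ct_values))) stop("Ct values must be finite")
  fit <- stats::lm(ct ~ log10_quantity, data = curve_points)
  a <- stats::coef(fit)[[1]]; b <- stats::coef(fit)[[2]]
  if (abs(b) < tol) stop("flat standard curve: |slope| below tolerance")
  10 ^ ((ct_values - a) / b)
}

#' Normalize a target's expression to endogenous controls
#'
#' Aggregates each measurement's replicates by their median, then divides
#' the target's median quantity by the mean of the controls' median
#' quantities.
#'
#' @param target A [qpcr_measurement()] for the gene of interest.
#' @param controls List of [qpcr_measurement()]s for the endogenous
#'   controls (at least one).
#' @return Normalized quantity (scalar).
#' @examples
#' t <- qpcr_measurement("s1", "PLCD1", c(1.0, 1.1, 5.0))
#' c1 <- qpcr_measurement("s1", "ACTB", c(2, 2, 2))
#' c2 <- qpcr_measurement("s1", "GUSB", c(4, 4, 4))
#' normalize_expression(t, list(c1, c2))  # 1.1 / 3
#' @export
normalize_expression <- function(target, controls) {
  stopifnot(inherits(target, "qpcr_measurement"), length(controls) >= 1)
  med <- function(m) {
    stopifnot(inherits(m, "qpcr_measurement"))
    stats::median(m$quantities)
  }
  denom <- mean(vapply(controls, med, numeric(1)))
  if (denom == 0) stop("control denominator is zero")
  med(target) / denom
}

as_qmsp <- function(x) {
  if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
  stopifnot(all(c("target_qty", "ref_qty") %in% names(x)))
  x
}

#' Percent of methylated reference (PMR)
#'
#' The ALU-normalized methylation level of a sample relative to a fully
#' methylated positive control:
#' `100 * (target/ref)_sample / (target/ref)_control`.
#'
#' @param sample,positive_control Lists (or single data.frame rows) with
#'   fields `target_qty` (methylation-specific signal, >= 0) and `ref_qty`
#'   (ALU reference, > 0); the control's `target_qty` must be positive.
#' @return PMR value in percent (>= 0; 100 means the sample's ratio equals
#'   the control's).
#' @examples
#' pmr(list(target_qty = 2, ref_qty = 50),
#'     list(target_qty = 8, ref_qty = 50))  # 25
#' @export
pmr <- function(sample, positive_control) {
  s <- as_qmsp(sample); ctrl <- as_qmsp(positive_control)
  for (m in list(s, ctrl)) {
    if (!is.finite(m$ref_qty) || m$ref_qty <= 0) {
      stop("reference (ALU) quantity must be positive")
    }
    if (!is.finite(m$target_qty) || m$target_qty < 0) {
      stop("target quantity must be non-negative")
    }
  }
  if (ctrl$target_qty <= 0) {
    stop("positive control must have a positive target/reference ratio")
  }
  100 * (s$target_qty / s$ref_qty) / (ctrl$target_qty / ctrl$ref_qty)
}

#' Call methylation from a PMR value
#'
#' A sample is methylated when its PMR strictly exceeds the highest PMR
#' observed in the normal panel (floor 0). With an all-zero or empty
#' normal panel this reduces to the `PMR > 0` rule.
#'
#' @param pmr_value PMR of the sample, >= 0.
#' @param normal_panel_pmrs PMR values of the normal panel (may be empty).
#' @return `TRUE` if methylated.
#' @examples
#' call_methylation(5.69)                 # TRUE
#' call_methylation(0)                    # FALSE
#' call_methylation(1.2, c(0, 1.2, 0.4))  # FALSE (strict inequality)
#' @export
call_methylation <- function(pmr_value, normal_panel_pmrs = numeric(0)) {
  if (!is.finite(pmr_value) || pmr_value < 0) {
    stop("PMR value must be finite and non-negative")
  }
  if (length(normal_panel_pmrs) &&
      (any(!is.finite(normal_panel_pmrs)) || any(normal_panel_pmrs < 0))) {
    stop("normal-panel PMR values must be finite and non-negative")
  }
  pmr_value > max(c(normal_panel_pmrs, 0))
}

#' Compute PMR and methylation calls for a whole qMSP panel
#'
#' Convenience wrapper over [pmr()] and [call_methylation()] for a panel
#' data.frame as produced by [generate_qmsp_panel()]: exactly one
#' `positive-control` row supplies the reference ratio, the `normal` rows
#' define the calling threshold, and every non-control row receives a PMR
#' value and a call.
#'
#' @param panel Data.frame with columns `sample_id`, `role`, `target_qty`,
#'   `ref_qty`.
#' @return Data.frame `sample_id`, `role`, `pmr`, `methylated`.
#' @export
pmr_table <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("sample_id", "role", "target_qty", "ref_qty") %in%
                  names(panel)))
  ctrl_rows <- which(panel$role == "positive-control")
  if (length(ctrl_rows) != 1) {
    stop("panel must contain exactly one positive-control record")
  }
  ctrl <- as.list(panel[ctrl_rows, ])
  rest <- panel[-ctrl_rows, , drop = FALSE]
  vals <- vapply(seq_len(nrow(rest)), function(i) {
    pmr(as.list(rest[i, ]), ctrl)
  }, numeric(1))
  threshold_pool <- vals[rest$role == "normal"]
  methylated <- vapply(vals, call_methylation, logical(1),
                       normal_panel_pmrs = threshold_pool)
  data.frame(sample_id = rest$sample_id, role = rest$role, pmr = vals,
             methylated = methylated, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test between two groups. When both groups have at
#' most 8 observations and there are no ties, the exact null distribution
#' of the rank sum is used (the two-sided P doubles the smaller tail,
#' capped at 1); otherwise the tie-corrected normal approximation without
#' continuity correction, which for two groups agrees exactly with the
#' Kruskal-Wallis chi-square test.
#'
#' @param group1,group2 Numeric vectors, each with at least one value.
#' @return A list: `statistic` (the Mann-Whitney U of group 1), `p`,
#'   `exact` (logical).
#' @examples
#' mww_test(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 (= 2/20)
#' @export
mww_test <- function(group1, group2) {
  if (length(group1) < 1 || length(group2) < 1) {
    stop("each group needs at least one value")
  }
  ties <- anyDuplicated(c(group1, group2)) > 0
  exact <- length(group1) <= 8 && length(group2) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group1, group2, exact = exact, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' `k - 1` degrees of freedom. The degenerate case of all observations
#' identical across all groups is reported as `h = 0`, `p = 1`.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return A list: `h`, `df`, `p`.
#' @examples
#' kruskal_wallis_test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups")
  }
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    return(list(h = 0, df = length(groups) - 1L, p = 1))
  }
  ht <- stats::kruskal.test(x, g)
  list(h = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Screen expression against clinicopathological covariates
#'
#' Tests one gene's per-sample expression values against every covariate
#' of a clinical table: binary covariates by the Mann-Whitney-Wilcoxon
#' test, covariates with more than two observed levels by Kruskal-Wallis;
#' all tests two-sided, no multiple-testing correction (the returned
#' table carries a note to that effect). Covariates with a single observed
#' level are skipped with a warning.
#'
#' @param values Named numeric vector of expression values; names are
#'   sample ids.
#' @param clinical Data.frame with a `sample_id` column and one column per
#'   covariate.
#' @param covariates Covariate columns to test (default: all non-id
#'   columns).
#' @return Data.frame `covariate`, `test` (`"MWW"` / `"Kruskal-Wallis"`),
#'   `p`, `n`, `group_sizes`; attribute `"note"` records the absence of a
#'   multiplicity correction.
#' @export
association_screen <- function(values, clinical,
                               covariates = setdiff(names(clinical),
                                                    "sample_id")) {
  stopifnot(is.numeric(values), !is.null(names(values)),
            is.data.frame(clinical), "sample_id" %in% names(clinical))
  common <- intersect(names(values), clinical$sample_id)
  if (length(common) == 0) stop("no samples shared by values and clinical")
  values <- values[common]
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rows <- lapply(covariates, function(cv) {
    lab <- clinical[[cv]]
    ok <- !is.na(lab) & !is.na(values)
    groups <- split(values[ok], lab[ok])
    if (length(groups) < 2) {
      warning("covariate '", cv, "' has a single observed level; skipped")
      return(NULL)
    }
    if (length(groups) == 2) {
      res <- mww_test(groups[[1]], groups[[2]])
      test <- "MWW"
    } else {
      res <- kruskal_wallis_test(groups)
      test <- "Kruskal-Wallis"
    }
    data.frame(covariate = cv, test = test, p = res$p,
               n = sum(ok),
               group_sizes = paste(lengths(groups), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(covariate = character(0), test = character(0),
                      p = numeric(0), n = integer(0),
                      group_sizes = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "note") <-
    "two-sided tests, no multiple-testing correction; with many covariates expect some false positive associations"
  out
}
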