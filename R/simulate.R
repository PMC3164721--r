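#' Describe a two-platform simulation
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' a two-platform colorectal tumor/normal study: a smaller array series with
#' 46 tumors and 4 normals and a larger one with 91 tumors and 6 normals,
#' each platform carrying a partially overlapping subset of the gene
#' universe, some genes measured by several reporters, and a fraction of
#' genes too flat to pass the variability filter.
#'
#' @param n_genes Number of genes in the simulated universe.
#' @param n_sets Number of gene sets in the matching collection.
#' @param set_size_range Integer length-2 vector, min and max genes per set.
#' @param frac_sets_up,frac_sets_down Fractions of sets planted as up- or
#'   downregulated in tumors (the counts are exact: `round(frac * n_sets)`).
#' @param effect_size Mean tumor shift of planted genes, log2 units.
#' @param noise_sd Per-observation Gaussian noise standard deviation,
#'   log2 units.
#' @param platform_overlap Fraction of universe genes present on each
#'   platform (independent random subsets).
#' @param multiprobe_frac Fraction of a platform's genes measured by 2-3
#'   reporters instead of one.
#' @param lowvar_frac Fraction of a platform's genes rescaled so their IQR
#'   falls below the default variability filter threshold of 0.5.
#' @param samples_a,samples_b Integer length-2 vectors `(n_tumor, n_normal)`
#'   for platforms "A" and "B".
#' @param seed Master RNG seed; all component streams derive from it.
#'
#' @return An object of class `simulation_design` (a validated list).
#' @examples
#' simulation_design(n_genes = 100, n_sets = 10, set_size_range = c(5, 10))
#' @export
simulation_design <- function(n_genes = 1000, n_sets = 200,
                              set_size_range = c(10, 30),
                              frac_sets_up = 0.2, frac_sets_down = 0.2,
                              effect_size = 1.0, noise_sd = 1.0,
                              platform_overlap = 0.8,
                              multiprobe_frac = 0.2, lowvar_frac = 0.1,
                              samples_a = c(46, 4), samples_b = c(91, 6),
                              seed = 1L) {
  stopifnot(length(set_size_range) == 2, length(samples_a) == 2,
            length(samples_b) == 2)
  fracs <- c(frac_sets_up = frac_sets_up, frac_sets_down = frac_sets_down,
             platform_overlap = platform_overlap,
             multiprobe_frac = multiprobe_frac, lowvar_frac = lowvar_frac)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  }
  if (frac_sets_up + frac_sets_down > 1) {
    stop("frac_sets_up + frac_sets_down must not exceed 1")
  }
  if (n_genes < 0 || n_sets < 0) stop("counts must be non-negative")
  if (n_sets > 0 && set_size_range[1] < 1) stop("set_size_range minimum must be >= 1")
  if (set_size_range[1] > set_size_range[2]) {
    stop("set_size_range must be (min, max) with min <= max")
  }
  if (n_sets > 0 && set_size_range[2] > n_genes) {
    stop("invalid design: set_size_range maximum exceeds n_genes")
  }
  for (s in list(samples_a, samples_b)) {
    if (any(s < 2)) stop("need at least 2 samples per class (pooled t-test df)")
  }
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 frac_sets_up = frac_sets_up, frac_sets_down = frac_sets_down,
                 effect_size = effect_size, noise_sd = noise_sd,
                 platform_overlap = platform_overlap,
                 multiprobe_frac = multiprobe_frac, lowvar_frac = lowvar_frac,
                 samples_a = as.integer(samples_a),
                 samples_b = as.integer(samples_b),
                 seed = as.integer(seed)),
            class = "simulation_design")
}

design_universe <- function(design) {
  sprintf("G%05d", seq_len(design$n_genes))
}

#' Generate a gene-set collection with planted truth
#'
#' Draws `n_sets` sets of sizes uniform over `set_size_range` from the gene
#' universe and labels each set up, down or null according to the design
#' fractions (exact counts). A gene recruited by a shifted set inherits
#' that set's direction; later sets of the opposite direction never recruit
#' it, so no gene carries conflicting planted directions. Genes may belong
#' to any number of same-direction or null sets.
#'
#' @param design A [simulation_design()].
#' @return A list with elements `collection` (a [gene_set_collection()])
#'   and `truth`, an object of class `synthetic_truth` holding
#'   `set_direction` (named up/down/null per set), `de_genes` (symbols
#'   carrying the planted shift — exactly the union of non-null set
#'   members) and `gene_direction` (named up/down per de gene).
#' @examples
#' d <- simulation_design(n_genes = 100, n_sets = 10, set_size_range = c(5, 8))
#' generate_collection(d)$truth$set_direction
#' @export
generate_collection <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  universe <- design_universe(design)
  n <- design$n_sets
  if (n == 0) {
    return(list(
      collection = gene_set_collection(stats::setNames(list(), character(0)),
                                       source_tag = "synthetic"),
      truth = structure(list(set_direction = character(0),
                             de_genes = character(0),
                             gene_direction = character(0)),
                        class = "synthetic_truth")))
  }
  n_up <- round(design$frac_sets_up * n)
  n_down <- round(design$frac_sets_down * n)
  ids <- sprintf("SET%04d", seq_len(n))
  with_seed(child_seed(design$seed, "collection"), {
    dir_pool <- c(rep("up", n_up), rep("down", n_down),
                  rep("null", n - n_up - n_down))
    set_direction <- stats::setNames(sample(dir_pool), ids)
    gene_direction <- stats::setNames(character(0), character(0))
    sets <- vector("list", n)
    span <- design$set_size_range[2] - design$set_size_range[1] + 1L
    sizes <- design$set_size_range[1] + sample.int(span, n, replace = TRUE) - 1L
    for (i in seq_len(n)) {
      dir <- set_direction[[i]]
      eligible <- universe
      if (dir != "null") {
        opposite <- names(gene_direction)[gene_direction ==
                                            setdiff(c("up", "down"), dir)]
        eligible <- setdiff(universe, opposite)
      }
      k <- min(sizes[i], length(eligible))
      members <- sample(eligible, k)
      if (dir != "null") {
        fresh <- setdiff(members, names(gene_direction))
        gene_direction[fresh] <- dir
      }
      sets[[i]] <- members
    }
    names(sets) <- ids
    list(
      collection = gene_set_collection(
        sets,
        descriptions = sprintf("synthetic set %s (%s)", ids, set_direction),
        source_tag = "synthetic"),
      truth = structure(
        list(set_direction = set_direction,
             de_genes = sort(unique(unlist(sets[set_direction != "null"],
                                           use.names = FALSE))),
             gene_direction = gene_direction),
        class = "synthetic_truth"))
  })
}

#' Generate one platform's expression dataset
#'
#' Simulates a reporter-by-sample log2 intensity matrix for platform `"A"`
#' or `"B"` of the design. Each gene has a baseline intensity drawn once
#' from Normal(8, 1) (shared across platforms); every observation adds
#' independent Normal(0, `noise_sd`) noise; tumor samples of planted genes
#' are shifted by plus or minus `effect_size` according to the truth.
#' Multi-reporter genes emit 2-3 reporters sharing the gene's signal with
#' independent noise. Low-variability genes (chosen preferentially among
#' non-planted genes) have their sample-wise deviations rescaled to an IQR
#' of 0.25, below the default filter threshold. Each platform measures an
#' independent random subset of `platform_overlap * n_genes` genes.
#'
#' @param design A [simulation_design()].
#' @param truth The `truth` component returned by [generate_collection()].
#' @param platform `"A"` or `"B"`.
#' @return An [expression_dataset()].
#' @examples
#' d <- simulation_design(n_genes = 50, n_sets = 4, set_size_range = c(5, 8),
#'                        samples_a = c(5, 3), samples_b = c(6, 3))
#' gc <- generate_collection(d)
#' generate_expression(d, gc$truth, "A")
#' @export
generate_expression <- function(design, truth, platform = c("A", "B")) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(truth, "synthetic_truth"))
  if (!is.character(platform) || !all(platform %in% c("A", "B"))) {
    stop("unknown platform id; expected \"A\" or \"B\"")
  }
  platform <- match.arg(platform)
  if (length(truth$de_genes) &&
      !all(truth$de_genes %in% design_universe(design))) {
    stop("design/truth mismatch: truth genes outside the design universe")
  }
  universe <- design_universe(design)
  counts <- if (platform == "A") design$samples_a else design$samples_b
  n_tumor <- counts[1]; n_normal <- counts[2]

  baseline <- with_seed(child_seed(design$seed, "baseline"),
                        stats::setNames(stats::rnorm(design$n_genes, 8, 1),
                                        universe))

  with_seed(child_seed(design$seed, paste0("expression-", platform)), {
    genes <- sort(sample(universe,
                         round(design$platform_overlap * design$n_genes)))
    n_g <- length(genes)
    n_multi <- round(design$multiprobe_frac * n_g)
    multi <- sample(genes, n_multi)
    n_low <- round(design$lowvar_frac * n_g)
    # prefer non-planted genes so the rescaling does not erase the signal
    non_de <- setdiff(genes, truth$de_genes)
    low <- if (n_low <= length(non_de)) sample(non_de, n_low) else
      c(non_de, sample(intersect(genes, truth$de_genes),
                       n_low - length(non_de)))

    n_rep <- stats::setNames(rep(1L, n_g), genes)
    n_rep[multi] <- sample(2:3, n_multi, replace = TRUE)
    gene_of_row <- rep(genes, times = n_rep[genes])
    reporter_ids <- paste0(platform, "_", gene_of_row, "_r",
                           unlist(lapply(n_rep[genes], seq_len),
                                  use.names = FALSE))

    sample_ids <- c(paste0(platform, "_T", seq_len(n_tumor)),
                    paste0(platform, "_N", seq_len(n_normal)))
    classes <- c(rep("tumor", n_tumor), rep("normal", n_normal))

    shift <- stats::setNames(rep(0, n_g), genes)
    de_here <- intersect(genes, truth$de_genes)
    shift[de_here] <- ifelse(truth$gene_direction[de_here] == "up",
                             design$effect_size, -design$effect_size)

    n_s <- n_tumor + n_normal
    mu <- matrix(baseline[gene_of_row], nrow = length(gene_of_row),
                 ncol = n_s)
    mu[, classes == "tumor"] <- mu[, classes == "tumor"] + shift[gene_of_row]
    values <- mu + matrix(stats::rnorm(length(mu), 0, design$noise_sd),
                          nrow = nrow(mu))

    low_rows <- which(gene_of_row %in% low)
    for (i in low_rows) {
      x <- values[i, ]
      iqr <- stats::IQR(x)
      if (iqr > 0) values[i, ] <- mean(x) + (x - mean(x)) * (0.25 / iqr)
    }

    expression_dataset(values, reporter_ids, gene_of_row, sample_ids,
                       classes, platform)
  })
}

#' Generate a clinical label table (with optional planted associations)
#'
#' Draws per-tumor molecular and clinicopathological labels of the kind a
#' colorectal series carries: microsatellite status (MSI/MSS), mutation
#' status for KRAS, BRAF, TP53, PTEN and PIK3CA, tumor stage I-IV, and
#' localization (right/left/rectum). For each entry of `effects`, the named
#' genes' tumor values are additionally shifted in the labeled subgroup, so
#' a rank-based association screen can recover the covariate.
#'
#' @param design A [simulation_design()].
#' @param truth The truth from [generate_collection()].
#' @param dataset The [expression_dataset()] whose tumors are labeled.
#' @param effects Optional named list: names are covariate names from the
#'   generated table; each element is `list(genes =, shift =, level =)`,
#'   where `level` (default: the covariate's first non-reference level,
#'   e.g. `"mut"` or `"MSI"`) selects the subgroup whose tumor values of
#'   `genes` are shifted by `shift` log2 units.
#' @return A list: `clinical` (data.frame, one row per tumor sample),
#'   `dataset` (the input dataset with planted subgroup shifts applied)
#'   and `effects` (as supplied).
#' @examples
#' d <- simulation_design(n_genes = 50, n_sets = 2, set_size_range = c(5, 6),
#'                        samples_a = c(10, 3), samples_b = c(10, 3))
#' gc <- generate_collection(d)
#' ds <- generate_expression(d, gc$truth, "A")
#' cl <- generate_clinical(d, gc$truth, ds)
#' head(cl$clinical)
#' @export
generate_clinical <- function(design, truth, dataset, effects = NULL) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(dataset, "expression_dataset"))
  tumors <- dataset$samples[dataset$classes == "tumor"]
  n <- length(tumors)
  defaults <- list(msi = c("MSI", "MSS"), kras_mut = c("mut", "wt"),
                   braf_mut = c("mut", "wt"), tp53_mut = c("mut", "wt"),
                   pten_mut = c("mut", "wt"), pik3ca_mut = c("mut", "wt"))
  probs <- c(msi = 0.3, kras_mut = 0.4, braf_mut = 0.1, tp53_mut = 0.5,
             pten_mut = 0.1, pik3ca_mut = 0.15)
  with_seed(child_seed(design$seed, paste0("clinical-", dataset$platform)), {
    clinical <- data.frame(sample_id = tumors, stringsAsFactors = FALSE)
    for (cv in names(defaults)) {
      lv <- defaults[[cv]]
      clinical[[cv]] <- ifelse(stats::rbinom(n, 1, probs[[cv]]) == 1,
                               lv[1], lv[2])
    }
    clinical$stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                             prob = c(0.2, 0.3, 0.35, 0.15))
    clinical$localization <- sample(c("right", "left", "rectum"), n,
                                    replace = TRUE)

    if (!is.null(effects)) {
      for (cv in names(effects)) {
        if (!cv %in% names(clinical)) {
          stop("effect references unknown covariate: ", cv)
        }
        eff <- effects[[cv]]
        genes <- eff$genes
        if (!all(genes %in% dataset$genes)) {
          stop("effect on '", cv, "' references unknown gene: ",
               paste(setdiff(genes, dataset$genes), collapse = ", "))
        }
        level <- eff$level %||% {
          lv <- intersect(c("MSI", "mut"), unique(clinical[[cv]]))
          if (length(lv)) lv[1] else sort(unique(clinical[[cv]]))[1]
        }
        in_group <- clinical$sample_id[clinical[[cv]] == level]
        rows <- which(dataset$genes %in% genes)
        cols <- which(dataset$samples %in% in_group)
        dataset$values[rows, cols] <- dataset$values[rows, cols] + eff$shift
      }
    }
    list(clinical = clinical, dataset = dataset, effects = effects)
  })
}

#' Generate a synthetic qMSP panel
#'
#' Emulates the input of a quantitative methylation-specific PCR experiment:
#' per-sample target (methylation-specific) and ALU reference quantities,
#' one fully methylated positive control, and a panel of normal samples.
#' Methylated tumor samples receive a target/reference ratio that is a
#' random positive fraction of the positive control's ratio; unmethylated
#' samples and all normals have target quantity 0.
#'
#' @param n_samples Number of tumor samples.
#' @param n_normals Number of normal-panel samples.
#' @param frac_methylated Fraction of tumor samples methylated (the count
#'   is `round(frac_methylated * n_samples)`).
#' @param seed RNG seed.
#' @return A data.frame with columns `sample_id`, `role`
#'   (`"sample"`/`"normal"`/`"positive-control"`), `target_qty`, `ref_qty`.
#' @examples
#' generate_qmsp_panel(10, 4, 0.3, seed = 1)
#' @export
generate_qmsp_panel <- function(n_samples, n_normals, frac_methylated,
                                seed = 1L) {
  if (frac_methylated < 0 || frac_methylated > 1) {
    stop("frac_methylated must lie in [0, 1]")
  }
  stopifnot(n_samples >= 0, n_normals >= 0)
  with_seed(child_seed(seed, "qmsp"), {
    ctrl_ref <- stats::runif(1, 40, 60)
    ctrl_ratio <- 1  # fully methylated reference
    n_meth <- round(frac_methylated * n_samples)
    meth <- seq_len(n_samples) <= n_meth
    ref <- stats::runif(n_samples, 20, 100)
    ratio <- ifelse(meth, stats::runif(n_samples, 0.01, 1) * ctrl_ratio, 0)
    normals_ref <- stats::runif(n_normals, 20, 100)
    out <- rbind(
      data.frame(sample_id = "POS", role = "positive-control",
                 target_qty = ctrl_ratio * ctrl_ref, ref_qty = ctrl_ref,
                 stringsAsFactors = FALSE),
      if (n_samples > 0)
        data.frame(sample_id = sprintf("S%03d", seq_len(n_samples)),
                   role = "sample", target_qty = ratio * ref, ref_qty = ref,
                   stringsAsFactors = FALSE),
      if (n_normals > 0)
        data.frame(sample_id = sprintf("N%03d", seq_len(n_normals)),
                   role = "normal", target_qty = 0, ref_qty = normals_ref,
                   stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
  })
}
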