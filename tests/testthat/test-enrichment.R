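test_that("pooled t-test matches the textbook formula and is antisymmetric", {
  got <- two_class_ttest(c(1, 2, 3), c(4, 5, 6))
  want <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, want$t)
  expect_equal(got$p, want$p)
  # frozen from the oracle: t = -3/sqrt(2/3), df = 4
  expect_equal(got$t, -sqrt(13.5))
  expect_equal(got$p, 2 * pt(-sqrt(13.5), 4))

  set.seed(42)
  for (r in 1:10) {
    g1 <- rnorm(sample(2:8, 1)); g2 <- rnorm(sample(2:8, 1), 0.5)
    a <- two_class_ttest(g1, g2)
    b <- two_class_ttest(g2, g1)
    o <- oracle_pooled_t(g1, g2)
    expect_equal(a$t, o$t)
    expect_equal(a$p, o$p)
    expect_equal(a$t, -b$t)   # label swap negates t
    expect_equal(a$p, b$p)    # ... and leaves p unchanged
    shifted <- two_class_ttest(g1 + 7, g2 + 7)  # location invariance
    expect_equal(shifted$t, a$t)
  }

  same <- two_class_ttest(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("zero pooled variance is flagged, not fatal", {
  a <- two_class_ttest(c(2, 2), c(1, 1))
  expect_identical(a$t, Inf)
  expect_identical(a$p, 0)
  expect_true(a$zero_variance)
  b <- two_class_ttest(c(1, 1), c(2, 2))
  expect_identical(b$t, -Inf)
  c0 <- two_class_ttest(c(3, 3, 3), c(3, 3))
  expect_identical(c0$t, 0)
  expect_identical(c0$p, 1)
  expect_true(c0$zero_variance)
})

test_that("log fold change is the difference of log-scale group means", {
  expect_equal(log_fold_change(c(3, 3), c(1, 1)), 2)
  expect_equal(log_fold_change(c(1, 2), c(2, 1)), 0)
  expect_equal(log_fold_change(c(1, 2), c(5, 9)), -5.5)
  expect_equal(log_fold_change(c(5, 9), c(1, 2)), 5.5)  # antisymmetry
})

test_that("enrichment score is sum of t over sqrt(set size)", {
  expect_equal(enrichment_score(2.0), 2.0)
  expect_equal(enrichment_score(rep(0, 7)), 0)
  expect_equal(enrichment_score(c(1, 2, 3)), 6 / sqrt(3))
  expect_error(enrichment_score(numeric(0)), "empty")
  expect_error(enrichment_score(c(1, Inf)), "non-finite")
})

test_that("vectorized per-gene statistics agree with scalar t.test", {
  set.seed(7)
  ds <- random_dataset(n_reporters = 30, n_tumor = 6, n_normal = 5,
                       n_genes = 30)
  coll <- gene_set_collection(list(S = unique(ds$genes)))
  res <- run_enrichment(ds, coll, analysis_config(min_set_size = 1))
  is_tumor <- ds$classes == "tumor"
  for (i in seq_len(nrow(ds$values))) {
    ht <- t.test(ds$values[i, is_tumor], ds$values[i, !is_tumor],
                 var.equal = TRUE)
    j <- which(res$gene_stats$gene == ds$genes[i])
    expect_equal(res$gene_stats$t[j], unname(ht$statistic))
    expect_equal(res$gene_stats$p[j], ht$p.value)
    expect_equal(res$gene_stats$lfc[j],
                 mean(ds$values[i, is_tumor]) - mean(ds$values[i, !is_tumor]))
  }
  expect_true(all(sign(res$gene_stats$lfc) == sign(res$gene_stats$t)))
})

test_that("normal-reference set P-values hit standard normal quantiles", {
  cfg <- analysis_config(set_pvalue_method = "normal")
  expect_equal(set_pvalue(0, config = cfg), 1)
  expect_equal(set_pvalue(qnorm(0.975), config = cfg), 0.05)
  expect_equal(set_pvalue(-qnorm(0.975), config = cfg), 0.05)
  expect_equal(set_pvalue(qnorm(0.9995), config = cfg), 0.001)
})

test_that("permutation P-values match exhaustive enumeration on small data", {
  for (r in 1:5) {
    set.seed(500 + r)
    n_tumor <- sample(2:3, 1); n_normal <- sample(2:3, 1)
    ds <- random_dataset(n_reporters = 8, n_tumor = n_tumor,
                         n_normal = n_normal, n_genes = 8)
    members <- sample(unique(ds$genes), 4)
    cfg <- analysis_config(set_pvalue_method = "permutation",
                           n_permutations = 1000, min_set_size = 1)
    rows <- which(ds$genes %in% members)
    is_tumor <- ds$classes == "tumor"
    X <- ds$values[, c(which(is_tumor), which(!is_tumor)), drop = FALSE]
    obs_t <- vapply(rows, function(i) {
      oracle_pooled_t(ds$values[i, is_tumor], ds$values[i, !is_tumor])$t
    }, numeric(1))
    obs <- sum(obs_t) / sqrt(length(obs_t))
    want <- oracle_perm_pvalue(X, n_tumor, rows)
    got <- set_pvalue(obs, dataset = ds, members = members, config = cfg)
    expect_equal(got, want)
    expect_gte(got, 1 / (choose(n_tumor + n_normal, n_tumor)))
  }
})

test_that("sampled permutation P-values respect the plus-one bound", {
  set.seed(9)
  ds <- random_dataset(n_reporters = 12, n_tumor = 8, n_normal = 6,
                       n_genes = 12)
  cfg <- analysis_config(set_pvalue_method = "permutation",
                         n_permutations = 99, min_set_size = 1)
  members <- unique(ds$genes)[1:5]
  p <- set_pvalue(10, dataset = ds, members = members, config = cfg)
  expect_gte(p, 1 / 100)
  expect_lte(p, 1)
})

test_that("run_enrichment is deterministic and antisymmetric in the labels", {
  set.seed(11)
  ds <- random_dataset(n_reporters = 24, n_tumor = 5, n_normal = 5,
                       n_genes = 24)
  coll <- gene_set_collection(list(
    S1 = unique(ds$genes)[1:8], S2 = unique(ds$genes)[9:20]))
  cfg <- analysis_config(min_set_size = 1,
                         set_pvalue_method = "permutation",
                         n_permutations = 200, seed = 3)
  r1 <- run_enrichment(ds, coll, cfg)
  r2 <- run_enrichment(ds, coll, cfg)
  expect_identical(r1, r2)
  expect_identical(nrow(r1$pathway_results), 2L)

  flipped <- expression_dataset(
    ds$values, ds$reporters, ds$genes, ds$samples,
    ifelse(ds$classes == "tumor", "normal", "tumor"), ds$platform)
  r3 <- run_enrichment(flipped, coll, cfg)
  expect_equal(r3$gene_stats$t, -r1$gene_stats$t)
  expect_equal(r3$gene_stats$lfc, -r1$gene_stats$lfc)
  expect_equal(r3$gene_stats$p, r1$gene_stats$p)
  expect_equal(r3$pathway_results$score, -r1$pathway_results$score)
})

test_that("a planted upregulated pathway scores positive", {
  d <- simulation_design(n_genes = 200, n_sets = 6, set_size_range = c(15, 15),
                         frac_sets_up = 0.5, frac_sets_down = 0,
                         effect_size = 1, noise_sd = 1, lowvar_frac = 0,
                         samples_a = c(46, 4), seed = 31)
  gc <- generate_collection(d)
  ds <- generate_expression(d, gc$truth, "A")
  pre <- preprocess_dataset(ds, gc$collection, analysis_config())
  res <- run_enrichment(pre$dataset, pre$collection, analysis_config())
  up_ids <- names(gc$truth$set_direction)[gc$truth$set_direction == "up"]
  up_ids <- intersect(up_ids, res$pathway_results$set_id)
  expect_true(length(up_ids) > 0)
  scores <- res$pathway_results$score[match(up_ids,
                                            res$pathway_results$set_id)]
  expect_true(all(scores > 0))
})

test_that("normal-method set P-values are roughly calibrated under the null", {
  d <- simulation_design(n_genes = 800, n_sets = 80, set_size_range = c(10, 20),
                         frac_sets_up = 0, frac_sets_down = 0,
                         effect_size = 0, lowvar_frac = 0, multiprobe_frac = 0,
                         platform_overlap = 1,
                         samples_a = c(46, 4), seed = 77)
  gc <- generate_collection(d)
  ds <- generate_expression(d, gc$truth, "A")
  pre <- preprocess_dataset(ds, gc$collection, analysis_config())
  res <- run_enrichment(pre$dataset, pre$collection,
                        analysis_config(set_pvalue_method = "normal"))
  # slight anticonservatism is expected (t variance df/(df-2) > 1); the
  # rejection rate should still sit loosely around alpha
  rate <- mean(res$pathway_results$p <= 0.05)
  expect_lt(rate, 0.15)
})

test_that("degenerate inputs are rejected", {
  set.seed(2)
  ds <- random_dataset(n_reporters = 6, n_tumor = 2, n_normal = 2,
                       n_genes = 6)
  one_class <- expression_dataset(ds$values, ds$reporters, ds$genes,
                                  ds$samples, rep("tumor", 4))
  coll <- gene_set_collection(list(S = unique(ds$genes)))
  expect_error(run_enrichment(one_class, coll,
                              analysis_config(min_set_size = 1)),
               "at least 2")
  dup <- random_dataset(n_reporters = 8, n_tumor = 3, n_normal = 3,
                        n_genes = 3)
  expect_error(run_enrichment(dup, coll, analysis_config(min_set_size = 1)),
               "collapse")
})
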