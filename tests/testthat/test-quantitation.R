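test_that("standard curve quantification inverts the fitted line", {
  # perfect 10-fold dilution series with slope -3.32
  curve <- data.frame(log10_quantity = 0:4, ct = 32 - 3.32 * (0:4))
  # interpolating a curve point's own Ct returns its quantity
  for (i in seq_len(nrow(curve))) {
    expect_equal(standard_curve_quantify(curve$ct[i], curve),
                 10 ^ curve$log10_quantity[i])
  }
  # Ct midway between two points -> geometric mean of their quantities
  mid_ct <- mean(curve$ct[2:3])
  expect_equal(standard_curve_quantify(mid_ct, curve),
               sqrt(10 ^ curve$log10_quantity[2] * 10 ^ curve$log10_quantity[3]))

  # noisy points: fit must match the closed-form least-squares solution
  set.seed(3)
  noisy <- data.frame(log10_quantity = rep(0:4, 2),
                      ct = 30 - 3.1 * rep(0:4, 2) + rnorm(10, 0, 0.3))
  x <- noisy$log10_quantity; y <- noisy$ct
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  ct <- c(22.5, 27.1)
  expect_equal(standard_curve_quantify(ct, noisy), 10 ^ ((ct - a) / b))

  flat <- data.frame(log10_quantity = 0:3, ct = rep(25, 4))
  expect_error(standard_curve_quantify(24, flat), "flat")
  expect_error(standard_curve_quantify(24,
               data.frame(log10_quantity = c(1, 1), ct = c(20, 21))),
               "distinct")
})

test_that("expression normalization uses replicate medians and control means", {
  t1 <- qpcr_measurement("s1", "PLCD1", c(1.0, 1.1, 5.0))
  c1 <- qpcr_measurement("s1", "ACTB", c(2, 2, 2))
  c2 <- qpcr_measurement("s1", "GUSB", c(4, 4, 4))
  expect_equal(normalize_expression(t1, list(c1, c2)), 1.1 / 3)

  t2 <- qpcr_measurement("s1", "PLCE1", c(3, 3, 3))
  expect_equal(normalize_expression(t2, list(c1, c2)), 1.0)
  expect_equal(normalize_expression(t2, list(c1)), 1.5)

  z <- qpcr_measurement("s1", "ACTB", c(0, 0, 0))
  expect_error(normalize_expression(t2, list(z)), "zero")
  expect_error(qpcr_measurement("s", "a", numeric(0)), "replicate")
  expect_error(qpcr_measurement("s", "a", c(1, -2)), "non-negative")
})

test_that("PMR follows the ALU-normalized ratio-of-ratios definition", {
  ctrl <- list(target_qty = 8, ref_qty = 50)
  expect_equal(pmr(list(target_qty = 8, ref_qty = 50), ctrl), 100)
  expect_equal(pmr(list(target_qty = 0, ref_qty = 30), ctrl), 0)
  expect_equal(pmr(list(target_qty = 2, ref_qty = 50), ctrl), 25)
  # scale invariance in the sample's quantities
  set.seed(4)
  for (r in 1:10) {
    s <- list(target_qty = runif(1, 0, 5), ref_qty = runif(1, 1, 100))
    c_scale <- runif(1, 0.01, 50)
    scaled <- list(target_qty = s$target_qty * c_scale,
                   ref_qty = s$ref_qty * c_scale)
    expect_equal(pmr(scaled, ctrl), pmr(s, ctrl))
  }
  expect_error(pmr(list(target_qty = 1, ref_qty = 0), ctrl), "positive")
  expect_error(pmr(list(target_qty = 1, ref_qty = 10),
                   list(target_qty = 0, ref_qty = 10)), "positive control")
})

test_that("methylation calls exceed the normal-panel maximum strictly", {
  expect_true(call_methylation(5.69))          # typical low-PMR positive
  expect_false(call_methylation(0))
  expect_false(call_methylation(1.2, c(0, 1.2, 0.4)))  # ties are negative
  expect_true(call_methylation(1.3, c(0, 1.2, 0.4)))
  expect_error(call_methylation(-1), "non-negative")
  # monotone in the PMR value, antitone in the panel maximum
  panel <- c(0.5, 2, 0)
  calls <- vapply(c(0, 1, 2, 2.1, 5), call_methylation, logical(1),
                  normal_panel_pmrs = panel)
  expect_identical(calls, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(call_methylation(1, c(0.5)))
  expect_false(call_methylation(1, c(0.5, 1.5)))
})

test_that("exact MWW equals the enumeration oracle for all sizes <= 6", {
  expect_equal(mww_test(c(1, 2, 3), c(4, 5, 6))$p, 0.1)  # 2/20 enumerated
  expect_equal(mww_test(c(1, 2, 3), c(4, 5, 6))$p,
               oracle_mww_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(6)
  for (n1 in 1:6) {
    for (n2 in max(n1, 2):6) {
      g1 <- rnorm(n1); g2 <- rnorm(n2, 0.8)
      res <- mww_test(g1, g2)
      expect_true(res$exact)
      expect_equal(res$p, oracle_mww_p(g1, g2))
      expect_equal(mww_test(g2, g1)$p, res$p)  # group-swap symmetry
    }
  }
})

test_that("MWW falls back to the tie-corrected normal approximation", {
  g <- c(1, 2, 3)
  res <- mww_test(g, g)  # same multiset -> ties -> approximation, p = 1
  expect_false(res$exact)
  expect_equal(res$p, 1)
  big1 <- rnorm(12); big2 <- rnorm(15)
  expect_false(mww_test(big1, big2)$exact)
  expect_error(mww_test(numeric(0), 1:3), "at least one")
})

test_that("Kruskal-Wallis H matches a hand-coded rank computation", {
  groups <- list(c(2.1, 3.3, 1.2), c(4.4, 5.1, 2.2, 6.0), c(0.5, 1.9))
  res <- kruskal_wallis_test(groups)
  expect_equal(res$h, oracle_kw_h(groups))
  expect_identical(res$df, 2L)
  expect_equal(res$p, pchisq(res$h, 2, lower.tail = FALSE))

  with_ties <- list(c(1, 2, 2), c(2, 3, 4), c(4, 4, 5))
  expect_equal(kruskal_wallis_test(with_ties)$h, oracle_kw_h(with_ties))

  const <- list(c(3, 3), c(3, 3, 3))
  expect_equal(kruskal_wallis_test(const)$h, 0)
  expect_equal(kruskal_wallis_test(const)$p, 1)
  expect_error(kruskal_wallis_test(list(1:3)), "two groups")
})

test_that("two-group Kruskal-Wallis agrees with the MWW approximation", {
  set.seed(12)
  for (r in 1:20) {
    g1 <- rnorm(sample(9:15, 1)); g2 <- rnorm(sample(9:15, 1), 0.4)
    p_kw <- kruskal_wallis_test(list(g1, g2))$p
    p_mww <- mww_test(g1, g2)$p
    expect_equal(p_kw, p_mww, tolerance = 1e-12)
  }
})

test_that("association screen routes covariates and finds planted effects", {
  d <- simulation_design(n_genes = 80, n_sets = 2, set_size_range = c(5, 6),
                         samples_a = c(70, 4), noise_sd = 1, seed = 23)
  gc <- generate_collection(d)
  ds <- generate_expression(d, gc$truth, "A")
  gene <- setdiff(unique(ds$genes), gc$truth$de_genes)[1]
  cl <- generate_clinical(d, gc$truth, ds,
                          effects = list(kras_mut = list(genes = gene,
                                                         shift = 2.5)))
  row <- which(cl$dataset$genes == gene)[1]
  tumors <- cl$dataset$classes == "tumor"
  vals <- setNames(cl$dataset$values[row, tumors],
                   cl$dataset$samples[tumors])
  scr <- association_screen(vals, cl$clinical)
  expect_identical(scr$test[scr$covariate == "kras_mut"], "MWW")
  expect_identical(scr$test[scr$covariate == "stage"], "Kruskal-Wallis")
  expect_identical(scr$test[scr$covariate == "localization"],
                   "Kruskal-Wallis")
  expect_lt(scr$p[scr$covariate == "kras_mut"], 0.05)
  expect_match(attr(scr, "note"), "multiple-testing")

  # single-level covariate skipped with a warning
  cl2 <- cl$clinical
  cl2$constant <- "x"
  expect_warning(scr2 <- association_screen(vals, cl2),
                 "single observed level")
  expect_false("constant" %in% scr2$covariate)
})

test_that("association P-values are roughly uniform without planted effects", {
  d <- simulation_design(n_genes = 200, n_sets = 2, set_size_range = c(5, 6),
                         samples_a = c(60, 4), seed = 29,
                         frac_sets_up = 0, frac_sets_down = 0)
  gc <- generate_collection(d)
  ds <- generate_expression(d, gc$truth, "A")
  cl <- generate_clinical(d, gc$truth, ds)
  tumors <- ds$classes == "tumor"
  ps <- vapply(seq_len(min(150, nrow(ds$values))), function(i) {
    vals <- setNames(ds$values[i, tumors], ds$samples[tumors])
    lab <- cl$clinical$msi[match(names(vals), cl$clinical$sample_id)]
    mww_test(vals[lab == "MSI"], vals[lab == "MSS"])$p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / length(ps)))
  expect_gt(mean(ps), 0.4)  # centered like a uniform
})

test_that("pmr_table demands exactly one positive control", {
  panel <- generate_qmsp_panel(5, 2, 0.4, seed = 1)
  expect_error(pmr_table(panel[panel$role != "positive-control", ]),
               "exactly one")
  two <- rbind(panel, panel[panel$role == "positive-control", ])
  expect_error(pmr_table(two), "exactly one")
})
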