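test_that("run_contrast matches per-feature Student t-tests", {
  set.seed(101)
  sheet <- toy_sheet(c("M0", "M1"), 3)
  em <- toy_matrix(rnorm(40 * 6, 8, 1.5), sprintf("G%02d", 1:40),
                   sheet$sample_id)
  de <- run_contrast(em, sheet, "M1", "M0")
  vals <- expr_values(em)
  for (i in c(1, 7, 23, 40)) {
    ref <- t.test(vals[i, 4:6], vals[i, 1:3], var.equal = TRUE)
    expect_equal(de$t_statistic[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(de$log2_fold_change[i],
                 mean(vals[i, 4:6]) - mean(vals[i, 1:3]), tolerance = 1e-12)
  }
  # Welch option matches t.test default
  dew <- run_contrast(em, sheet, "M1", "M0", var_equal = FALSE)
  refw <- t.test(vals[5, 4:6], vals[5, 1:3])
  expect_equal(dew$p_value[5], refw$p.value, tolerance = 1e-12)
})

test_that("fold-change arithmetic follows the log2 convention", {
  sheet <- toy_sheet(c("M0", "M1"), 3)
  # identical values in both groups -> fold 1, p = 1, t = 0
  em <- toy_matrix(c(rep(5, 6),
                     c(2, 2, 2, 10.732, 10.732, 10.732)),
                   c("FLAT", "BIG"), sheet$sample_id)
  de <- run_contrast(em, sheet, "M1", "M0")
  flat <- de[de$feature_id == "FLAT", ]
  expect_identical(flat$log2_fold_change, 0)
  expect_identical(flat$linear_fold, 1)
  expect_identical(flat$t_statistic, 0)
  expect_identical(flat$p_value, 1)
  expect_true(flat$zero_variance)
  # log2FC 8.732 corresponds to the 425-fold regime
  big <- de[de$feature_id == "BIG", ]
  expect_equal(big$log2_fold_change, 8.732, tolerance = 1e-12)
  expect_equal(big$linear_fold, 2^8.732, tolerance = 1e-12)
  expect_equal(big$linear_fold, 425, tolerance = 0.001)
  # negative log2FC gives a negative signed fold of the same magnitude
  em2 <- toy_matrix(c(8, 8, 8, 6, 6, 6), "DOWN", sheet$sample_id)
  de2 <- run_contrast(em2, sheet, "M1", "M0")
  expect_equal(de2$linear_fold, -4)
})

test_that("t-test p-values rank features like an exhaustive permutation test", {
  set.seed(202)
  sheet <- toy_sheet(c("M0", "M1"), 3)
  em <- toy_matrix(c(rnorm(6, c(5, 5, 5, 9, 9, 9), 0.5),   # strong shift
                     rnorm(6, c(5, 5, 5, 6.5, 6.5, 6.5), 0.5), # medium
                     rnorm(6, 5, 0.5)),                     # null
                   c("STRONG", "MEDIUM", "NULL1"), sheet$sample_id)
  de <- run_contrast(em, sheet, "M1", "M0")
  vals <- expr_values(em)
  # permutation oracle: all 20 assignments of 6 samples to two groups of 3
  perm_p <- apply(vals, 1L, function(x) {
    obs <- abs(mean(x[4:6]) - mean(x[1:3]))
    splits <- utils::combn(6, 3)
    stats <- apply(splits, 2L, function(idx) {
      abs(mean(x[idx]) - mean(x[-idx]))
    })
    mean(stats >= obs - 1e-12)
  })
  expect_identical(order(de$p_value), order(perm_p))
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_identical(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(33)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), brute_force_bh(p), tolerance = 1e-12)
  }
  # order invariance
  p <- runif(15)
  perm <- sample(15)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
})

test_that("contrast summaries count up/down significant features", {
  empty <- summarize_contrast(
    tibble::tibble(feature_id = character(0), p_value = numeric(0),
                   log2_fold_change = numeric(0)), 0.05)
  expect_identical(empty$n_significant, 0L)
  expect_identical(empty$n_up + empty$n_down, 0L)

  rec <- tibble::tibble(
    feature_id = paste0("g", 1:10),
    p_value = c(rep(1e-5, 4), rep(0.5, 6)),
    log2_fold_change = c(2, 1, 0.5, -1, 1, -1, 2, -2, 0, 3)
  )
  s <- summarize_contrast(rec, 1e-4)
  expect_identical(s$n_significant, 4L)
  expect_identical(s$n_up, 3L)
  expect_identical(s$n_down, 1L)
  expect_equal(s$pct_up, 75)
  expect_equal(s$pct_up + s$pct_down, 100)
  # significant feature with log2FC exactly 0 counts as neither class
  rec0 <- tibble::tibble(feature_id = "g", p_value = 1e-6,
                         log2_fold_change = 0)
  s0 <- summarize_contrast(rec0, 1e-4)
  expect_identical(s0$n_significant, 1L)
  expect_identical(s0$n_up + s0$n_down, 0L)
})

test_that("type-I error of the contrast is near alpha under the global null", {
  set.seed(404)
  sheet <- toy_sheet(c("M0", "M1"), 3)
  em <- toy_matrix(rnorm(2000 * 6, 7, 1), sprintf("N%04d", 1:2000),
                   sheet$sample_id)
  de <- run_contrast(em, sheet, "M1", "M0")
  frac <- mean(de$p_value < 0.05)
  # binomial sd at p=0.05, n=2000 is ~0.0049; allow 4 sd
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("miRNA shortlist applies the strict reference-fraction rule", {
  sheet <- toy_sheet(c("M0", "M1"), 2)
  # means chosen on log2 scale so linear means are exact fractions of ref
  ref_level <- 10
  ids <- c("miR-ref", "miR-half", "miR-above", "miR-low", "miR-notsig")
  em <- toy_matrix(c(rep(ref_level, 4),
                     rep(ref_level - 1, 4),        # exactly 50% of ref
                     rep(ref_level - 0.5, 4),      # ~70% of ref
                     rep(ref_level - 3, 4),        # 12.5% of ref
                     rep(ref_level - 0.2, 4)),     # high but not significant
                   ids, sheet$sample_id, feature_kind = "miRNA")
  rec <- tibble::tibble(
    feature_id = normalize_mirna(ids),
    log2_fold_change = c(1, 1, -1, 1, 0.5),
    p_value = c(0.01, 0.01, 0.01, 0.01, 0.5)
  )
  out <- select_mirnas(rec, em, "miR-ref", min_fraction = 0.5,
                       p_threshold = 0.05)
  # at exactly 50% the strict inequality excludes; the reference itself stays
  expect_setequal(out$mirna_id, c("miR-ref", "miR-above"))
  expect_identical(out$direction[out$mirna_id == "miR-above"], "down")
  expect_error(select_mirnas(rec, em, "miR-missing"), "not found")
})

test_that("ddCT conversion and method concordance behave as defined", {
  expect_identical(ddct_to_fold(0), 1)
  expect_identical(ddct_to_fold(-2), 4)
  x <- c(-3.1, 0, 2.5)
  expect_equal(fold_to_ddct(ddct_to_fold(x)), x, tolerance = 1e-12)

  a <- c(1, 2, 3, 5, 8)
  expect_equal(method_concordance(a, 2 * a + 1), 1, tolerance = 1e-12)
  # r^2 is invariant to affine rescaling
  b <- c(2, 1, 4, 3, 7)
  expect_equal(method_concordance(a, b),
               method_concordance(3 * a - 2, -0.5 * b + 4), tolerance = 1e-12)
  set.seed(9)
  big_a <- rnorm(5000); big_b <- rnorm(5000)
  expect_lt(method_concordance(big_a, big_b), 0.01)
  expect_error(method_concordance(1:4, 1:5), "equal length")
  expect_error(method_concordance(c(1, 1, 1), c(1, 2, 3)), "variance")
})
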