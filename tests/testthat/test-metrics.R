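test_that("confusion counts exclude white background and partition pixels", {
  # 3x3 toy: reference tumour = left column, prediction = top row,
  # background = bottom-right pixel
  ref <- matrix(0L, 3, 3); ref[, 1] <- 1L
  pred <- matrix(0L, 3, 3); pred[1, ] <- 1L
  bg <- matrix(0L, 3, 3); bg[3, 3] <- 1L
  cc <- confusion_counts(pred, ref, bg)
  expect_equal(cc$N, 8)
  expect_equal(cc$TP, 1)
  expect_equal(cc$FN, 2)
  expect_equal(cc$FP, 2)
  expect_equal(cc$TN, 3)
  expect_equal(cc$RP, cc$TP + cc$FN)
  expect_equal(cc$PP, cc$TP + cc$FP)
  # all background: empty evaluation domain
  cc0 <- confusion_counts(pred, ref, matrix(1L, 3, 3))
  expect_equal(cc0$N, 0)
  expect_error(confusion_counts(pred, ref, matrix(0L, 2, 2)), "mismatch")
})

test_that("confusion totals are invariant under pixel permutations", {
  set.seed(8)
  pred <- matrix(rbinom(100, 1, 0.4), 10)
  ref <- matrix(rbinom(100, 1, 0.3), 10)
  bg <- matrix(rbinom(100, 1, 0.2), 10)
  a <- confusion_counts(pred, ref, bg)
  p <- sample(100)
  b <- confusion_counts(matrix(pred[p], 10), matrix(ref[p], 10), matrix(bg[p], 10))
  expect_identical(unclass(a), unclass(b))
})

test_that("metric set reproduces hand-computed statistics", {
  perfect <- confusion_counts(matrix(c(1L, 1L, 0L, 0L), 2),
                              matrix(c(1L, 1L, 0L, 0L), 2),
                              matrix(0L, 2, 2))
  ms <- metric_set(perfect)
  expect_equal(unname(ms[c("DSC", "MCC", "BIN", "BMA")]), c(1, 1, 1, 1))
  tab <- structure(list(N = 100, RP = 10, RN = 90, PP = 10, PN = 90,
                        TP = 8, FN = 2, FP = 2, TN = 88),
                   class = "confusion_counts")
  expect_equal(unname(metric_set(tab)["DSC"]), 0.8)
  # swap prediction and reference: DSC unchanged
  swapped <- structure(list(N = 100, RP = 10, RN = 90, PP = 10, PN = 90,
                            TP = 8, FN = 2, FP = 2, TN = 88),
                       class = "confusion_counts")
  swapped$FN <- tab$FP; swapped$FP <- tab$FN
  expect_equal(metric_set(swapped)["DSC"], metric_set(tab)["DSC"])
  # undefined metrics are NA, not 0
  empty_pred <- structure(list(N = 10, RP = 0, RN = 10, PP = 0, PN = 10,
                               TP = 0, FN = 0, FP = 0, TN = 10),
                          class = "confusion_counts")
  expect_true(is.na(metric_set(empty_pred)["TPR"]))
  expect_true(is.na(metric_set(empty_pred)["DSC"]))
})

test_that("metric identities hold on random contingency tables", {
  set.seed(17)
  for (i in 1:300) {
    tab <- random_confusion_table()
    ms <- metric_set(tab)
    # DSC is the harmonic mean of TPR and PPV
    expect_equal(unname(ms["DSC"]),
                 2 / (1 / ms[["TPR"]] + 1 / ms[["PPV"]]), tolerance = 1e-12)
    # MCC is the signed geometric mean of informedness and markedness
    expect_equal(unname(ms["MCC"]),
                 sign(ms[["BIN"]]) * sqrt(ms[["BIN"]] * ms[["BMA"]]),
                 tolerance = 1e-9)
    expect_true(ms[["MCC"]] >= -1 && ms[["MCC"]] <= 1)
    expect_true(ms[["DSC"]] >= 0 && ms[["DSC"]] <= 1)
    expect_equal(ms[["TPR"]] + ms[["FNR"]], 1, tolerance = 1e-12)
    expect_equal(ms[["TNR"]] + ms[["FPR"]], 1, tolerance = 1e-12)
  }
})

test_that("cohort t intervals match the closed form", {
  expect_equal(unname(cohort_mean_ci(rep(0.9, 5))[1:3]), c(0.9, 0.9, 0.9))
  ci <- cohort_mean_ci(c(0.8, 0.9))
  half <- qt(0.975, df = 1) * sd(c(0.8, 0.9)) / sqrt(2)
  expect_equal(unname(ci["mean"]), 0.85)
  expect_equal(unname(ci["ci_low"]), 0.85 - half)
  expect_equal(unname(ci["ci_high"]), 0.85 + half)
  expect_equal(half, 0.6353, tolerance = 1e-4)
  expect_error(cohort_mean_ci(0.5), "at least two")
})

test_that("t intervals achieve nominal coverage", {
  set.seed(31)
  hits <- 0L
  n_rep <- 600L
  for (r in seq_len(n_rep)) {
    v <- rnorm(100, 0.85, 0.05)
    ci <- cohort_mean_ci(v)
    if (ci["ci_low"] <= 0.85 && 0.85 <= ci["ci_high"]) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.92)
  expect_lt(hits / n_rep, 0.98)
})

test_that("Spearman correlation matches first-principles computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 3, 2, 5, 4)
  r <- spearman_correlation(x, y)
  expect_equal(r$rho, 0.8)
  expect_equal(r$t_stat, 0.8 * sqrt(3 / 0.36), tolerance = 1e-9)
  expect_equal(r$p, 2 * pt(-0.8 * sqrt(3 / 0.36), df = 3), tolerance = 1e-12)
  expect_equal(r$ci_low, tanh(atanh(0.8) - qnorm(0.975) / sqrt(2)), tolerance = 1e-12)
  expect_equal(r$ci_high, tanh(atanh(0.8) + qnorm(0.975) / sqrt(2)), tolerance = 1e-12)
  # monotone transforms give rho = +-1
  expect_equal(spearman_correlation(1:6, exp(1:6))$rho, 1)
  expect_equal(spearman_correlation(1:6, -(1:6)^3)$rho, -1)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:3, 1:3), "at least 4")
})

test_that("Spearman agrees with the rank oracle on vectors with ties", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- x + sample(-3:3, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    r <- spearman_correlation(x, y)
    expect_equal(r$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(r$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_true(r$ci_low <= r$rho && r$rho <= r$ci_high)
  }
})
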