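test_that("ROC sweep handles separation, ties and the 4-point fixture", {
  y4 <- c("onfh", "onfh", "union", "union")
  expect_identical(roc_curve(c(0.3, 0.4, 1.0, 1.2), y4)$auc, 1)
  expect_identical(roc_curve(rep(0.7, 4), y4)$auc, 0.5)
  # pos {0.3, 0.9}, neg {0.6, 1.2}: 3 concordant, 1 discordant -> 0.75
  rc <- roc_curve(c(0.3, 0.9, 0.6, 1.2), y4)
  expect_identical(rc$auc, 0.75)
  expect_identical(rc$auc, brute_pair_auc(c(0.3, 0.9, 0.6, 1.2), y4))
  # curve contract: starts at (0,0), ends at (1,1), monotone sweep
  expect_identical(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_identical(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]), c(1, 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))

  expect_error(roc_curve(c(0.3, 0.4), c("onfh", "onfh")), "ROC undefined")
  expect_error(roc_curve(c(0.3, NA), c("onfh", "union")), "finite")
})

test_that("trapezoidal AUC equals pair-count AUC and brute enumeration", {
  set.seed(19)
  for (i in 1:100) {
    fx <- random_roc_fixture(n_max = 30L)
    trap <- roc_curve(fx$scores, fx$outcomes)$auc
    mw <- auc_mann_whitney(fx$scores, fx$outcomes)
    expect_equal(trap, mw, tolerance = 1e-12)
    expect_equal(mw, brute_pair_auc(fx$scores, fx$outcomes),
                 tolerance = 1e-12)
  }
})

test_that("AUC respects orientation duality and monotone transforms", {
  set.seed(23)
  for (i in 1:20) {
    fx <- random_roc_fixture(n_max = 25L)
    a_lo <- auc_mann_whitney(fx$scores, fx$outcomes, "lower_is_positive")
    expect_equal(a_lo,
                 auc_mann_whitney(-fx$scores, fx$outcomes,
                                  "higher_is_positive"), tolerance = 1e-12)
    expect_equal(a_lo,
                 1 - auc_mann_whitney(fx$scores, fx$outcomes,
                                      "higher_is_positive"), tolerance = 1e-12)
    # strictly increasing transform leaves the sweep unchanged
    expect_equal(roc_curve(exp(fx$scores), fx$outcomes)$auc, a_lo,
                 tolerance = 1e-12)
  }
})

test_that("Youden cutoff lands midway between separated groups", {
  # groups bounded away from each other around 0.5
  set.seed(101)
  y <- c(rep("onfh", 6), rep("union", 24))
  s <- c(runif(6, 0.2, 0.45), runif(24, 0.55, 2.5))
  yc <- youden_cutoff(roc_curve(s, y))
  expect_equal(yc$cutoff, (max(s[1:6]) + min(s[-(1:6)])) / 2,
               tolerance = 1e-12)
  expect_identical(yc$sensitivity, 1)
  expect_identical(yc$specificity, 1)
  expect_identical(yc$youden_j, 1)
  # uninformative scores: J = 0
  expect_identical(youden_cutoff(roc_curve(rep(1, 10),
                                           rep(c("onfh", "union"), 5)))$youden_j,
                   0)
})

test_that("Youden cutoff matches an exhaustive threshold scan", {
  set.seed(29)
  for (i in 1:20) {
    fx <- random_roc_fixture(n_max = 25L)
    yc <- youden_cutoff(roc_curve(fx$scores, fx$outcomes))
    # brute scan over candidate thresholds (all distinct scores + sentinel)
    cand <- c(-Inf, sort(unique(fx$scores)))
    pos <- fx$outcomes == "onfh"
    best_j <- -Inf
    for (t in cand) {
      called <- fx$scores <= t
      sens <- sum(called & pos) / sum(pos)
      spec <- sum(!called & !pos) / sum(!pos)
      best_j <- max(best_j, sens + spec - 1)
    }
    expect_equal(yc$youden_j, best_j, tolerance = 1e-12)
  }
})

test_that("DeLong self-comparison is exactly null", {
  set.seed(37)
  fx <- paired_marker_fixture(n = 20, n_pos = 8)
  res <- delong_test(fx$scores_a, fx$scores_a, fx$outcomes)
  expect_identical(res$z_statistic, 0)
  expect_identical(res$p_value, 1)
  expect_identical(res$auc_a, res$auc_b)
  # a strictly increasing transform of the same marker is also null
  res2 <- delong_test(fx$scores_a, 2 * fx$scores_a - 1, fx$outcomes)
  expect_identical(res2$p_value, 1)
})

test_that("DeLong agrees with the pROC reference implementation", {
  set.seed(41)
  for (i in 1:10) {
    fx <- paired_marker_fixture(n = 30)
    mine <- delong_test(fx$scores_a, fx$scores_b, fx$outcomes)
    ra <- pROC::roc(fx$outcomes, fx$scores_a, levels = c("union", "onfh"),
                    direction = ">", quiet = TRUE)
    rb <- pROC::roc(fx$outcomes, fx$scores_b, levels = c("union", "onfh"),
                    direction = ">", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(mine$auc_a, as.numeric(ra$auc), tolerance = 1e-12)
    expect_equal(mine$auc_b, as.numeric(rb$auc), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$variance_a, pROC::var(ra, method = "delong"),
                 tolerance = 1e-9)
  }
})

test_that("DeLong covariance obeys the Cauchy-Schwarz bound", {
  set.seed(43)
  for (i in 1:10) {
    fx <- paired_marker_fixture(n = 24)
    res <- delong_test(fx$scores_a, fx$scores_b, fx$outcomes)
    expect_gte(res$variance_a, 0)
    expect_gte(res$variance_b, 0)
    expect_lte(abs(res$covariance),
               sqrt(res$variance_a * res$variance_b) + 1e-12)
    expect_gte(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("unpaired DeLong compares independent cohorts", {
  set.seed(47)
  fa <- paired_marker_fixture(n = 30, n_pos = 10)
  fb <- paired_marker_fixture(n = 24, n_pos = 8)
  res <- delong_test(fa$scores_a, fb$scores_a, fa$outcomes,
                     outcomes_b = fb$outcomes, paired = FALSE)
  expect_identical(res$covariance, 0)
  expect_false(res$paired)
  expect_error(delong_test(fa$scores_a, fb$scores_a, fa$outcomes,
                           paired = TRUE), "equal-length")
})
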