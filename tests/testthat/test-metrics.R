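# Confusion metrics, ROC/AUC, paired t-test, Wilcoxon signed-rank.

test_that("confusion metrics match direct formula arithmetic", {
  m <- confusion_metrics(40, 15, 35, 10)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$precision, 40 / 55, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (40 / 55) * 0.8 / (40 / 55 + 0.8), tolerance = 1e-12)
  expect_equal(m$accuracy, 0.75)
  expect_length(m$undefined, 0)
})

test_that("confusion metric edge cases behave as defined", {
  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "f1")]) == 1))
  allneg <- confusion_metrics(0, 0, 20, 5)
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_true("precision" %in% allneg$undefined)
  expect_error(confusion_metrics(0, 0, 0, 0), class = "mieeg_validation_error")
})

test_that("accuracy decomposes exactly into class-weighted sens/spec", {
  withr::local_seed(1)
  for (i in 1:20) {
    cts <- sample(0:30, 4, replace = TRUE)
    if (sum(cts) == 0) next
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    P <- cts[1] + cts[4]; N <- cts[2] + cts[3]
    sens <- if (P == 0) 0 else cts[1] / P
    spec <- if (N == 0) 0 else cts[3] / N
    expect_equal(m$accuracy, (sens * P + spec * N) / (P + N))
  }
})

test_that("AUC endpoints and the hand case match pair counting", {
  expect_equal(roc_auc(c(5, 4, 3, 2), c(1, 1, 2, 2))$auc, 1)
  hand_scores <- c(0.9, 0.7, 0.7, 0.5, 0.4, 0.1)
  hand_labels <- c(1, 2, 1, 1, 2, 2)
  expect_equal(roc_auc(hand_scores, hand_labels)$auc,
               oracle_auc_pairs(hand_scores, hand_labels))
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "mieeg_validation_error")
})

test_that("label-independent scores give AUC near one half", {
  withr::local_seed(2)
  scores <- rnorm(1e4)
  labels <- sample(c(1, 2), 1e4, replace = TRUE)
  expect_equal(roc_auc(scores, labels)$auc, 0.5, tolerance = 0.02)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::local_seed(3)
  scores <- rnorm(200)
  labels <- rep(c(1, 2), 100)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(2 * scores - 7, labels)$auc, a0)
  expect_equal(roc_auc(atan(scores), labels)$auc, a0)
})

test_that("ROC points match pair counting on randomized tied fixtures", {
  withr::local_seed(4)
  for (i in 1:10) {
    scores <- sample(1:5, 30, replace = TRUE)   # heavy ties
    labels <- sample(c(1, 2), 30, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 oracle_auc_pairs(scores, labels))
  }
})

test_that("paired t-test matches the scalar formula and handles a == b", {
  a <- c(1.0, 2.5, 3.1); b <- c(0.4, 2.0, 3.4)
  res <- paired_ttest(a, b)
  d <- a - b
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-12)
  same <- paired_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_ttest(a, a - 1), class = "mieeg_degenerate_error")
  expect_error(paired_ttest(1:3, 1:4), class = "mieeg_validation_error")
})

test_that("signed-rank p matches exhaustive enumeration at n = 5", {
  withr::local_seed(5)
  for (i in 1:10) {
    d <- round(rnorm(5), 2)
    d[d == 0] <- 0.01
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$p, oracle_wilcoxon_exact(d), tolerance = 1e-12,
                 info = paste(d, collapse = ","))
  }
})

test_that("signed-rank statistic uses average ranks and min rank sum", {
  # |d| = 1, 2, 2, 3 -> ranks 1, 2.5, 2.5, 4; negatives at |2| and |3|
  d <- c(1, 2, -2, -3)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$w_pos, 1 + 2.5)
  expect_equal(res$w_neg, 2.5 + 4)
  expect_equal(res$statistic, 3.5)
})

test_that("signed-rank zero handling follows the exclusion rule", {
  res <- wilcoxon_signed_rank(c(0, 0, 0, 2))
  expect_equal(res$n_used, 1L)
  expect_equal(res$n_zero, 3L)
  expect_true(res$statistic %in% c(0, 1))
  expect_error(wilcoxon_signed_rank(rep(0, 4)),
               class = "mieeg_degenerate_error")
})

test_that("signed-rank normal approximation kicks in past n = 25", {
  withr::local_seed(6)
  d <- rnorm(30) + 0.5
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$method, "normal-approximation")
  ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})
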