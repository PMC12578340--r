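# Hybrid channel selection: t statistics, Bonferroni mask, correlation
# criterion, and channel-reduction arithmetic.

test_that("per-channel t statistics match the Welch formula oracle", {
  ep <- shifted_epochs(n_per_class = 3, n_channels = 4, seed = 5)
  cfg <- selection_config()
  ts <- channel_tstats(ep, cfg)
  feats <- log(band_power(ep, cfg$band) + .Machine$double.xmin)
  for (ch in 1:4) {
    o <- oracle_welch_t(feats[ep$labels == 1L, ch], feats[ep$labels == 2L, ch])
    expect_equal(ts$t[ch], o$t, tolerance = 1e-10)
    expect_equal(ts$p[ch], o$p, tolerance = 1e-10)
  }
})

test_that("identical class features give t = 0, p = 1", {
  base <- withr::with_seed(1, array(rnorm(3 * 2 * 100), c(3, 2, 100)))
  data <- array(0, c(6, 2, 100))
  data[1:3, , ] <- base
  data[4:6, , ] <- base                 # class 2 duplicates class 1 exactly
  ep <- eeg_epochs(data, c(1L, 1L, 1L, 2L, 2L, 2L), fs = 100)
  ts <- channel_tstats(ep)
  expect_equal(ts$t, rep(0, 2))
  expect_equal(ts$p, rep(1, 2))
})

test_that("single-class input is rejected", {
  ep <- eeg_epochs(array(rnorm(400), c(4, 1, 100)), rep(1L, 4), 100)
  expect_error(channel_tstats(ep), class = "mieeg_validation_error")
})

test_that("a planted amplitude shift makes that channel's p the minimum", {
  hits <- 0L
  for (seed in 1:100) {
    ep <- shifted_epochs(n_per_class = 50, n_channels = 5, scale2 = 1.3,
                         seed = seed)
    ts <- channel_tstats(ep)
    hits <- hits + (which.min(ts$p) == 1L)
  }
  expect_gte(hits, 95L)
})

test_that("Bonferroni mask arithmetic and degenerate cases", {
  bm <- bonferroni_mask(rep(0.5, 118), alpha = 0.10)
  expect_equal(bm$corrected_threshold, 0.10 / 118)
  expect_false(any(bm$mask))
  expect_error(bonferroni_mask(numeric(0), 0.1),
               class = "mieeg_validation_error")
  expect_false(any(bonferroni_mask(rep(1, 10), 0.1)$mask))
})

test_that("lowering alpha never enlarges the Bonferroni mask", {
  p <- withr::with_seed(3, runif(59)^3)
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  sizes <- vapply(alphas, function(a) sum(bonferroni_mask(p, a)$mask), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("channel correlation has unit diagonal and detects duplicates", {
  ep <- null_epochs(n_trials = 5, n_channels = 3, seed = 2)
  ep$data[, 3, ] <- ep$data[, 2, ]          # duplicate channel
  r <- channel_correlation(ep)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r[2, 3], 1)
  expect_equal(r, t(r))
})

test_that("shared-source channels reach the closed-form correlation", {
  # x1 = s + e1, x2 = s + e2 with var(s)/var(x) = 0.8 => cor(x1,x2) = 0.8
  n <- 30000
  withr::local_seed(7)
  s <- rnorm(n, sd = sqrt(0.8))
  x1 <- s + rnorm(n, sd = sqrt(0.2))
  x2 <- s + rnorm(n, sd = sqrt(0.2))
  data <- array(0, c(2, 2, n / 2))
  data[1, 1, ] <- x1[1:(n / 2)]; data[1, 2, ] <- x2[1:(n / 2)]
  data[2, 1, ] <- x1[(n / 2 + 1):n]; data[2, 2, ] <- x2[(n / 2 + 1):n]
  ep <- eeg_epochs(data, c(1L, 2L), 100)
  r <- channel_correlation(ep)
  expect_equal(r[1, 2], 0.8, tolerance = 0.05)
})

test_that("zero-variance channels get zeroed correlations with a warning", {
  ep <- null_epochs(n_trials = 3, n_channels = 3, seed = 4)
  ep$data[, 2, ] <- 7
  expect_warning(r <- channel_correlation(ep), "zero-variance")
  expect_equal(r[2, 1], 0)
  expect_equal(r[2, 2], 1)
})

test_that("selection retains exactly the planted correlated channels", {
  sim <- simulate_epochs(sim_config(n_channels = 20, informative = 1:4,
                                    n_trials_per_class = 100,
                                    erd_depth = 0.8, seed = 42))
  sel <- select_channels(sim$epochs)
  expect_identical(sel$selected, 1:4)
  expect_equal(sel$rc, 4L)
  expect_equal(sel$oc, 20L)
  expect_equal(sel$retention_ratio, 0.20)
  expect_equal(sel$reduction_rate, 0.80)
  expect_false(sel$empty)
})

test_that("selection is empty and flagged when nothing is significant", {
  ep <- null_epochs(n_trials = 10, n_channels = 6, seed = 11)
  sel <- suppressMessages(select_channels(ep))
  expect_length(sel$selected, 0L)
  expect_true(sel$empty)
  expect_equal(sel$rc, 0L)
})

test_that("shuffling class labels destroys the selection", {
  sim <- simulate_epochs(sim_config(n_channels = 10, informative = 1:3,
                                    n_trials_per_class = 40,
                                    erd_depth = 0.8, seed = 13))
  retained <- integer(20)
  for (i in 1:20) {
    ep <- sim$epochs
    ep$labels <- withr::with_seed(i, sample(ep$labels))
    retained[i] <- suppressMessages(select_channels(ep))$rc
  }
  # expected retained count under the null is far below one channel
  expect_lte(mean(retained), 0.5)
})

test_that("selection is deterministic for identical inputs", {
  sim <- simulate_epochs(sim_config(n_trials_per_class = 20, seed = 31))
  s1 <- select_channels(sim$epochs)
  s2 <- select_channels(sim$epochs)
  expect_identical(s1, s2)
})

test_that("redundancy pruning drops the larger-p member of a redundant pair", {
  sim <- simulate_epochs(sim_config(n_channels = 8, informative = 1:3,
                                    n_trials_per_class = 60,
                                    erd_depth = 0.8, seed = 17))
  ep <- sim$epochs
  ep$data[, 3, ] <- ep$data[, 2, ] + 1e-3 * rnorm(length(ep$data[, 2, ]))
  cfg <- selection_config(prune_redundant = TRUE, r_redundant = 0.99)
  sel <- select_channels(ep, cfg)
  expect_false(all(c(2L, 3L) %in% sel$selected))
  expect_true(any(c(2L, 3L) %in% sel$selected))
})

test_that("channel-reduction statistics follow truncation, not rounding", {
  # 93/118 = 0.78813... truncates to 0.78
  expect_equal(crr(118, 93)$retention_ratio, 0.78)
  expect_equal(crr(10, 10)$retention_ratio, 1.00)
  expect_equal(crr(10, 10)$reduction_rate, 0)
  expect_equal(crr(118, 49)$reduction_rate, 1 - 49 / 118)
  expect_error(crr(10, 11), class = "mieeg_validation_error")
})
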