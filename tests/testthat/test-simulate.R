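# Synthetic ERD generator: determinism, spectral content, ground truth.

test_that("the generator is fully determined by its seed", {
  cfg <- sim_config(n_channels = 6, informative = 1:2,
                    n_trials_per_class = 5, seed = 77)
  s1 <- simulate_epochs(cfg)
  s2 <- simulate_epochs(cfg)
  expect_identical(s1$epochs$data, s2$epochs$data)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$signal, r2$signal)
})

test_that("simulated recordings carry one marker per trial, interleaved", {
  cfg <- sim_config(n_channels = 4, informative = 1:2,
                    n_trials_per_class = 7, seed = 5)
  rec <- simulate_recording(cfg)
  expect_equal(nrow(rec$markers), 14L)
  expect_identical(rec$markers$label, rep(c(1L, 2L), 7))
})

test_that("epoching a simulated recording reproduces the epoch statistics", {
  cfg <- sim_config(n_channels = 8, informative = 1:3,
                    n_trials_per_class = 30, seed = 9)
  direct <- simulate_epochs(cfg)
  cut <- epoch_recording(simulate_recording(cfg), cfg$epoch_s)
  expect_equal(dim(cut$data), dim(direct$epochs$data))
  bp_direct <- band_power(direct$epochs, cfg$mu_band)
  bp_cut <- band_power(cut, cfg$mu_band)
  for (cls in 1:2) {
    m_direct <- mean(bp_direct[direct$epochs$labels == cls, cfg$informative])
    m_cut <- mean(bp_cut[cut$labels == cls, cfg$informative])
    expect_equal(m_cut, m_direct, tolerance = 0.05 * m_direct)
  }
})

test_that("noise-only channels show the configured 1/f spectral slope", {
  cfg <- sim_config(n_channels = 2, informative = integer(0),
                    n_trials_per_class = 1, pink_exponent = 1,
                    white_sd = 0, seed = 3)
  rec <- simulate_recording(cfg)
  x <- rec$signal[1, ]
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[2:(n %/% 2)]^2 / n
  f <- (2:(n %/% 2) - 1) * cfg$fs / n
  keep <- f >= 1 & f <= 30
  slope <- coef(lm(log(sp[keep]) ~ log(f[keep])))[2]
  expect_equal(as.numeric(slope), -1, tolerance = 0.2)
})

test_that("ground truth reports the informative set and the ERD power ratio", {
  sim <- simulate_epochs(sim_config(n_channels = 10, informative = 3:5,
                                    n_trials_per_class = 40,
                                    erd_depth = 0.8, seed = 15))
  gt <- sim$ground_truth
  expect_identical(gt$informative, 3:5)
  expect_gt(gt$band_power_ratio, 1.5)   # class 2 carries the full mu power
  expect_equal(gt$band_power_class2 / gt$band_power_class1,
               gt$band_power_ratio)
})

test_that("deeper ERD yields larger informative-channel |t| statistics", {
  med_t <- vapply(c(0.2, 0.5, 0.8), function(depth) {
    vals <- vapply(1:5, function(seed) {
      sim <- simulate_epochs(sim_config(n_channels = 8, informative = 1:2,
                                        n_trials_per_class = 30,
                                        erd_depth = depth, seed = seed))
      ts <- channel_tstats(sim$epochs)
      median(abs(ts$t[1:2]))
    }, 1)
    median(vals)
  }, 1)
  expect_true(all(diff(med_t) > 0))
})

test_that("separable features have the closed-form Bayes accuracy", {
  sep <- make_separable_features(500, 5, margin = 6, seed = 21)
  expect_equal(sep$bayes_accuracy, pnorm(3))
  expect_identical(sep$X, make_separable_features(500, 5, 6, seed = 21)$X)
  # projected class means sit margin apart along the planted direction
  proj <- sep$X %*% sep$direction
  gap <- mean(proj[sep$y == 2]) - mean(proj[sep$y == 1])
  expect_equal(gap, 6, tolerance = 0.3)
  flat <- make_separable_features(60, 3, margin = 0, seed = 2)
  expect_equal(flat$bayes_accuracy, 0.5)
})

test_that("generator configuration is validated", {
  expect_error(sim_config(n_channels = 4, informative = 1:6),
               class = "mieeg_validation_error")
  expect_error(sim_config(erd_depth = 1.2), class = "mieeg_validation_error")
  expect_error(sim_config(mu_band = c(8, 60)),
               class = "mieeg_validation_error")
})
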