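# Resampling, Butterworth band-pass, epoching and band power.

test_that("resampling at the current rate is the identity", {
  rec <- eeg_recording(matrix(rnorm(200), 2), fs = 100)
  expect_identical(resample_recording(rec, 100), rec)
})

test_that("downsampling produces the arithmetic sample count", {
  rec <- eeg_recording(matrix(rnorm(1000), 1), fs = 250)
  out <- resample_recording(rec, 100)
  expect_equal(ncol(out$signal), 400L)
  expect_equal(out$fs, 100)
})

test_that("downsampling preserves an in-band spectral peak", {
  fs <- 250; n <- 2500
  rec <- make_sine_recording(10, fs, n)
  out <- resample_recording(rec, 100)
  x <- out$signal[1, ]
  # FFT oracle: locate the peak and measure its amplitude
  sp <- Mod(fft(x))[1:(length(x) / 2)]
  peak_bin <- which.max(sp)
  freq <- (peak_bin - 1) * 100 / length(x)
  expect_equal(freq, 10, tolerance = 0.01)
  interior <- x[100:(length(x) - 100)]      # away from filter edge effects
  expect_equal(sqrt(mean(interior^2)) * sqrt(2), 1, tolerance = 0.02)
})

test_that("marker indices rescale with half-up rounding", {
  rec <- eeg_recording(matrix(rnorm(1000), 1), fs = 250,
                       markers = data.frame(sample = c(1L, 251L, 500L),
                                            label = c(1L, 2L, 1L)))
  out <- resample_recording(rec, 100)
  expect_equal(out$markers$sample, c(1L, 101L, 201L))
})

test_that("pass-band sinusoid goes through the band-pass nearly unchanged", {
  fs <- 100; n <- 3000
  rec <- make_sine_recording(10, fs, n)
  out <- bandpass_recording(rec, filter_spec(0.5, 30, 5))
  mid <- out$signal[1, 500:2500]
  ref <- rec$signal[1, 500:2500]
  expect_equal(max(abs(mid)), max(abs(ref)), tolerance = 0.01)
})

test_that("stop-band attenuation matches the Butterworth magnitude oracle", {
  fs <- 500; n <- 5000
  rec <- make_sine_recording(60, fs, n)
  out <- bandpass_recording(rec, filter_spec(0.5, 30, 5))
  # closed-form single-pass attenuation 10*log10(1+(60/30)^10) ~ 30.1 dB,
  # doubled by the forward-backward pass => >= 60 dB
  amp <- sqrt(mean(out$signal[1, 1000:4000]^2)) * sqrt(2)
  expect_lt(20 * log10(amp / 1), -60)
})

test_that("DC input is suppressed by the band-pass", {
  rec <- eeg_recording(matrix(5, 1, 6000), fs = 100)
  out <- bandpass_recording(rec, filter_spec())
  # steady state (away from the 0.5 Hz edge transient): < 1e-3 of the level
  expect_lt(mean(abs(out$signal[1, 2000:4000])) / 5, 1e-3)
})

test_that("filtering is linear and zero-phase", {
  fs <- 100
  rec <- eeg_recording(matrix(rnorm(2000), 1), fs = fs)
  spec <- filter_spec()
  f1 <- bandpass_recording(rec, spec)$signal
  rec10 <- rec; rec10$signal <- 10 * rec10$signal
  f10 <- bandpass_recording(rec10, spec)$signal
  expect_equal(f10, 10 * f1, tolerance = 1e-8)

  sine <- make_sine_recording(10, fs, 2000)
  filt <- bandpass_recording(sine, spec)$signal[1, ]
  cc <- ccf(filt[200:1800], sine$signal[1, 200:1800], lag.max = 10,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band-pass rejects an edge at or above Nyquist", {
  rec <- eeg_recording(matrix(rnorm(500), 1), fs = 50)
  expect_error(bandpass_recording(rec, filter_spec(0.5, 30)),
               class = "mieeg_validation_error")
})

test_that("3-s windows at 100 Hz give 301-sample epochs with ordered labels", {
  n <- 40
  starts <- seq(100L, by = 400L, length.out = n)
  labels <- rep(c(1L, 2L), n / 2)
  rec <- eeg_recording(matrix(rnorm(2 * (max(starts) + 400)), 2), fs = 100,
                       markers = data.frame(sample = starts, label = labels))
  ep <- epoch_recording(rec, window_s = 3)
  expect_equal(dim(ep$data), c(n, 2L, 301L))
  expect_identical(ep$labels, labels)
  # first epoch is exactly the samples from the marker, inclusive ends
  expect_equal(ep$data[1, 1, ], rec$signal[1, 100:400])
})

test_that("epochs overrunning the recording are dropped with a message", {
  rec <- eeg_recording(matrix(rnorm(500), 1), fs = 100,
                       markers = data.frame(sample = c(50L, 490L),
                                            label = c(1L, 2L)))
  expect_message(ep <- epoch_recording(rec, 3), "dropped 1")
  expect_equal(n_trials(ep), 1L)
  rec_all_late <- eeg_recording(matrix(rnorm(100), 1), fs = 100,
                                markers = data.frame(sample = 90L, label = 1L))
  expect_error(suppressMessages(epoch_recording(rec_all_late, 3)),
               class = "mieeg_empty_result_error")
})

test_that("adjacent epochs never duplicate samples when markers are spaced", {
  rec <- eeg_recording(matrix(seq_len(2000), 1), fs = 100,
                       markers = data.frame(sample = c(1L, 302L, 603L),
                                            label = c(1L, 2L, 1L)))
  ep <- epoch_recording(rec, 3)
  flat <- as.vector(t(ep$data[, 1, ]))
  expect_false(any(duplicated(flat)))
})

test_that("band power matches the analytic sinusoid mean square", {
  fs <- 100; m <- 300
  tt <- (seq_len(m) - 1) / fs
  data <- array(0, c(2, 1, m))
  data[1, 1, ] <- sin(2 * pi * 10 * tt)
  data[2, 1, ] <- sin(2 * pi * 10 * tt + 1)
  ep <- eeg_epochs(data, c(1L, 2L), fs)
  bp_mu <- band_power(ep, c(8, 12))
  expect_equal(as.numeric(bp_mu), c(0.5, 0.5), tolerance = 0.05)
  bp_beta <- band_power(ep, c(20, 30))
  expect_lt(max(bp_beta) / 0.5, 0.01)
  # zero signal has zero band power
  ep0 <- eeg_epochs(array(0, c(1, 1, m)), 1L, fs)
  expect_equal(as.numeric(band_power(ep0, c(8, 12))), 0)
})

test_that("band power rejects degenerate bands", {
  ep <- eeg_epochs(array(rnorm(100), c(1, 1, 100)), 1L, 100)
  expect_error(band_power(ep, c(12, 8)), class = "mieeg_validation_error")
  expect_error(band_power(ep, c(10, 60)), class = "mieeg_validation_error")
})
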