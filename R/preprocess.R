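# Sampling-rate standardization, Butterworth band-pass filtering,
# marker-aligned epoching, and band-power summaries.

#' Band-pass filter specification
#'
#' Defaults follow the common motor-imagery preprocessing choice: a 5th-order
#' Butterworth band-pass from 0.5 to 30 Hz, applied forward-backward
#' (zero-phase) because the analysis is offline; zero-phase application
#' squares the magnitude response, doubling the stop-band attenuation in dB.
#'
#' @param low_hz lower pass-band edge in Hz.
#' @param high_hz upper pass-band edge in Hz (must stay below Nyquist of the
#'   signal it is applied to).
#' @param order filter order (>= 1).
#' @param zero_phase apply forward-backward (`TRUE`, default) or causal
#'   single-pass (`FALSE`).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 30, order = 5,
                        zero_phase = TRUE) {
  assert_scalar_number(low_hz, "low_hz", positive = TRUE)
  assert_scalar_number(high_hz, "high_hz", positive = TRUE)
  if (low_hz >= high_hz)
    validation_error("low_hz must be below high_hz")
  assert_scalar_number(order, "order")
  if (order < 1) validation_error("order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Resample a recording to a target rate
#'
#' Polyphase FIR anti-aliased resampling (via [signal::resample()]) of every
#' channel. The output length is `round(n * target_fs / fs)` and marker
#' indices are rescaled by `target_fs / fs` with half-up rounding.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate in Hz (default 100).
#' @return A resampled [eeg_recording()]. If `target_fs` equals the current
#'   rate the input is returned unchanged.
#' @export
resample_recording <- function(rec, target_fs = 100) {
  if (!inherits(rec, "eeg_recording"))
    validation_error("rec must be an eeg_recording")
  assert_scalar_number(target_fs, "target_fs", positive = TRUE)
  if (abs(target_fs - rec$fs) < 1e-12) return(rec)
  frac <- ratio_integers(target_fs, rec$fs)
  p <- frac[1L]; q <- frac[2L]
  n_out <- round_half_up(ncol(rec$signal) * target_fs / rec$fs)
  # polyphase FIR chain: upsample by p, anti-alias/anti-image low-pass at
  # min(1/p, 1/q) of the upsampled Nyquist, downsample by q
  h <- p * signal::fir1(20L * max(p, q), 1 / max(p, q), "low")
  delay <- (length(h) - 1L) / 2
  sig <- t(apply(rec$signal, 1L, function(x) {
    up <- numeric(length(x) * p)
    up[seq(1L, by = p, length.out = length(x))] <- x
    yf <- signal::fftfilt(h, c(up, numeric(length(h))))
    yf <- yf[seq.int(delay + 1L, delay + length(up))]
    y <- yf[seq.int(1L, length(yf), by = q)]
    length(y) <- n_out              # pad/trim to the arithmetic length
    y[is.na(y)] <- 0
    y
  }))
  markers <- rec$markers
  if (nrow(markers)) {
    # rescale the 0-based offset, then back to 1-based; round half-up
    markers$sample <- pmin(pmax(
      round_half_up((markers$sample - 1) * target_fs / rec$fs) + 1L, 1L), n_out)
  }
  eeg_recording(sig, fs = target_fs, channel_names = rec$channel_names,
                markers = markers, subject_id = rec$subject_id)
}

# Smallest integer p/q with p/q == a/b (rationalized to 1e-6 resolution).
ratio_integers <- function(a, b) {
  p <- round(a * 1e6); q <- round(b * 1e6)
  g <- function(x, y) if (y == 0) x else Recall(y, x %% y)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Band-pass filter a recording
#'
#' Applies the Butterworth band-pass per channel on the continuous signal
#' (before epoching, to keep filter transients out of the trials).
#'
#' @param rec an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @return The filtered [eeg_recording()]; shape unchanged.
#' @export
bandpass_recording <- function(rec, spec = filter_spec()) {
  if (!inherits(rec, "eeg_recording"))
    validation_error("rec must be an eeg_recording")
  if (!inherits(spec, "filter_spec")) validation_error("spec must be a filter_spec")
  nyq <- rec$fs / 2
  if (spec$high_hz >= nyq)
    validation_error("high_hz (", spec$high_hz, ") must be below Nyquist (",
                     nyq, ")")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  apply_fn <- if (spec$zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  sig <- t(apply(rec$signal, 1L, apply_fn))
  eeg_recording(sig, fs = rec$fs, channel_names = rec$channel_names,
                markers = rec$markers, subject_id = rec$subject_id)
}

#' Cut marker-aligned epochs from a recording
#'
#' Each epoch spans `[marker + offset, marker + offset + window_s]` with both
#' endpoints included, i.e. `round(window_s * fs) + 1` samples — 301 samples
#' for a 3-s window at 100 Hz. Epochs that would overrun the recording are
#' dropped with a message.
#'
#' @param rec an [eeg_recording()] with at least one marker.
#' @param window_s epoch length in seconds (default 3).
#' @param offset_s start of the window relative to the marker, in seconds
#'   (default 0).
#' @return An [eeg_epochs()] with labels in marker order.
#' @export
epoch_recording <- function(rec, window_s = 3, offset_s = 0) {
  if (!inherits(rec, "eeg_recording"))
    validation_error("rec must be an eeg_recording")
  if (nrow(rec$markers) == 0L)
    validation_error("recording has no markers to epoch around")
  assert_scalar_number(window_s, "window_s", positive = TRUE)
  wlen <- round_half_up(window_s * rec$fs) + 1L
  starts <- rec$markers$sample + round_half_up(offset_s * rec$fs)
  ok <- starts >= 1L & (starts + wlen - 1L) <= ncol(rec$signal)
  if (any(!ok))
    message("dropped ", sum(!ok), " epoch(s) overrunning the recording")
  if (!any(ok))
    stop_mieeg("no usable epochs: every window overruns the recording",
               class = "mieeg_empty_result_error")
  starts <- starts[ok]
  labels <- rec$markers$label[ok]
  nc <- nrow(rec$signal)
  data <- array(0, dim = c(length(starts), nc, wlen))
  for (i in seq_along(starts))
    data[i, , ] <- rec$signal[, seq.int(starts[i], length.out = wlen)]
  eeg_epochs(data, labels, rec$fs, rec$channel_names)
}

# Squared magnitude response of the digital Butterworth band-pass at
# normalized frequencies w (radians/sample), raised to the number of passes.
butter_power_response <- function(w, low_hz, high_hz, order, fs,
                                  passes = 2L) {
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  z <- exp(-1i * w)
  h <- vapply(z, function(zz) {
    sum(bf$b * zz^(seq_along(bf$b) - 1)) / sum(bf$a * zz^(seq_along(bf$a) - 1))
  }, complex(1))
  Mod(h)^(2L * passes)
}

#' Per-trial, per-channel band power
#'
#' Mean squared amplitude of each epoch after zero-phase Butterworth
#' band-pass restriction to `band`. Computed spectrally: the per-epoch
#' periodogram is weighted by the squared zero-phase magnitude response of
#' the band-pass (the filter's power transfer), which is the Parseval form of
#' filtering and vectorizes across all trials and channels.
#'
#' @param x an [eeg_epochs()] object.
#' @param band numeric length-2 vector `(low, high)` in Hz, within Nyquist.
#' @param order Butterworth order used for the band restriction (default 5).
#' @return trials x channels matrix of band power (microvolts squared);
#'   strictly positive for non-zero signals, 0 for all-zero epochs.
#' @examples
#' ep <- simulate_epochs(sim_config(n_channels = 4, informative = 1:2,
#'                                  n_trials_per_class = 5, seed = 1))$epochs
#' bp <- band_power(ep, c(8, 12))
#' dim(bp)
#' @export
band_power <- function(x, band, order = 5) {
  if (!inherits(x, "eeg_epochs"))
    validation_error("x must be an eeg_epochs object")
  if (length(band) != 2L || !is.numeric(band) || band[1L] >= band[2L])
    validation_error("band must be (low, high) with low < high")
  if (band[1L] <= 0 || band[2L] >= x$fs / 2)
    validation_error("band must lie strictly inside (0, Nyquist)")
  d <- dim(x$data)
  n_tr <- d[1L]; n_ch <- d[2L]; m <- d[3L]
  # samples x (trial*channel) matrix, per-series mean removed
  flat <- matrix(aperm(x$data, c(3L, 1L, 2L)), nrow = m)
  flat <- sweep(flat, 2L, colMeans(flat))
  spec <- Mod(mvfft(flat))^2
  w <- 2 * pi * (seq_len(m) - 1L) / m
  wt <- butter_power_response(w, band[1L], band[2L], order, x$fs, passes = 2L)
  power <- colSums(spec * wt) / m^2
  matrix(power, nrow = n_tr, ncol = n_ch)
}
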