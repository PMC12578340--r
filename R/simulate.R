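# Synthetic two-class motor-imagery EEG with ground-truth discriminative
# channels. Event-related desynchronization (ERD) is modeled as a
# multiplicative attenuation of a shared mu-band oscillation on the
# informative channels in class 1; the background is 1/f (pink) plus white
# noise, partially shared across informative channels to give them the
# inter-channel correlation the selection criterion looks for.

#' Simulation configuration
#'
#' Defaults describe a desk-scale motor-imagery session: 20 channels of which
#' 4 carry the class effect, 100 trials per class, 3-s epochs at 100 Hz, and
#' microvolt-scale amplitudes (signals stay within roughly +/-50 uV).
#'
#' @param n_channels total channel count.
#' @param informative indices of the channels carrying the class effect.
#' @param n_trials_per_class trials per class (>= 1).
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch length in seconds; epochs have
#'   `round(epoch_s * fs) + 1` samples.
#' @param mu_band frequency band of the oscillation, Hz.
#' @param erd_depth fractional mu-power attenuation in class 1 on the
#'   informative channels, in `[0, 1]`; the class-1 oscillation amplitude is
#'   scaled by `sqrt(1 - erd_depth)`.
#' @param pink_exponent spectral exponent of the 1/f^exponent background.
#' @param pink_sd,white_sd background noise scales (uV).
#' @param mu_amplitude oscillation amplitude (uV) in the unattenuated class.
#' @param mixing_corr fraction of background variance shared among the
#'   informative channels; approximately their inter-channel correlation.
#' @param seed integer seed; the simulation is fully determined by it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_channels = 20, informative = 1:4,
                       n_trials_per_class = 100, fs = 100, epoch_s = 3,
                       mu_band = c(8, 12), erd_depth = 0.8,
                       pink_exponent = 1, pink_sd = 10, white_sd = 2,
                       mu_amplitude = 8, mixing_corr = 0.7, seed = 1) {
  informative <- as.integer(informative)
  if (length(informative) &&
      (any(informative < 1L) || any(informative > n_channels)))
    validation_error("informative indices must lie in [1, n_channels]")
  if (erd_depth < 0 || erd_depth > 1)
    validation_error("erd_depth must be in [0, 1]")
  if (n_trials_per_class < 1) validation_error("need >= 1 trial per class")
  if (mu_band[1L] <= 0 || mu_band[2L] >= fs / 2 || mu_band[1L] >= mu_band[2L])
    validation_error("mu_band must lie strictly inside (0, Nyquist)")
  if (mixing_corr < 0 || mixing_corr > 1)
    validation_error("mixing_corr must be in [0, 1]")
  structure(list(n_channels = as.integer(n_channels),
                 informative = informative,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 fs = fs, epoch_s = epoch_s, mu_band = as.numeric(mu_band),
                 erd_depth = erd_depth, pink_exponent = pink_exponent,
                 pink_sd = pink_sd, white_sd = white_sd,
                 mu_amplitude = mu_amplitude, mixing_corr = mixing_corr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Unit-variance pink noise via spectral shaping of white noise.
pink_noise <- function(n, exponent) {
  if (exponent == 0) return(rnorm(n))
  half <- floor(n / 2)
  f <- seq_len(half)
  amp <- f^(-exponent / 2)
  phases <- runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(half + 1)] <- spec
  if (n %% 2 == 0) {
    full[half + 1] <- complex(real = amp[half] * sign(rnorm(1)))
    if (half > 1) full[seq.int(n, half + 2)] <- Conj(spec[seq_len(half - 1)])
  } else {
    full[seq.int(n, half + 2)] <- Conj(spec)
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  as.numeric(x / sd(x))
}

sim_background <- function(m, cfg) {
  cfg$pink_sd * pink_noise(m, cfg$pink_exponent) + cfg$white_sd * rnorm(m)
}

# One trial: channels x samples matrix plus its label.
sim_trial <- function(cfg, label, m) {
  sig <- matrix(0, cfg$n_channels, m)
  shared <- sim_background(m, cfg)
  tt <- (seq_len(m) - 1L) / cfg$fs
  f_mu <- runif(1, cfg$mu_band[1L], cfg$mu_band[2L])
  phase <- runif(1, 0, 2 * pi)
  amp <- cfg$mu_amplitude * if (label == 1L) sqrt(1 - cfg$erd_depth) else 1
  osc <- amp * sin(2 * pi * f_mu * tt + phase)
  rho <- cfg$mixing_corr
  for (ch in seq_len(cfg$n_channels)) {
    own <- sim_background(m, cfg)
    if (ch %in% cfg$informative) {
      sig[ch, ] <- sqrt(rho) * shared + sqrt(1 - rho) * own + osc
    } else {
      sig[ch, ] <- own
    }
  }
  sig
}

#' Simulate epoched two-class motor-imagery EEG
#'
#' Class labels are interleaved (1, 2, 1, 2, ...). Class 2 carries the full
#' mu oscillation on the informative channels; class 1 is attenuated by
#' `sqrt(1 - erd_depth)` — the ERD signature the channel-selection statistic
#' targets. The generator is fully determined by `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `epochs` (an [eeg_epochs()]) and `ground_truth`
#'   (informative indices, configured depth, and the realized per-class mean
#'   mu-band power and their ratio on the informative channels).
#' @export
simulate_epochs <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) validation_error("cfg must be a sim_config")
  m <- round_half_up(cfg$epoch_s * cfg$fs) + 1L
  n_tr <- 2L * cfg$n_trials_per_class
  labels <- rep(c(1L, 2L), cfg$n_trials_per_class)
  data <- with_seed(cfg$seed, {
    arr <- array(0, dim = c(n_tr, cfg$n_channels, m))
    for (i in seq_len(n_tr)) arr[i, , ] <- sim_trial(cfg, labels[i], m)
    arr
  })
  ep <- eeg_epochs(data, labels, cfg$fs)
  gt <- list(informative = cfg$informative, erd_depth = cfg$erd_depth)
  if (length(cfg$informative)) {
    bp <- band_power(ep, cfg$mu_band)
    inf_bp <- bp[, cfg$informative, drop = FALSE]
    gt$band_power_class1 <- mean(inf_bp[labels == 1L, ])
    gt$band_power_class2 <- mean(inf_bp[labels == 2L, ])
    gt$band_power_ratio <- gt$band_power_class2 / gt$band_power_class1
  }
  list(epochs = ep, ground_truth = gt)
}

#' Simulate a continuous recording with markers
#'
#' Trial segments (generated as in [simulate_epochs()]) are embedded in a
#' continuous record separated by 1 s of plain background noise, with one
#' marker at each trial onset and interleaved class labels — suitable for
#' exercising the epoching and the file writers.
#'
#' @param cfg a [sim_config()].
#' @return An [eeg_recording()] with `2 * n_trials_per_class` markers.
#' @export
simulate_recording <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) validation_error("cfg must be a sim_config")
  m <- round_half_up(cfg$epoch_s * cfg$fs) + 1L
  gap <- as.integer(round(cfg$fs))
  n_tr <- 2L * cfg$n_trials_per_class
  labels <- rep(c(1L, 2L), cfg$n_trials_per_class)
  total <- gap + n_tr * (m + gap)
  with_seed(cfg$seed, {
    sig <- matrix(0, cfg$n_channels, total)
    for (ch in seq_len(cfg$n_channels))
      sig[ch, ] <- sim_background(total, cfg)
    starts <- gap + 1L + (seq_len(n_tr) - 1L) * (m + gap)
    for (i in seq_len(n_tr)) {
      idx <- seq.int(starts[i], length.out = m)
      sig[, idx] <- sim_trial(cfg, labels[i], m)
    }
    eeg_recording(sig, fs = cfg$fs,
                  markers = data.frame(sample = starts, label = labels),
                  subject_id = "simulated")
  })
}

#' Linearly separable Gaussian feature clusters
#'
#' Two isotropic unit-variance Gaussian clusters displaced by `margin` along
#' a random direction, giving a closed-form Bayes accuracy of
#' `pnorm(margin / 2)`.
#'
#' @param n total sample count (split as evenly as possible).
#' @param d feature dimension.
#' @param margin distance between the class means in SD units (> 0 for
#'   separable classes; 0 gives indistinguishable classes).
#' @param seed integer seed.
#' @return List with `X` (n x d), `y` (labels in `{1, 2}`), `bayes_accuracy`,
#'   and the displacement `direction`.
#' @export
make_separable_features <- function(n, d, margin, seed = 1) {
  if (margin < 0) validation_error("margin must be >= 0")
  with_seed(seed, {
    u <- rnorm(d)
    u <- u / sqrt(sum(u^2))
    y <- rep(c(1L, 2L), length.out = n)
    X <- matrix(rnorm(n * d), n, d)
    shift <- ifelse(y == 1L, -margin / 2, margin / 2)
    X <- X + outer(shift, u)
    list(X = X, y = y, bayes_accuracy = pnorm(margin / 2), direction = u)
  })
}
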