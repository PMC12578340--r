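# Independent scalar-formula oracles and small fixture builders used across
# the suite. Each oracle is written directly from the defining formula, never
# by calling the implementation it checks.

# Welch two-sample t statistic and two-sided p, scalar arithmetic only.
oracle_welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df))
}

# Ledoit-Wolf intensity, literal per-observation loops over the formula for
# shrinkage toward nu*I with nu = trace(S)/n.
oracle_lw_gamma <- function(obs) {
  n <- nrow(obs); T_ <- ncol(obs)
  S <- matrix(0, n, n)
  for (t in seq_len(T_)) S <- S + obs[, t] %*% t(obs[, t])
  S <- S / T_
  nu <- sum(diag(S)) / n
  d2 <- sum((S - nu * diag(n))^2) / n
  b2bar <- 0
  for (t in seq_len(T_))
    b2bar <- b2bar + sum((obs[, t] %*% t(obs[, t]) - S)^2)
  b2bar <- b2bar / (T_^2 * n)
  min(b2bar, d2) / d2
}

# AUC by exhaustive positive/negative pair counting with half credit on ties.
oracle_auc_pairs <- function(scores, labels, positive = 1) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  sums <- as.matrix(signs) %*% r
  p_le <- mean(sums <= w_obs)
  p_ge <- mean(sums >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# White-noise epochs with no class structure (null fixture).
null_epochs <- function(n_trials = 10, n_channels = 5, m = 120, fs = 100,
                        seed = 1) {
  withr::with_seed(seed, {
    data <- array(rnorm(2 * n_trials * n_channels * m),
                  dim = c(2 * n_trials, n_channels, m))
    eeg_epochs(data, rep(c(1L, 2L), n_trials), fs)
  })
}

# Epochs whose first channel has its class-2 amplitude scaled, planting a
# known log-band-power shift on that channel only.
shifted_epochs <- function(n_per_class = 50, n_channels = 5, m = 150,
                           scale2 = 1.5, fs = 100, seed = 1) {
  withr::with_seed(seed, {
    n_tr <- 2L * n_per_class
    labels <- rep(c(1L, 2L), n_per_class)
    data <- array(rnorm(n_tr * n_channels * m), c(n_tr, n_channels, m))
    for (i in which(labels == 2L)) data[i, 1L, ] <- scale2 * data[i, 1L, ]
    eeg_epochs(data, labels, fs)
  })
}

# Two-class epochs drawn from known diagonal covariances (CSP toy problem).
diag_cov_epochs <- function(n_per_class = 100, m = 60, d1 = c(2, 1),
                            d2 = c(1, 2), seed = 1) {
  withr::with_seed(seed, {
    n_tr <- 2L * n_per_class
    labels <- rep(c(1L, 2L), n_per_class)
    data <- array(0, c(n_tr, length(d1), m))
    for (i in seq_len(n_tr)) {
      sds <- sqrt(if (labels[i] == 1L) d1 else d2)
      data[i, , ] <- sds * matrix(rnorm(length(d1) * m), length(d1), m)
    }
    eeg_epochs(data, labels, fs = 100)
  })
}

make_sine_recording <- function(freq, fs, n, channels = 1, amp = 1,
                                markers = NULL) {
  tt <- (seq_len(n) - 1) / fs
  sig <- matrix(rep(amp * sin(2 * pi * freq * tt), channels),
                nrow = channels, byrow = TRUE)
  eeg_recording(sig, fs = fs, markers = markers)
}
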