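# Hybrid statistical channel selection: per-channel Welch t-tests on a
# per-trial feature, Bonferroni family-wise correction, and an inter-channel
# correlation criterion, summarized by channel-reduction statistics.

#' Channel-selection configuration
#'
#' @param alpha family-wise significance level for the per-channel tests
#'   (default 0.10).
#' @param r_min absolute-correlation criterion: a significant channel is
#'   retained only if it correlates at `|r| >= r_min` with at least one other
#'   significant channel (default 0.5).
#' @param r_redundant redundancy-pruning threshold: when pruning is enabled,
#'   of any retained pair with `|r| > r_redundant` the channel with the
#'   larger p-value is dropped (default 0.95).
#' @param prune_redundant enable redundancy pruning (default `FALSE`).
#' @param feature per-trial channel feature the classes are compared on:
#'   `"log-band-power"` (default; log mean-square amplitude in `band`, the
#'   physiologically discriminative quantity for motor imagery) or
#'   `"raw-amplitude"` (per-trial mean amplitude, for sensitivity analysis).
#' @param band frequency band in Hz for the band-power feature (default
#'   `c(8, 30)`, the mu + beta range).
#' @return A `selection_config` list.
#' @export
selection_config <- function(alpha = 0.10, r_min = 0.5, r_redundant = 0.95,
                             prune_redundant = FALSE,
                             feature = c("log-band-power", "raw-amplitude"),
                             band = c(8, 30)) {
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) validation_error("alpha must be in (0, 1)")
  assert_scalar_number(r_min, "r_min")
  if (r_min < 0 || r_min > 1) validation_error("r_min must be in [0, 1]")
  assert_scalar_number(r_redundant, "r_redundant")
  if (r_redundant < r_min)
    validation_error("r_redundant must be >= r_min")
  structure(list(alpha = alpha, r_min = r_min, r_redundant = r_redundant,
                 prune_redundant = isTRUE(prune_redundant),
                 feature = match.arg(feature), band = as.numeric(band)),
            class = "selection_config")
}

# trials x channels matrix of the per-trial feature the t-test compares.
selection_feature <- function(x, cfg) {
  if (cfg$feature == "log-band-power") {
    log(band_power(x, cfg$band) + .Machine$double.xmin)
  } else {
    t(apply(x$data, 1L, rowMeans))
  }
}

#' Per-channel two-class Welch t statistics
#'
#' For every channel, a two-sided Welch (unequal-variance) two-sample t-test
#' compares the per-trial feature (see [selection_config()]) between the two
#' motor-imagery classes.
#'
#' @param x an [eeg_epochs()] with both classes present (>= 2 trials each).
#' @param cfg a [selection_config()].
#' @return List with numeric vectors `t` and `p` (two-sided), one entry per
#'   channel.
#' @export
channel_tstats <- function(x, cfg = selection_config()) {
  if (!inherits(x, "eeg_epochs"))
    validation_error("x must be an eeg_epochs object")
  if (length(unique(x$labels)) < 2L)
    validation_error("both classes must be present")
  if (min(table(x$labels)) < 2L)
    validation_error("each class needs at least 2 trials")
  feats <- selection_feature(x, cfg)
  i1 <- x$labels == 1L
  res <- apply(feats, 2L, function(f) {
    if (sd(f[i1]) == 0 && sd(f[!i1]) == 0) {
      if (isTRUE(all.equal(mean(f[i1]), mean(f[!i1])))) return(c(0, 1))
      return(c(sign(mean(f[i1]) - mean(f[!i1])) * Inf, 0))
    }
    tt <- t.test(f[i1], f[!i1], var.equal = FALSE)
    c(unname(tt$statistic), tt$p.value)
  })
  list(t = res[1L, ], p = res[2L, ])
}

#' Bonferroni mask over per-channel p-values
#'
#' @param p_values numeric vector of per-channel p-values.
#' @param alpha family-wise level in (0, 1).
#' @return List with logical `mask` (`TRUE` where `p < alpha / n`) and the
#'   `corrected_threshold` `alpha / n`.
#' @examples
#' bonferroni_mask(runif(118), 0.10)$corrected_threshold  # 0.10 / 118
#' @export
bonferroni_mask <- function(p_values, alpha = 0.10) {
  if (length(p_values) == 0L)
    validation_error("p_values must be non-empty")
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) validation_error("alpha must be in (0, 1)")
  thr <- alpha / length(p_values)
  list(mask = p_values < thr, corrected_threshold = thr)
}

#' Pearson correlation between channels
#'
#' Correlation of the trial-concatenated channel time series. Zero-variance
#' channels get correlation 0 against every other channel (diagonal stays 1)
#' with a warning.
#'
#' @param x an [eeg_epochs()] object.
#' @return channels x channels symmetric correlation matrix with unit
#'   diagonal.
#' @export
channel_correlation <- function(x) {
  if (!inherits(x, "eeg_epochs"))
    validation_error("x must be an eeg_epochs object")
  d <- dim(x$data)
  if (d[1L] * d[3L] < 2L) validation_error("need at least 2 time points")
  # channels x (trials * samples)
  flat <- matrix(aperm(x$data, c(2L, 3L, 1L)), nrow = d[2L])
  sds <- apply(flat, 1L, sd)
  degenerate <- sds == 0
  r <- suppressWarnings(cor(t(flat)))
  if (any(degenerate)) {
    warning("zero-variance channel(s): ",
            paste(x$channel_names[degenerate], collapse = ", "),
            "; correlations set to 0")
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  diag(r) <- 1
  dimnames(r) <- list(x$channel_names, x$channel_names)
  r
}

#' Channel-reduction statistics
#'
#' Two summaries of how many channels survive selection are in circulation:
#' the retention ratio `rc / oc`, truncated (not rounded) to two decimals as
#' commonly tabulated, and the reduction rate `1 - rc / oc`. Both are
#' returned.
#'
#' @param oc original channel count (> 0).
#' @param rc retained channel count (0 <= rc <= oc).
#' @return List with `retention_ratio` (`floor(100 * rc / oc) / 100`) and
#'   `reduction_rate` (`1 - rc / oc`).
#' @examples
#' crr(118, 49)  # retention 0.41, reduction 0.5847...
#' @export
crr <- function(oc, rc) {
  assert_scalar_number(oc, "oc", positive = TRUE)
  assert_scalar_number(rc, "rc")
  if (rc < 0 || rc > oc)
    validation_error("rc must satisfy 0 <= rc <= oc")
  list(retention_ratio = floor(100 * rc / oc) / 100,
       reduction_rate = 1 - rc / oc)
}

#' Hybrid statistical channel selection
#'
#' Retains the channels that (a) pass the Bonferroni-corrected per-channel
#' Welch t-test at level `alpha` and (b) correlate at `|r| >= r_min` with at
#' least one other channel passing the test — a coherent-task-network
#' criterion. Optional redundancy pruning drops, from any retained pair with
#' `|r| > r_redundant`, the channel with the larger p-value.
#'
#' @param x an [eeg_epochs()] with both classes present.
#' @param cfg a [selection_config()].
#' @return An object of class `mi_selection`: `t`, `p`,
#'   `corrected_threshold`, `corr` (channel correlation matrix), `selected`
#'   (ordered indices), `oc`, `rc`, `retention_ratio`, `reduction_rate`,
#'   `empty` flag, and the `config`.
#' @examples
#' ep <- simulate_epochs(sim_config(n_trials_per_class = 30, seed = 2))$epochs
#' sel <- select_channels(ep)
#' sel$selected
#' @export
select_channels <- function(x, cfg = selection_config()) {
  ts <- channel_tstats(x, cfg)
  bm <- bonferroni_mask(ts$p, cfg$alpha)
  r <- channel_correlation(x)
  sig <- which(bm$mask)
  selected <- integer(0)
  if (length(sig) >= 2L) {
    rs <- abs(r[sig, sig, drop = FALSE])
    diag(rs) <- 0
    selected <- sig[apply(rs, 1L, max) >= cfg$r_min]
  }
  if (cfg$prune_redundant && length(selected) >= 2L) {
    repeat {
      rs <- abs(r[selected, selected, drop = FALSE])
      diag(rs) <- 0
      over <- which(rs > cfg$r_redundant, arr.ind = TRUE)
      if (nrow(over) == 0L) break
      pair <- over[which.max(rs[over]), ]
      drop_local <- pair[which.max(ts$p[selected[pair]])]
      selected <- selected[-drop_local]
    }
  }
  selected <- sort(selected)
  oc <- n_channels(x)
  rc <- length(selected)
  stats <- crr(oc, rc)
  if (rc == 0L)
    message("no channels selected (empty selection flagged)")
  structure(
    list(t = ts$t, p = ts$p, corrected_threshold = bm$corrected_threshold,
         corr = r, selected = selected,
         channel_names = x$channel_names[selected],
         oc = oc, rc = rc,
         retention_ratio = stats$retention_ratio,
         reduction_rate = stats$reduction_rate,
         empty = rc == 0L, config = cfg),
    class = "mi_selection")
}

#' @export
print.mi_selection <- function(x, ...) {
  cat("<mi_selection>\n")
  cat(sprintf("  %d of %d channels retained (retention %.2f, reduction %.3f)\n",
              x$rc, x$oc, x$retention_ratio, x$reduction_rate))
  cat(sprintf("  Bonferroni threshold: %.3g (alpha %.2f)\n",
              x$corrected_threshold, x$config$alpha))
  if (x$rc > 0L)
    cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}
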