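# Confusion-matrix metrics, ROC/AUC, and the paired model-comparison tests.

#' Confusion-matrix metrics
#'
#' @param tp,fp,tn,fn non-negative counts (at least one must be positive).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `f1`, and `undefined` — the names of any metric whose denominator was
#'   zero, which are reported as 0.
#' @examples
#' confusion_metrics(40, 15, 35, 10)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0))
    validation_error("counts must be non-negative numbers")
  total <- sum(counts)
  if (total == 0) validation_error("all counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  vals <- c(accuracy = (tp + tn) / total, sensitivity = sens,
            specificity = spec, precision = prec, f1 = f1)
  undefined <- names(vals)[is.na(vals)]
  vals[is.na(vals)] <- 0
  c(as.list(vals), list(undefined = undefined))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the observed scores and reports
#' `(fpr, tpr)` points plus the trapezoidal area under the curve. The
#' trapezoid over tied scores credits ties with 1/2, so the AUC equals
#' `P(score_pos > score_neg) + P(score_pos = score_neg) / 2`.
#'
#' @param scores numeric vector of scores for the positive class.
#' @param labels per-sample labels; `positive` marks the positive class.
#' @param positive the positive class value (default 1).
#' @return List with `roc` (data frame of `fpr`, `tpr` from (0,0) to (1,1))
#'   and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 2, 2))$auc  # 1
#' @export
roc_auc <- function(scores, labels, positive = 1) {
  if (length(scores) != length(labels))
    validation_error("scores and labels must have equal length")
  pos <- labels == positive
  if (!any(pos) || all(pos))
    validation_error("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  sc <- scores[ord]
  # cumulative counts at each distinct threshold
  keep <- c(diff(sc) != 0, TRUE)
  tp <- cumsum(pos)[keep]
  fp <- cumsum(!pos)[keep]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Paired two-sided t-test on accuracy vectors
#'
#' @param a,b equal-length paired numeric vectors (n >= 2).
#' @return List with `t`, `p` (two-sided), `df`, and `mean_diff` (`a - b`).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b))
    validation_error("a and b must have equal length")
  if (length(a) < 2L) validation_error("need at least 2 pairs")
  d <- a - b
  if (all(d == 0))
    return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0))
  if (sd(d) == 0)
    stop_mieeg("paired differences have zero variance: t-test is degenerate",
               class = "mieeg_degenerate_error")
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d))
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired test. Zero differences are excluded (the zero-exclusion
#' rule); ties among the absolute differences share average ranks, so the
#' reported statistic — the smaller of the positive- and negative-rank sums —
#' can be fractional. For n <= 25 retained pairs the null distribution is
#' computed exactly by dynamic programming over the (doubled, hence integer)
#' ranks; beyond that a normal approximation with tie correction is used.
#'
#' @param a,b equal-length paired numeric vectors, or give the differences
#'   directly in `a` with `b = NULL`.
#' @return List with `statistic` (min rank sum), `w_pos`, `w_neg`, `p`
#'   (two-sided), `n_used`, `n_zero`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL) {
  d <- if (is.null(b)) a else {
    if (length(a) != length(b))
      validation_error("a and b must have equal length")
    a - b
  }
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop_mieeg("all differences are zero: signed-rank test is degenerate",
               class = "mieeg_degenerate_error")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  stat <- min(w_pos, w_neg)
  if (n <= 25L) {
    # exact null: distribution of the positive-rank sum over 2^n equiprobable
    # sign assignments; doubling the (possibly half-integer) ranks makes all
    # sums integers for the DP
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)   # counts[s + 1] = #assignments with sum s
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(total + 1L - rr)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    wp2 <- as.integer(round(2 * w_pos))
    p_le <- sum(probs[seq_len(wp2 + 1L)])
    p_ge <- sum(probs[seq.int(wp2 + 1L, total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = stat, w_pos = w_pos, w_neg = w_neg, p = p,
       n_used = n, n_zero = n_zero, method = method)
}
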