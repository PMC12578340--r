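# Shrinkage-regularized common spatial patterns: per-class covariance
# estimation, Ledoit-Wolf shrinkage intensity, the generalized eigenproblem,
# and log-variance feature extraction.

#' Per-trial covariance matrix
#'
#' `C = X X' / m` after per-trial mean removal, where `X` is the channels x
#' samples trial matrix and `m` the sample count. The `1/m` normalization
#' (not `1/(m-1)`) is the convention used throughout the CSP stage.
#'
#' @param x numeric channels x samples matrix with at least 2 samples.
#' @return channels x channels symmetric positive semi-definite matrix.
#' @export
trial_covariance <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    validation_error("x must be a numeric channels x samples matrix")
  m <- ncol(x)
  if (m < 2L) validation_error("need at least 2 samples")
  xc <- x - rowMeans(x)
  C <- tcrossprod(xc) / m
  (C + t(C)) / 2
}

#' Class-average covariance
#'
#' Mean of the per-trial covariances over all trials of one class.
#'
#' @param x an [eeg_epochs()] object.
#' @param class_label class whose covariance to estimate (1 or 2).
#' @return channels x channels covariance matrix.
#' @export
class_covariance <- function(x, class_label) {
  if (!inherits(x, "eeg_epochs"))
    validation_error("x must be an eeg_epochs object")
  idx <- which(x$labels == as.integer(class_label))
  if (length(idx) == 0L)
    validation_error("no trials with label ", class_label)
  n <- n_channels(x)
  C <- matrix(0, n, n)
  for (i in idx) C <- C + trial_covariance(trial_matrix(x, i))
  C / length(idx)
}

#' Ledoit-Wolf shrinkage intensity
#'
#' Analytically optimal intensity for shrinking a sample covariance toward
#' the scaled identity `nu * I` with `nu = trace(C) / n` (the mean variance),
#' following the Ledoit-Wolf well-conditioned estimator. The observations are
#' the pooled, per-trial-centered time samples of the class. The intensity is
#' clipped to `[0, 1]`; it tends to 0 as the sample count grows and toward 1
#' when channels outnumber samples.
#'
#' @param x trials of one class: a trials x channels x samples array, a
#'   single channels x samples matrix, or a list of such matrices.
#' @return Shrinkage intensity `gamma` in `[0, 1]`, with the target scale
#'   `nu` attached as attribute `"nu"`.
#' @export
lw_intensity <- function(x) {
  if (is.matrix(x)) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- lapply(seq_len(dim(x)[1L]), function(i) {
      m <- x[i, , , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = dim(x)[2L])
      m
    })
  }
  if (!is.list(x) || !length(x))
    validation_error("x must be trials as a matrix, list or 3-d array")
  obs <- do.call(cbind, lapply(x, function(m) m - rowMeans(m)))
  n <- nrow(obs)
  T_ <- ncol(obs)
  S <- tcrossprod(obs) / T_
  mu <- sum(diag(S)) / n
  d2 <- sum((S - mu * diag(n))^2) / n
  if (d2 < .Machine$double.eps)
    return(structure(0, nu = mu))
  # (1/T^2) sum_t ||x_t x_t' - S||_F^2 / n, via
  # ||x x' - S||^2 = (x'x)^2 - 2 x'Sx + ||S||^2
  xx <- colSums(obs^2)
  xsx <- colSums(obs * (S %*% obs))
  b2bar <- (sum(xx^2) - 2 * sum(xsx) + T_ * sum(S^2)) / (T_^2 * n)
  gamma <- min(b2bar, d2) / d2
  structure(max(0, min(1, gamma)), nu = mu)
}

#' Shrink a covariance toward a scaled identity
#'
#' `C_reg = alpha * C + (1 - alpha) * nu * I`. With `nu = 1` this is the
#' literal identity-target form; with `nu = trace(C)/n` it is the
#' scale-consistent Ledoit-Wolf target. Eigenvalues map as
#' `alpha * eig(C) + (1 - alpha) * nu`, so `C_reg` is positive definite
#' whenever `alpha < 1` and `nu > 0`.
#'
#' @param C symmetric covariance matrix.
#' @param alpha mixing weight on the sample covariance, in `[0, 1]`
#'   (`alpha = 1 - gamma` for Ledoit-Wolf intensity `gamma`).
#' @param nu shrinkage-target scale (default 1).
#' @return The regularized covariance matrix.
#' @export
shrink_covariance <- function(C, alpha, nu = 1) {
  if (!is_symmetric_matrix(C))
    validation_error("C must be a symmetric matrix")
  assert_scalar_number(alpha, "alpha")
  if (alpha < 0 || alpha > 1)
    validation_error("alpha must be in [0, 1]")
  assert_scalar_number(nu, "nu")
  alpha * C + (1 - alpha) * nu * diag(nrow(C))
}

#' Shrinkage-regularized class covariance estimate
#'
#' Combines [class_covariance()], [lw_intensity()] and [shrink_covariance()]
#' for one class: the Ledoit-Wolf intensity `gamma` is estimated from the
#' class's trials and the class covariance is shrunk with
#' `alpha = 1 - gamma` toward the chosen target.
#'
#' @param x an [eeg_epochs()] object.
#' @param class_label class (1 or 2).
#' @param target `"scaled"` (default; `nu = trace(C)/n`) or `"identity"`
#'   (`nu = 1`).
#' @return List of class `mi_cov` with `C`, `C_reg`, `alpha`, `gamma`, `nu`.
#' @export
class_cov_estimate <- function(x, class_label,
                               target = c("scaled", "identity")) {
  target <- match.arg(target)
  C <- class_covariance(x, class_label)
  idx <- which(x$labels == as.integer(class_label))
  trials <- lapply(idx, function(i) trial_matrix(x, i))
  gamma <- lw_intensity(trials)
  nu <- if (target == "scaled") attr(gamma, "nu") else 1
  alpha <- 1 - as.numeric(gamma)
  structure(list(C = C, C_reg = shrink_covariance(C, alpha, nu),
                 alpha = alpha, gamma = as.numeric(gamma), nu = nu,
                 target = target),
            class = "mi_cov")
}

#' Common spatial pattern filters
#'
#' Solves the generalized eigenproblem `C1 w = lambda (C1 + C2) w` by
#' whitening the composite covariance: eigenvalues lie in (0, 1) and filters
#' are normalized so that `w' (C1 + C2) w = 1`. The `m_pairs` filters with
#' the largest eigenvalues (variance maximal for class 1) and the `m_pairs`
#' with the smallest (variance maximal for class 2) are kept. The kept
#' filters simultaneously diagonalize both class covariances.
#'
#' @param C1,C2 symmetric positive definite class covariances of equal size
#'   (matrices or [class_cov_estimate()] results, whose `C_reg` is used).
#' @param m_pairs filter pairs to keep; `2 * m_pairs` must not exceed the
#'   channel count.
#' @return Object of class `mi_csp`: `W` (channels x `2*m_pairs`),
#'   `eigvals` (all, descending), `kept` (indices into the full spectrum),
#'   `m_pairs`, `cov1`, `cov2`, and a `non_discriminative` flag (all
#'   eigenvalues near 0.5).
#' @examples
#' f <- csp_filters(diag(c(2, 1)), diag(c(1, 2)), m_pairs = 1)
#' f$eigvals  # 2/3, 1/3
#' @export
csp_filters <- function(C1, C2, m_pairs = 3) {
  cov1 <- if (inherits(C1, "mi_cov")) C1 else NULL
  cov2 <- if (inherits(C2, "mi_cov")) C2 else NULL
  if (!is.null(cov1)) C1 <- cov1$C_reg
  if (!is.null(cov2)) C2 <- cov2$C_reg
  if (!is_symmetric_matrix(C1) || !is_symmetric_matrix(C2))
    validation_error("C1 and C2 must be symmetric matrices")
  if (!identical(dim(C1), dim(C2)))
    validation_error("C1 and C2 must have equal size")
  n <- nrow(C1)
  m_pairs <- as.integer(m_pairs)
  if (m_pairs < 1L || 2L * m_pairs > n)
    validation_error("need 1 <= 2*m_pairs <= channel count")
  M <- C1 + C2
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(em$values) <= n * max(em$values) * .Machine$double.eps)
    stop_mieeg("composite covariance is numerically singular; ",
               "apply shrinkage (see shrink_covariance) before CSP",
               class = "mieeg_decomposition_error")
  P <- em$vectors %*% (t(em$vectors) / sqrt(em$values))
  K <- P %*% C1 %*% P
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  W_full <- P %*% ek$vectors
  lambda <- pmin(pmax(ek$values, 0), 1)
  kept <- c(seq_len(m_pairs), seq.int(n - m_pairs + 1L, n))
  non_disc <- max(abs(lambda - 0.5)) < 1e-6
  if (non_disc)
    message("all CSP eigenvalues are 0.5: classes are not discriminable ",
            "by second-order statistics")
  structure(list(W = W_full[, kept, drop = FALSE], eigvals = lambda,
                 kept = kept, m_pairs = m_pairs,
                 cov1 = if (is.null(cov1)) C1 else cov1,
                 cov2 = if (is.null(cov2)) C2 else cov2,
                 non_discriminative = non_disc),
            class = "mi_csp")
}

#' @export
print.mi_csp <- function(x, ...) {
  cat(sprintf("<mi_csp> %d filter pairs over %d channels\n",
              x$m_pairs, nrow(x$W)))
  cat("  kept eigenvalues:",
      paste(sprintf("%.3f", x$eigvals[x$kept]), collapse = ", "), "\n")
  invisible(x)
}

#' CSP log-variance features
#'
#' Projects every trial through the spatial filters and takes the log of the
#' projected variance: `feature_j = log(var(w_j' X))`. Zero-variance
#' projections are floored at machine epsilon with a warning.
#'
#' @param model an `mi_csp` from [csp_filters()].
#' @param x an [eeg_epochs()] with the channel count the model was fit on.
#' @return trials x `2 * m_pairs` feature matrix.
#' @export
csp_log_features <- function(model, x) {
  if (!inherits(model, "mi_csp")) validation_error("model must be an mi_csp")
  if (!inherits(x, "eeg_epochs"))
    validation_error("x must be an eeg_epochs object")
  if (n_channels(x) != nrow(model$W))
    validation_error("epochs have ", n_channels(x), " channels but the model ",
                     "was fit on ", nrow(model$W))
  n_tr <- n_trials(x)
  out <- matrix(0, n_tr, ncol(model$W))
  floored <- FALSE
  for (i in seq_len(n_tr)) {
    proj <- t(model$W) %*% trial_matrix(x, i)
    v <- apply(proj, 1L, function(y) mean((y - mean(y))^2))
    if (any(v <= 0)) {
      v <- pmax(v, .Machine$double.eps)
      floored <- TRUE
    }
    out[i, ] <- log(v)
  }
  if (floored)
    warning("zero-variance projection(s) floored at machine epsilon")
  colnames(out) <- paste0("csp", seq_len(ncol(out)))
  out
}
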