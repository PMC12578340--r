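# The central fitted model: channel selection -> shrinkage-regularized CSP ->
# ridge refinement -> neural-network classifier, as one S3 object.

#' Fit the channel-selection + regularized-CSP classification model
#'
#' Runs the full modelling chain on epoched two-class data: hybrid
#' statistical channel selection (optional), Ledoit-Wolf shrinkage-regularized
#' class covariances, CSP spatial filters, log-variance features, an
#' L2-regularized linear refinement whose discriminant scores augment the
#' feature vector, and a neural-network classifier.
#'
#' @param x an [eeg_epochs()] object with both classes present.
#' @param selection a [selection_config()], or `NULL` to keep all channels.
#' @param m_pairs CSP filter pairs (capped at `floor(channels / 2)`).
#' @param shrink_target covariance shrinkage target, `"scaled"` or
#'   `"identity"` (see [class_cov_estimate()]).
#' @param lambda ridge penalty for the refinement: a number, or `"auto"` for
#'   5-fold selection over `10^(-3..3)` on the training data.
#' @param classifier `"mlp"` (default) or `"lstm"`.
#' @param train a [train_config()].
#' @param positive positive class for reporting (default 1).
#' @return An object of class `mi_fit` with components `selection`,
#'   `csp`, `ridge`, `classifier`, `lambda`, and the configurations used.
#'   Methods: `print`, `summary`, `predict`, `coef`, `plot`.
#' @examples
#' sim <- simulate_epochs(sim_config(n_trials_per_class = 30, seed = 4))
#' fit <- mi_fit(sim$epochs, train = train_config(epochs = 20, seed = 4))
#' fit
#' table(predict(fit, sim$epochs), sim$epochs$labels)
#' @export
mi_fit <- function(x, selection = selection_config(), m_pairs = 3,
                   shrink_target = c("scaled", "identity"), lambda = "auto",
                   classifier = c("mlp", "lstm"), train = train_config(),
                   positive = 1) {
  if (!inherits(x, "eeg_epochs"))
    validation_error("x must be an eeg_epochs object")
  shrink_target <- match.arg(shrink_target)
  classifier <- match.arg(classifier)
  sel <- NULL
  x_sel <- x
  if (!is.null(selection)) {
    sel <- select_channels(x, selection)
    if (sel$rc < 2L)
      stop_mieeg("channel selection retained ", sel$rc, " channel(s); ",
                 "at least 2 are needed for spatial filtering. Relax the ",
                 "selection (or pass selection = NULL).",
                 class = "mieeg_empty_result_error")
    x_sel <- subset_channels(x, sel$selected)
  }
  m_pairs <- min(as.integer(m_pairs), floor(n_channels(x_sel) / 2))
  cov1 <- class_cov_estimate(x_sel, 1L, target = shrink_target)
  cov2 <- class_cov_estimate(x_sel, 2L, target = shrink_target)
  csp <- csp_filters(cov1, cov2, m_pairs = m_pairs)
  feats <- csp_log_features(csp, x_sel)
  if (identical(lambda, "auto"))
    lambda <- select_ridge_lambda(feats, x$labels,
                                  seed = derive_seed(train$seed, 3L))
  ridge <- ridge_refine(feats, x$labels, lambda = lambda)
  full_feats <- cbind(feats, feats %*% ridge$W)
  colnames(full_feats) <- c(colnames(feats),
                            paste0("ridge", seq_len(ncol(ridge$W))))
  spec <- if (classifier == "mlp") mlp_spec(ncol(full_feats)) else
    rnn_spec(ncol(full_feats))
  net <- train_classifier(spec, full_feats, x$labels, train)
  structure(list(selection = sel, csp = csp, ridge = ridge, lambda = lambda,
                 classifier = net, classifier_type = classifier,
                 features = full_feats, labels = x$labels,
                 channel_names = x_sel$channel_names, positive = positive,
                 m_pairs = m_pairs, shrink_target = shrink_target,
                 train = train),
            class = "mi_fit")
}

# CSP + ridge features for new epochs, using the fitted stages only.
mi_fit_features <- function(object, x) {
  if (!is.null(object$selection))
    x <- subset_channels(x, object$selection$selected)
  feats <- csp_log_features(object$csp, x)
  cbind(feats, feats %*% object$ridge$W)
}

#' @export
predict.mi_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "eeg_epochs"))
    validation_error("newdata must be an eeg_epochs object")
  feats <- mi_fit_features(object, newdata)
  predict(object$classifier, feats, type = type)
}

#' @export
print.mi_fit <- function(x, ...) {
  cat("<mi_fit> shrinkage-CSP motor-imagery classifier\n")
  if (!is.null(x$selection))
    cat(sprintf("  channels: %d of %d retained (retention %.2f)\n",
                x$selection$rc, x$selection$oc, x$selection$retention_ratio))
  cat(sprintf("  CSP: %d pairs; shrinkage alpha = %.3f / %.3f (%s target)\n",
              x$m_pairs, x$csp$cov1$alpha, x$csp$cov2$alpha,
              x$shrink_target))
  cat(sprintf("  ridge lambda = %g; classifier: %s (%d parameters)\n",
              x$lambda, x$classifier_type, x$classifier$spec$n_params))
  invisible(x)
}

#' @export
summary.mi_fit <- function(object, ...) {
  print(object)
  pred <- max.col(predict(object$classifier, object$features, type = "prob"))
  cat(sprintf("\n  training accuracy: %.1f %%\n",
              100 * mean(pred == object$labels)))
  cat("  kept CSP eigenvalues:",
      paste(sprintf("%.3f", object$csp$eigvals[object$csp$kept]),
            collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.mi_fit <- function(object, ...) {
  list(spatial_filters = object$csp$W, refinement = object$ridge$W)
}

#' @export
plot.mi_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(x$csp$eigvals, type = "h", ylim = c(0, 1), xlab = "component",
       ylab = "generalized eigenvalue", main = "CSP spectrum")
  abline(h = 0.5, lty = 2, col = "grey")
  f <- x$features
  plot(f[, 1L], f[, ncol(x$csp$W)], col = x$labels, pch = 19,
       xlab = "first CSP log-variance", ylab = "last CSP log-variance",
       main = "feature separation")
  legend("topright", legend = c("class 1", "class 2"), col = 1:2, pch = 19)
  invisible(x)
}

#' Cross-validated evaluation of the full model on epoched data
#'
#' Applies the fitted-on-all-data selection and CSP/ridge feature extraction,
#' then evaluates the classifier by stratified [kfold_cv()] on the resulting
#' features (standardization is re-fit inside every training split).
#'
#' @inheritParams mi_fit
#' @param k number of folds.
#' @return An `mi_cv_report` (see [kfold_cv()]) with the `mi_selection`
#'   attached as `$selection`.
#' @export
mi_cv <- function(x, k = 5, selection = selection_config(), m_pairs = 3,
                  shrink_target = c("scaled", "identity"), lambda = "auto",
                  classifier = c("mlp", "lstm"), train = train_config(),
                  positive = 1) {
  shrink_target <- match.arg(shrink_target)
  classifier <- match.arg(classifier)
  fit <- mi_fit(x, selection = selection, m_pairs = m_pairs,
                shrink_target = shrink_target, lambda = lambda,
                classifier = classifier, train = train, positive = positive)
  spec <- if (classifier == "mlp") mlp_spec(ncol(fit$features)) else
    rnn_spec(ncol(fit$features))
  rep <- kfold_cv(fit$features, x$labels, k = k, spec = spec,
                  config = train, positive = positive)
  rep$selection <- fit$selection
  rep$lambda <- fit$lambda
  rep
}
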