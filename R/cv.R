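# Stratified k-fold cross-validation with per-fold standardization and
# confusion/ROC metrics.

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits the samples into `k` stratified folds (per-class fold sizes differ
#' by at most one), trains the classifier on `k - 1` folds and tests on the
#' held-out fold, so each sample is tested exactly once. Feature
#' standardization is fit on the training folds only (inside
#' [train_classifier()]), never on the test fold.
#'
#' @param X n x d feature matrix.
#' @param y labels in `{1, 2}`.
#' @param k number of folds (default 5).
#' @param spec architecture specification; default [mlp_spec()] sized to `X`.
#' @param config a [train_config()]; its `seed` drives the fold assignment
#'   and per-fold training, making the whole report reproducible.
#' @param positive positive class for sensitivity/precision (default 1).
#' @return Object of class `mi_cv_report`: `per_fold` data frame (accuracy,
#'   sensitivity, specificity, precision, f1, auc per fold), `mean_sd`
#'   matrix, `roc` (per-fold ROC point data frames), `folds` assignment,
#'   `k`, `positive`, `config`.
#' @examples
#' sep <- make_separable_features(60, 4, margin = 6, seed = 1)
#' rep <- kfold_cv(sep$X, sep$y, k = 5,
#'                 config = train_config(epochs = 20, seed = 1))
#' rep$mean_sd["accuracy", ]
#' @export
kfold_cv <- function(X, y, k = 5, spec = NULL, config = train_config(),
                     positive = 1) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- prepare_labels(y, nrow(X))
  n <- nrow(X)
  k <- as.integer(k)
  if (n < k) validation_error("need at least k samples")
  if (is.null(spec)) spec <- mlp_spec(ncol(X))
  folds <- with_seed(derive_seed(config$seed, 17L), {
    f <- integer(n)
    start <- 0L              # rotate across classes so totals stay balanced
    for (cls in c(1L, 2L)) {
      idx <- sample(which(y == cls))
      f[idx] <- ((seq_along(idx) - 1L + start) %% k) + 1L
      start <- (start + length(idx)) %% k
    }
    f
  })
  if (any(vapply(seq_len(k), function(f)
    length(unique(y[folds != f])) < 2L, logical(1))))
    validation_error("stratification failed: a training split lost a class")
  per_fold <- vector("list", k)
  rocs <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, f)
    fit <- train_classifier(spec, X[tr, , drop = FALSE], y[tr], fold_cfg)
    probs <- predict(fit, X[!tr, , drop = FALSE], type = "prob")
    pred <- max.col(probs)
    truth <- y[!tr]
    tp <- sum(pred == positive & truth == positive)
    fp <- sum(pred == positive & truth != positive)
    tn <- sum(pred != positive & truth != positive)
    fn <- sum(pred != positive & truth == positive)
    metrics <- confusion_metrics(tp, fp, tn, fn)
    ra <- roc_auc(probs[, positive], truth, positive = positive)
    per_fold[[f]] <- data.frame(fold = f, accuracy = metrics$accuracy,
                                sensitivity = metrics$sensitivity,
                                specificity = metrics$specificity,
                                precision = metrics$precision,
                                f1 = metrics$f1, auc = ra$auc)
    rocs[[f]] <- ra$roc
  }
  per_fold <- do.call(rbind, per_fold)
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f1", "auc")
  mean_sd <- t(vapply(metric_names, function(m)
    c(mean = mean(per_fold[[m]]), sd = sd(per_fold[[m]])), numeric(2)))
  structure(list(per_fold = per_fold, mean_sd = mean_sd, roc = rocs,
                 folds = folds, k = k, positive = positive, config = config,
                 spec = spec),
            class = "mi_cv_report")
}

#' @export
print.mi_cv_report <- function(x, ...) {
  cat(sprintf("<mi_cv_report> %d-fold cross-validation (%s)\n", x$k,
              class(x$spec)[1L]))
  for (m in rownames(x$mean_sd))
    cat(sprintf("  %-12s %.2f +/- %.2f %%\n", m,
                100 * x$mean_sd[m, "mean"], 100 * x$mean_sd[m, "sd"]))
  invisible(x)
}

#' @export
summary.mi_cv_report <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics:\n")
  print(object$per_fold, row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
plot.mi_cv_report <- function(x, ...) {
  plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Per-fold ROC (mean AUC %.3f)",
                      x$mean_sd["auc", "mean"]), ...)
  for (f in seq_along(x$roc))
    lines(x$roc[[f]]$fpr, x$roc[[f]]$tpr, col = f)
  legend("bottomright", legend = paste("fold", seq_along(x$roc)),
         col = seq_along(x$roc), lty = 1, cex = 0.8)
  invisible(x)
}
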