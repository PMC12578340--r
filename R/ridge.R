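# L2-regularized linear refinement of the CSP feature space:
# minimize ||X W - Y||^2 + lambda ||W||^2.

#' Ridge-regularized linear refinement
#'
#' Minimizes the penalized squared error `||X W - Y||^2 + lambda ||W||^2`
#' over the feature-space weights `W`. The closed-form solution
#' `(X'X + lambda I)^{-1} X'Y` is the default; `method = "gd"` solves the
#' same problem by gradient descent (with a step size guaranteeing a
#' monotonically non-increasing loss) and is mainly useful as an independent
#' check of the closed form.
#'
#' @param X numeric n x d feature matrix.
#' @param y targets: a vector coded in `{-1, +1}` (or a factor / `{1, 2}`
#'   labels, recoded to +/-1), or an n x k matrix (e.g. one-hot).
#' @param lambda L2 penalty, >= 0.
#' @param method `"closed"` (default) or `"gd"`.
#' @param max_iter,tol gradient-descent iteration cap and relative loss
#'   tolerance.
#' @return Object of class `mi_ridge`: `W` (d x k), `lambda`, `loss`, and
#'   for `"gd"` the per-iteration `loss_trace`.
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' y <- sign(X[, 1] + rnorm(50, sd = 0.1))
#' fit <- ridge_refine(X, y, lambda = 1)
#' fit$loss
#' @export
ridge_refine <- function(X, y, lambda = 1, method = c("closed", "gd"),
                         max_iter = 5000L, tol = 1e-12) {
  method <- match.arg(method)
  if (!is.matrix(X) || !is.numeric(X))
    validation_error("X must be a numeric matrix")
  assert_scalar_number(lambda, "lambda")
  if (lambda < 0) validation_error("lambda must be >= 0")
  Y <- ridge_targets(y, nrow(X))
  d <- ncol(X)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  A <- XtX + lambda * diag(d)
  loss_trace <- NULL
  if (method == "closed") {
    W <- tryCatch(solve(A, XtY), error = function(e) NULL)
    if (is.null(W)) {
      if (lambda > 0)
        stop_mieeg("ridge system is numerically singular",
                   class = "mieeg_decomposition_error")
      warning("X'X is rank deficient with lambda = 0; ",
              "using the pseudo-inverse (minimum-norm) solution")
      sv <- svd(X)
      pos <- sv$d > max(sv$d) * max(dim(X)) * .Machine$double.eps
      W <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    }
  } else {
    # Lipschitz constant of the gradient is 2*(||X'X|| + lambda)
    L <- 2 * (max(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values) +
                lambda)
    step <- 1 / L
    W <- matrix(0, d, ncol(Y))
    loss_trace <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      grad <- 2 * (XtX %*% W - XtY + lambda * W)
      W <- W - step * grad
      cur <- ridge_loss(X, Y, W, lambda)
      loss_trace <- c(loss_trace, cur)
      if (is.finite(prev) && abs(prev - cur) <= tol * max(1, prev)) break
      prev <- cur
    }
  }
  structure(list(W = W, lambda = lambda, loss = ridge_loss(X, Y, W, lambda),
                 loss_trace = loss_trace, method = method),
            class = "mi_ridge")
}

ridge_targets <- function(y, n) {
  if (is.matrix(y)) {
    if (nrow(y) != n) validation_error("target rows must match X rows")
    return(y)
  }
  if (is.factor(y)) y <- as.integer(y)
  if (length(y) != n) validation_error("length(y) must match nrow(X)")
  vals <- sort(unique(y))
  if (identical(as.numeric(vals), c(-1, 1))) return(matrix(y, ncol = 1L))
  if (length(vals) == 2L)
    return(matrix(ifelse(y == vals[1L], -1, 1), ncol = 1L))
  validation_error("y must be binary (two distinct values) or a matrix")
}

ridge_loss <- function(X, Y, W, lambda) {
  sum((X %*% W - Y)^2) + lambda * sum(W^2)
}

#' @export
print.mi_ridge <- function(x, ...) {
  cat(sprintf("<mi_ridge> %d x %d weights, lambda = %g, loss = %.6g (%s)\n",
              nrow(x$W), ncol(x$W), x$lambda, x$loss, x$method))
  invisible(x)
}

# Pick lambda by k-fold cross-validated squared error on a log grid.
select_ridge_lambda <- function(X, y, grid = 10^seq(-3, 3), k = 5L,
                                seed = 1L) {
  Y <- ridge_targets(y, nrow(X))
  n <- nrow(X)
  k <- min(k, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  errs <- vapply(grid, function(lam) {
    e <- 0
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- ridge_refine(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], lam)
      e <- e + sum((X[!tr, , drop = FALSE] %*% fit$W -
                      Y[!tr, , drop = FALSE])^2)
    }
    e
  }, numeric(1))
  grid[which.min(errs)]
}
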