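# Feed-forward classifier: dense 64 -> dropout 0.5 -> dense 64 ->
# dropout 0.5 -> dense 100 -> softmax(2), trained with Adam on categorical
# cross-entropy. Written in base R matrix operations.

#' Feed-forward network specification
#'
#' Three ReLU hidden layers (64, 64, 100 units by default) with dropout 0.5
#' after the first two, and a 2-unit softmax output. With the defaults the
#' trainable parameter count is `64 * input_dim + 10926`; a 54-dimensional
#' input gives 14,382 parameters. Dropout layers contribute no parameters.
#'
#' @param input_dim feature dimension (>= 1).
#' @param hidden hidden-layer sizes.
#' @param dropout dropout rate applied after the first two hidden layers.
#' @param n_classes output classes (softmax width).
#' @return Object of class `mlp_spec` with an `n_params` field.
#' @examples
#' mlp_spec(54)$n_params  # 14382
#' @export
mlp_spec <- function(input_dim, hidden = c(64, 64, 100), dropout = 0.5,
                     n_classes = 2) {
  assert_scalar_number(input_dim, "input_dim")
  if (input_dim < 1) validation_error("input_dim must be >= 1")
  sizes <- c(as.integer(input_dim), as.integer(hidden), as.integer(n_classes))
  n_params <- sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), dropout = dropout,
                 n_classes = as.integer(n_classes), sizes = sizes,
                 n_params = n_params),
            class = "mlp_spec")
}

#' @export
print.mlp_spec <- function(x, ...) {
  cat(sprintf("<mlp_spec> %s (dropout %.2f), %d trainable parameters\n",
              paste(x$sizes, collapse = "-"), x$dropout, x$n_params))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs training epochs (default 100).
#' @param batch_size mini-batch size (default 32; 64 and 128 are the other
#'   commonly benchmarked settings).
#' @param lr,beta1,beta2,eps Adam optimizer constants.
#' @param seed integer seed; training is deterministic given the seed.
#' @param standardize z-score features using statistics of the training data
#'   (default `TRUE`).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, batch_size = 32, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1,
                         standardize = TRUE) {
  assert_scalar_number(epochs, "epochs", positive = TRUE)
  assert_scalar_number(batch_size, "batch_size", positive = TRUE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

#' Train a classifier from a specification
#'
#' Generic dispatching on the architecture specification: [mlp_spec()] trains
#' the feed-forward network, [rnn_spec()] the LSTM comparator. Both use Adam
#' on categorical cross-entropy and are deterministic given `config$seed`.
#'
#' @param spec an architecture specification.
#' @param X n x d feature matrix.
#' @param y per-sample labels in `{1, 2}` (or a factor).
#' @param config a [train_config()].
#' @param ... unused.
#' @return A fitted model with a `predict()` method returning per-class
#'   probabilities (`type = "prob"`) or hard labels (`type = "class"`).
#' @export
train_classifier <- function(spec, X, y, config = train_config(), ...) {
  UseMethod("train_classifier")
}

prepare_labels <- function(y, n) {
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (length(y) != n) validation_error("length(y) must match nrow(X)")
  if (!all(y %in% c(1L, 2L)) || length(unique(y)) < 2L)
    validation_error("y must contain both classes 1 and 2")
  y
}

fit_scaler <- function(X, enabled) {
  if (!enabled) return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_step <- function(state, grads, cfg, t) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    mhat <- state$m[[nm]] / (1 - cfg$beta1^t)
    vhat <- state$v[[nm]] / (1 - cfg$beta2^t)
    state$par[[nm]] <- state$par[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
  }
  state
}

mlp_init <- function(spec) {
  sizes <- spec$sizes
  par <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    par[[paste0("W", l)]] <- matrix(
      rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
      sizes[l], sizes[l + 1L])
    par[[paste0("b", l)]] <- rep(0, sizes[l + 1L])
  }
  par
}

# Forward pass; when training, applies inverted dropout after hidden layers
# flagged in spec$dropout_after.
mlp_forward <- function(par, X, spec, dropout = FALSE) {
  n_layers <- length(spec$sizes) - 1L
  acts <- list(X)
  masks <- vector("list", n_layers)
  H <- X
  for (l in seq_len(n_layers)) {
    Z <- sweep(H %*% par[[paste0("W", l)]], 2L, par[[paste0("b", l)]], "+")
    if (l < n_layers) {
      H <- pmax(Z, 0)
      if (dropout && l <= 2L && spec$dropout > 0) {
        keep <- matrix(runif(length(H)) > spec$dropout, nrow(H), ncol(H))
        H <- H * keep / (1 - spec$dropout)
        masks[[l]] <- keep
      }
    } else {
      H <- softmax_rows(Z)
    }
    acts[[l + 1L]] <- H
  }
  list(probs = H, acts = acts, masks = masks)
}

mlp_backward <- function(par, fwd, Yhot, spec) {
  n_layers <- length(spec$sizes) - 1L
  n <- nrow(Yhot)
  grads <- list()
  delta <- (fwd$probs - Yhot) / n           # d loss / d logits (softmax + CE)
  for (l in rev(seq_len(n_layers))) {
    H_prev <- fwd$acts[[l]]
    grads[[paste0("W", l)]] <- crossprod(H_prev, delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(par[[paste0("W", l)]])
      if (!is.null(fwd$masks[[l - 1L]]))
        delta <- delta * fwd$masks[[l - 1L]] / (1 - spec$dropout)
      delta <- delta * (fwd$acts[[l]] > 0)
    }
  }
  grads
}

#' @rdname train_classifier
#' @export
train_classifier.mlp_spec <- function(spec, X, y, config = train_config(),
                                      ...) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) != spec$input_dim)
    validation_error("X has ", ncol(X), " features but the spec expects ",
                     spec$input_dim)
  y <- prepare_labels(y, nrow(X))
  scaler <- fit_scaler(X, config$standardize)
  Xs <- apply_scaler(X, scaler)
  Yhot <- diag(spec$n_classes)[y, , drop = FALSE]
  n <- nrow(Xs)
  model <- with_seed(config$seed, {
    par <- mlp_init(spec)
    state <- list(par = par,
                  m = lapply(par, function(p) p * 0),
                  v = lapply(par, function(p) p * 0))
    t_step <- 0L
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[seq.int(start, min(start + config$batch_size - 1L, n))]
        fwd <- mlp_forward(state$par, Xs[idx, , drop = FALSE], spec,
                           dropout = TRUE)
        loss <- -mean(log(rowSums(fwd$probs * Yhot[idx, , drop = FALSE]) +
                            1e-12))
        if (!is.finite(loss))
          stop_mieeg("training diverged (non-finite loss) at epoch ", ep,
                     "; inspect feature scaling and learning rate",
                     class = "mieeg_training_error")
        ep_loss <- ep_loss + loss * length(idx)
        grads <- mlp_backward(state$par, fwd,
                              Yhot[idx, , drop = FALSE], spec)
        t_step <- t_step + 1L
        state <- adam_step(state, grads, config, t_step)
      }
      losses[ep] <- ep_loss / n
    }
    list(par = state$par, losses = losses)
  })
  structure(list(spec = spec, par = model$par, scaler = scaler,
                 config = config, losses = model$losses),
            class = "mi_mlp")
}

#' @export
predict.mi_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  Xs <- apply_scaler(newdata, object$scaler)
  probs <- mlp_forward(object$par, Xs, object$spec, dropout = FALSE)$probs
  colnames(probs) <- paste0("class", seq_len(ncol(probs)))
  if (type == "prob") probs else max.col(probs)
}

#' @export
print.mi_mlp <- function(x, ...) {
  cat(sprintf("<mi_mlp> %s, %d parameters, final training loss %.4f\n",
              paste(x$spec$sizes, collapse = "-"), x$spec$n_params,
              tail(x$losses, 1L)))
  invisible(x)
}
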