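# Recurrent comparator: single LSTM layer (16 units) -> dense 32 (ReLU) ->
# dropout 0.5 -> softmax(2), trained with Adam via backpropagation through
# time. Feature vectors are presented as sequences of `step_dim`-dimensional
# steps; the parameter count is independent of the sequence length.

#' Recurrent network specification
#'
#' One LSTM layer followed by a ReLU dense layer, dropout, and a softmax
#' output. For per-step input dimension `d` and `u` LSTM units the trainable
#' parameter count is `4 * ((d + u) * u + u)` for the LSTM plus
#' `u * dense + dense` and `dense * n_classes + n_classes` for the head —
#' independent of sequence length.
#'
#' @param input_dim total feature dimension of one sample; must be divisible
#'   by `step_dim`. The sample is presented as `input_dim / step_dim` steps.
#' @param step_dim per-step input dimension (default 1).
#' @param lstm_units LSTM state size (default 16).
#' @param dense_units dense-layer width (default 32).
#' @param dropout dropout rate before the output layer (default 0.5).
#' @param n_classes output classes.
#' @return Object of class `rnn_spec` with an `n_params` field.
#' @examples
#' rnn_spec(10)$n_params  # 4*((1+16)*16+16) + (16*32+32) + (32*2+2)
#' @export
rnn_spec <- function(input_dim, step_dim = 1, lstm_units = 16,
                     dense_units = 32, dropout = 0.5, n_classes = 2) {
  assert_scalar_number(input_dim, "input_dim")
  if (input_dim < 1) validation_error("input_dim must be >= 1")
  if (input_dim %% step_dim != 0)
    validation_error("input_dim (", input_dim, ") is not divisible by ",
                     "step_dim (", step_dim, "): cannot form a sequence")
  u <- as.integer(lstm_units); d <- as.integer(step_dim)
  dn <- as.integer(dense_units); k <- as.integer(n_classes)
  n_params <- 4L * ((d + u) * u + u) + (u * dn + dn) + (dn * k + k)
  structure(list(input_dim = as.integer(input_dim), step_dim = d,
                 seq_len = as.integer(input_dim / step_dim), lstm_units = u,
                 dense_units = dn, dropout = dropout, n_classes = k,
                 n_params = n_params),
            class = "rnn_spec")
}

#' @export
print.rnn_spec <- function(x, ...) {
  cat(sprintf(
    "<rnn_spec> LSTM(%d) over %d x %d steps -> dense(%d) -> softmax(%d); %d parameters\n",
    x$lstm_units, x$seq_len, x$step_dim, x$dense_units, x$n_classes,
    x$n_params))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

rnn_init <- function(spec) {
  d <- spec$step_dim; u <- spec$lstm_units
  g <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)
  list(Wx = g(d, 4L * u), Wh = g(u, 4L * u), b = rep(0, 4L * u),
       Wd = g(u, spec$dense_units), bd = rep(0, spec$dense_units),
       Wo = g(spec$dense_units, spec$n_classes), bo = rep(0, spec$n_classes))
}

# Gate slices of the 4u-wide pre-activation: input, forget, candidate, output.
gate_idx <- function(u) {
  list(i = 1:u, f = (u + 1):(2 * u), g = (2 * u + 1):(3 * u),
       o = (3 * u + 1):(4 * u))
}

rnn_forward <- function(par, Xseq, spec, dropout = FALSE) {
  n <- dim(Xseq)[1L]; T_ <- dim(Xseq)[2L]
  u <- spec$lstm_units
  gi <- gate_idx(u)
  H <- matrix(0, n, u); C <- matrix(0, n, u)
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    Xt <- matrix(Xseq[, t, ], n, spec$step_dim)
    Z <- sweep(Xt %*% par$Wx + H %*% par$Wh, 2L, par$b, "+")
    ig <- sigmoid(Z[, gi$i, drop = FALSE])
    fg <- sigmoid(Z[, gi$f, drop = FALSE])
    gg <- tanh(Z[, gi$g, drop = FALSE])
    og <- sigmoid(Z[, gi$o, drop = FALSE])
    C_new <- fg * C + ig * gg
    tc <- tanh(C_new)
    H_new <- og * tc
    cache[[t]] <- list(Xt = Xt, H_prev = H, C_prev = C, i = ig, f = fg,
                       g = gg, o = og, tc = tc)
    H <- H_new; C <- C_new
  }
  D_pre <- sweep(H %*% par$Wd, 2L, par$bd, "+")
  D <- pmax(D_pre, 0)
  mask <- NULL
  Dd <- D
  if (dropout && spec$dropout > 0) {
    mask <- matrix(runif(length(D)) > spec$dropout, nrow(D), ncol(D))
    Dd <- D * mask / (1 - spec$dropout)
  }
  logits <- sweep(Dd %*% par$Wo, 2L, par$bo, "+")
  list(probs = softmax_rows(logits), H = H, D = D, Dd = Dd, mask = mask,
       cache = cache)
}

rnn_backward <- function(par, fwd, Yhot, spec) {
  n <- nrow(Yhot); u <- spec$lstm_units
  gi <- gate_idx(u)
  delta <- (fwd$probs - Yhot) / n
  gWo <- crossprod(fwd$Dd, delta)
  gbo <- colSums(delta)
  dDd <- delta %*% t(par$Wo)
  if (!is.null(fwd$mask)) dDd <- dDd * fwd$mask / (1 - spec$dropout)
  dD <- dDd * (fwd$D > 0)
  gWd <- crossprod(fwd$H, dD)
  gbd <- colSums(dD)
  dH <- dD %*% t(par$Wd)
  dC <- matrix(0, n, u)
  gWx <- par$Wx * 0; gWh <- par$Wh * 0; gb <- par$b * 0
  for (t in rev(seq_along(fwd$cache))) {
    cc <- fwd$cache[[t]]
    do_ <- dH * cc$tc
    dC <- dC + dH * cc$o * (1 - cc$tc^2)
    di <- dC * cc$g
    df <- dC * cc$C_prev
    dg <- dC * cc$i
    dZ <- matrix(0, n, 4L * u)
    dZ[, gi$i] <- di * cc$i * (1 - cc$i)
    dZ[, gi$f] <- df * cc$f * (1 - cc$f)
    dZ[, gi$g] <- dg * (1 - cc$g^2)
    dZ[, gi$o] <- do_ * cc$o * (1 - cc$o)
    gWx <- gWx + crossprod(cc$Xt, dZ)
    gWh <- gWh + crossprod(cc$H_prev, dZ)
    gb <- gb + colSums(dZ)
    dH <- dZ %*% t(par$Wh)
    dC <- dC * cc$f
  }
  list(Wx = gWx, Wh = gWh, b = gb, Wd = gWd, bd = gbd, Wo = gWo, bo = gbo)
}

as_sequences <- function(X, spec) {
  n <- nrow(X)
  array(X, dim = c(n, spec$seq_len, spec$step_dim))
}

#' @rdname train_classifier
#' @export
train_classifier.rnn_spec <- function(spec, X, y, config = train_config(),
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
    par <- rnn_init(spec)
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
        Xb <- as_sequences(Xs[idx, , drop = FALSE], spec)
        fwd <- rnn_forward(state$par, Xb, spec, dropout = TRUE)
        loss <- -mean(log(rowSums(fwd$probs * Yhot[idx, , drop = FALSE]) +
                            1e-12))
        if (!is.finite(loss))
          stop_mieeg("training diverged (non-finite loss) at epoch ", ep,
                     class = "mieeg_training_error")
        ep_loss <- ep_loss + loss * length(idx)
        grads <- rnn_backward(state$par, fwd, Yhot[idx, , drop = FALSE], spec)
        t_step <- t_step + 1L
        state <- adam_step(state, grads, config, t_step)
      }
      losses[ep] <- ep_loss / n
    }
    list(par = state$par, losses = losses)
  })
  structure(list(spec = spec, par = model$par, scaler = scaler,
                 config = config, losses = model$losses),
            class = "mi_lstm")
}

#' @export
predict.mi_lstm <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  Xs <- apply_scaler(newdata, object$scaler)
  probs <- rnn_forward(object$par, as_sequences(Xs, object$spec),
                       object$spec, dropout = FALSE)$probs
  colnames(probs) <- paste0("class", seq_len(ncol(probs)))
  if (type == "prob") probs else max.col(probs)
}

#' @export
print.mi_lstm <- function(x, ...) {
  cat(sprintf("<mi_lstm> LSTM(%d), %d parameters, final training loss %.4f\n",
              x$spec$lstm_units, x$spec$n_params, tail(x$losses, 1L)))
  invisible(x)
}
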