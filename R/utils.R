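# Internal helpers shared across modules.

stop_mieeg <- function(..., class = "mieeg_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

validation_error <- function(...) stop_mieeg(..., class = "mieeg_validation_error")
format_error <- function(...) stop_mieeg(..., class = "mieeg_format_error")

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(name, " must be a single finite number")
  if (positive && x <= 0)
    validation_error(name, " must be positive")
  invisible(x)
}

# Round-half-up (the usual "round half away from zero" for positive values);
# base round() rounds half to even, which would shift marker indices.
round_half_up <- function(x) floor(x + 0.5)

# Derive a per-stage seed from a global one; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_symmetric_matrix <- function(C, tol = 1e-8) {
  is.matrix(C) && nrow(C) == ncol(C) &&
    max(abs(C - t(C))) <= tol * max(1, max(abs(C)))
}
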