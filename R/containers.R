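#' Continuous multichannel EEG recording
#'
#' An `eeg_recording` holds a continuous multichannel signal together with its
#' sampling rate, channel labels and trial markers. Signals are stored as a
#' channels x time matrix in microvolts. Marker positions are 1-based sample
#' indices into the signal; marker labels are the two motor-imagery classes,
#' normalized to integers 1 and 2 (original label values, when not already
#' 1/2, are kept in the `label_map` attribute of the markers data frame).
#'
#' @param signal numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of unique channel labels; defaults to
#'   `Ch1..ChN`.
#' @param markers data frame with columns `sample` (1-based index into the
#'   signal) and `label` (class, in `{1, 2}`), or `NULL` for none.
#' @param subject_id free-text subject identifier.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(400), 2), fs = 100)
#' print(rec)
#' @export
eeg_recording <- function(signal, fs, channel_names = NULL, markers = NULL,
                          subject_id = "unknown") {
  if (!is.matrix(signal) || !is.numeric(signal))
    validation_error("signal must be a numeric channels x time matrix")
  if (nrow(signal) < 1L || ncol(signal) < 1L)
    validation_error("signal needs at least one channel and one sample")
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (is.null(channel_names))
    channel_names <- paste0("Ch", seq_len(nrow(signal)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(signal))
    validation_error("channel_names length (", length(channel_names),
                     ") must equal the channel count (", nrow(signal), ")")
  if (anyDuplicated(channel_names))
    validation_error("channel_names must be unique")
  if (is.null(markers)) {
    markers <- data.frame(sample = integer(0), label = integer(0))
  } else {
    if (!is.data.frame(markers) || !all(c("sample", "label") %in% names(markers)))
      validation_error("markers must be a data frame with columns sample, label")
    markers <- data.frame(sample = as.integer(markers$sample),
                          label = as.integer(markers$label))
    if (any(markers$sample < 1L) || any(markers$sample > ncol(signal)))
      validation_error("marker sample indices must lie inside the recording")
    if (nrow(markers) && !all(markers$label %in% c(1L, 2L)))
      validation_error("marker labels must be 1 or 2 after normalization")
  }
  structure(
    list(signal = signal, fs = as.numeric(fs), channel_names = channel_names,
         markers = markers, subject_id = as.character(subject_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject:", x$subject_id, "\n")
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, nrow(x$markers)))
  invisible(x)
}

#' Epoched two-class EEG trials
#'
#' An `eeg_epochs` object holds marker-aligned trials as a
#' trials x channels x samples array with one class label in `{1, 2}` per
#' trial. All pipeline stages after epoching operate on this container.
#'
#' @param data numeric array, trials x channels x samples, microvolts.
#' @param labels integer vector of per-trial class labels in `{1, 2}`.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of unique channel labels.
#' @return An object of class `eeg_epochs`.
#' @examples
#' ep <- eeg_epochs(array(rnorm(5 * 2 * 50), c(5, 2, 50)),
#'                  labels = c(1, 2, 1, 2, 1), fs = 100)
#' n_trials(ep)
#' @export
eeg_epochs <- function(data, labels, fs, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    validation_error("data must be a trials x channels x samples array")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1L])
    validation_error("labels length (", length(labels),
                     ") must equal the trial count (", dim(data)[1L], ")")
  if (!all(labels %in% c(1L, 2L)))
    validation_error("labels must take values in {1, 2}")
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (is.null(channel_names))
    channel_names <- paste0("Ch", seq_len(dim(data)[2L]))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[2L])
    validation_error("channel_names length must equal the channel count")
  if (anyDuplicated(channel_names))
    validation_error("channel_names must be unique")
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = channel_names),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  tab <- table(factor(x$labels, levels = c(1, 2)))
  cat(sprintf("  class 1: %d trials, class 2: %d trials\n", tab[[1L]], tab[[2L]]))
  invisible(x)
}

#' @rdname eeg_epochs
#' @param x an `eeg_epochs` object.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' @rdname eeg_epochs
#' @export
n_channels <- function(x) {
  if (inherits(x, "eeg_recording")) nrow(x$signal) else dim(x$data)[2L]
}

#' Restrict epochs to a subset of channels
#'
#' @param x an `eeg_epochs` object.
#' @param channels integer indices or channel names to keep (order preserved
#'   as given).
#' @return An `eeg_epochs` object with the selected channels.
#' @export
subset_channels <- function(x, channels) {
  if (!inherits(x, "eeg_epochs"))
    validation_error("x must be an eeg_epochs object")
  if (is.character(channels))
    channels <- match(channels, x$channel_names)
  channels <- as.integer(channels)
  if (length(channels) < 1L || anyNA(channels) ||
      any(channels < 1L) || any(channels > n_channels(x)))
    validation_error("invalid channel selection")
  eeg_epochs(x$data[, channels, , drop = FALSE], x$labels, x$fs,
             x$channel_names[channels])
}

# Extract one trial as a channels x samples matrix.
trial_matrix <- function(x, i) {
  m <- x$data[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(x$data)[2L])
  m
}
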