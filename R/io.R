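# Recording and epoch container I/O: format dispatch, the BCI Competition MAT
# layout, and the internal lossless container (compressed R serialization).

#' Read a continuous EEG recording
#'
#' Dispatches on file extension (or an explicit `format`):
#' * `mat` — the BCI Competition continuous-EEG layout: `cnt` (time x
#'   channels; transposed to channels x time in memory), `mrk` struct with
#'   `pos`/`y`, `nfo` struct with `fs`/`clab`. Signals stored as 16-bit
#'   integers are scaled by 0.1 to microvolts, following the competition
#'   convention. Unlabeled (NaN) markers are dropped with a message; marker
#'   class values are normalized to `{1, 2}`.
#' * `edf` — see [read_edf()].
#' * `rds` — the internal container written by [write_recording()].
#'
#' @param path input file.
#' @param format one of `"auto"`, `"mat"`, `"edf"`, `"rds"`.
#' @return An [eeg_recording()].
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 2), fs = 100,
#'                      markers = data.frame(sample = c(10, 60),
#'                                           label = c(1, 2)))
#' p <- tempfile(fileext = ".mat")
#' write_recording(rec, p)
#' rec2 <- read_recording(p)
#' stopifnot(all.equal(rec$signal, rec2$signal))
#' @export
read_recording <- function(path, format = c("auto", "mat", "edf", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mat = "mat", edf = "edf", rds = "rds",
                     stop_mieeg("cannot dispatch on extension '.", ext,
                                "'; pass format= explicitly",
                                class = "mieeg_dispatch_error"))
  }
  switch(format,
         mat = read_bci_mat(path),
         edf = read_edf(path),
         rds = read_recording_rds(path))
}

#' Write a continuous EEG recording
#'
#' The `mat` and `rds` writers are lossless for double-precision signals;
#' `edf` quantizes to 16 bits. Files written here are re-readable by
#' [read_recording()].
#'
#' @param rec an [eeg_recording()].
#' @param path output file; extension picks the format unless `format` is
#'   given.
#' @param format one of `"auto"`, `"mat"`, `"edf"`, `"rds"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "mat", "edf", "rds")) {
  if (!inherits(rec, "eeg_recording"))
    validation_error("rec must be an eeg_recording")
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mat = "mat", edf = "edf", rds = "rds",
                     stop_mieeg("cannot dispatch on extension '.", ext,
                                "'; pass format= explicitly",
                                class = "mieeg_dispatch_error"))
  }
  switch(format,
         mat = write_bci_mat(rec, path),
         edf = write_edf(rec, path),
         rds = write_recording_rds(rec, path))
}

read_recording_rds <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$container, "mieeg_recording"))
    format_error(path, " is not an mieeg recording container")
  eeg_recording(obj$signal, obj$fs, obj$channel_names, obj$markers,
                obj$subject_id)
}

write_recording_rds <- function(rec, path) {
  saveRDS(list(container = "mieeg_recording", schema = 1L,
               signal = rec$signal, fs = rec$fs,
               channel_names = rec$channel_names, markers = rec$markers,
               subject_id = rec$subject_id),
          path, compress = "gzip")
  invisible(path)
}

# BCI Competition MAT layout <-> eeg_recording.

read_bci_mat <- function(path) {
  vars <- read_mat5(path)
  for (field in c("cnt", "mrk", "nfo")) {
    if (is.null(vars[[field]]))
      format_error("MAT container is missing required field '", field, "'")
  }
  cnt <- vars$cnt
  if (!is.numeric(cnt) || is.null(dim(cnt)))
    format_error("'cnt' must be a numeric time x channels matrix")
  mat_class <- attr(vars$cnt, "mat_class")
  attr(cnt, "mat_class") <- NULL
  if (!is.null(mat_class) && mat_class %in% c(MX_INT16, MX_UINT16)) {
    # competition files store cnt as int16 in 0.1 uV units
    cnt <- 0.1 * cnt
    message("scaled int16 'cnt' by 0.1 to microvolts")
  }
  mrk <- vars$mrk
  if (is.null(mrk$pos) || is.null(mrk$y))
    format_error("MAT container 'mrk' struct is missing 'pos' or 'y'")
  pos <- as.numeric(mrk$pos)
  y <- as.numeric(mrk$y)
  keep <- is.finite(y)
  if (any(!keep))
    message("dropped ", sum(!keep), " unlabeled (NaN) marker(s)")
  pos <- pos[keep]; y <- y[keep]
  classes <- sort(unique(y))
  if (length(classes) > 2L)
    format_error("more than two marker classes present")
  lab <- match(y, classes)
  nfo <- vars$nfo
  if (is.null(nfo$fs))
    format_error("MAT container 'nfo' struct is missing 'fs'")
  clab <- nfo$clab
  names_vec <- if (is.null(clab)) NULL else
    vapply(clab, function(x) as.character(x)[1L], character(1))
  markers <- if (length(pos)) data.frame(sample = pos, label = lab) else NULL
  rec <- eeg_recording(t(cnt), fs = as.numeric(nfo$fs)[1L],
                       channel_names = names_vec, markers = markers,
                       subject_id = if (is.null(vars$subject))
                         "unknown" else as.character(vars$subject))
  if (length(classes) && !identical(as.numeric(classes), c(1, 2)))
    attr(rec$markers, "label_map") <- classes
  rec
}

write_bci_mat <- function(rec, path) {
  vars <- list(
    cnt = t(rec$signal),                       # stored time x channels on disk
    mrk = list(pos = as.numeric(rec$markers$sample),
               y = as.numeric(rec$markers$label)),
    nfo = list(fs = rec$fs,
               clab = as.list(rec$channel_names)),
    subject = rec$subject_id)
  write_mat5(vars, path)
  invisible(path)
}

#' Read and write epoched datasets
#'
#' The internal epoch container is a compressed R serialization holding the
#' trials x channels x samples tensor, labels, sampling rate and channel
#' names; the round-trip is lossless.
#'
#' @param x an [eeg_epochs()] object.
#' @param path file path (conventionally `.rds`).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` returns
#'   an [eeg_epochs()].
#' @export
write_epochs <- function(x, path) {
  if (!inherits(x, "eeg_epochs"))
    validation_error("x must be an eeg_epochs object")
  saveRDS(list(container = "mieeg_epochs", schema = 1L, data = x$data,
               labels = x$labels, fs = x$fs, channel_names = x$channel_names),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$container, "mieeg_epochs"))
    format_error(path, " is not an mieeg epochs container")
  eeg_epochs(obj$data, obj$labels, obj$fs, obj$channel_names)
}
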