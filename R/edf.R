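# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores 16-bit samples with per-channel linear scaling between a digital
# and a physical range, in fixed-duration data records. Plain EDF has no
# annotation track, so trial markers are carried in a dedicated status channel
# (label "MI_STATUS") that holds the class label at each marker onset sample
# and zero elsewhere; the reader converts it back into a marker table. The
# true sample count is recorded in the reserved header field ("NSAMP=...") so
# that zero-padding of the final data record can be trimmed on re-read.

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

edf_num <- function(x, width) {
  s <- formatC(x, width = width, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(trimws(s), width)
}

STATUS_CHANNEL <- "MI_STATUS"

#' Write a recording to an EDF file
#'
#' Samples are quantized to the 16-bit EDF digital range per channel, so the
#' round-trip is lossy at roughly `range/65534` resolution. Markers are stored
#' in an appended `MI_STATUS` channel (see [read_edf()]).
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  if (!inherits(rec, "eeg_recording"))
    validation_error("rec must be an eeg_recording")
  if (abs(rec$fs - round(rec$fs)) > 1e-9)
    validation_error("EDF export requires an integer sampling rate")
  fs <- as.integer(round(rec$fs))
  sig <- rec$signal
  n <- ncol(sig)
  status <- numeric(n)
  if (nrow(rec$markers))
    status[rec$markers$sample] <- rec$markers$label
  sig <- rbind(sig, status)
  labels <- c(rec$channel_names, STATUS_CHANNEL)
  ns <- nrow(sig)
  n_rec <- as.integer(ceiling(n / fs))
  pmin_ <- apply(sig, 1L, min)
  pmax_ <- apply(sig, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32767; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$subject_id, 80))
  wr(edf_pad("mieeg recording", 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256L + 256L * ns, 8))
  wr(edf_pad(sprintf("NSAMP=%d", n), 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))
  for (lab in labels) wr(edf_pad(lab, 16))
  wr(strrep(" ", 80 * ns))                       # transducer
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(edf_num(pmin_[i], 8))
  for (i in seq_len(ns)) wr(edf_num(pmax_[i], 8))
  for (i in seq_len(ns)) wr(edf_pad(dmin, 8))
  for (i in seq_len(ns)) wr(edf_pad(dmax, 8))
  wr(strrep(" ", 80 * ns))                       # prefiltering
  for (i in seq_len(ns)) wr(edf_pad(fs, 8))
  wr(strrep(" ", 32 * ns))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  padded <- cbind(sig, matrix(0, ns, n_rec * fs - n))
  for (r in seq_len(n_rec)) {
    idx <- seq.int((r - 1L) * fs + 1L, r * fs)
    for (i in seq_len(ns)) {
      dig <- round((padded[i, idx] - pmin_[i]) * scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' All signals must share one sampling rate. If an `MI_STATUS` channel is
#' present (as written by [write_edf()]) it is converted back into the marker
#' table and removed from the signal matrix.
#'
#' @param path path to an `.edf` file.
#' @param subject_id subject identifier; defaults to the EDF patient field.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL) {
  if (!file.exists(path)) format_error("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  version <- trimws(rd(8))
  if (version != "0") format_error(path, " is not an EDF file")
  patient <- trimws(rd(80)); rd(80); rd(8); rd(8)
  rd(8)                                         # header bytes
  reserved <- trimws(rd(44))
  n_rec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  labels <- vapply(seq_len(ns), function(i) trimws(rd(16)), character(1))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(trimws(rd(8))), 1)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(trimws(rd(8))), 1)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(trimws(rd(8))), 1)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(trimws(rd(8))), 1)
  rd(80 * ns)
  spr <- vapply(seq_len(ns), function(i) as.integer(trimws(rd(8))), 1L)
  rd(32 * ns)
  if (length(unique(spr)) != 1L)
    format_error("mixed per-channel sampling rates are not supported")
  fs <- spr[1L] / dur
  sig <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin_[i] + (dig - dmin[i]) * (pmax_[i] - pmin_[i]) /
        (dmax[i] - dmin[i])
      sig[i, seq.int((r - 1L) * spr[i] + 1L, r * spr[i])] <- phys
    }
  }
  m <- regmatches(reserved, regexec("NSAMP=([0-9]+)", reserved))[[1L]]
  if (length(m) == 2L) {
    n_true <- as.integer(m[2L])
    if (n_true <= ncol(sig)) sig <- sig[, seq_len(n_true), drop = FALSE]
  }
  markers <- NULL
  st <- which(labels == STATUS_CHANNEL)
  if (length(st) == 1L) {
    status <- round(sig[st, ])
    pos <- which(status > 0.5)
    markers <- data.frame(sample = pos, label = as.integer(status[pos]))
    sig <- sig[-st, , drop = FALSE]
    labels <- labels[-st]
  }
  eeg_recording(sig, fs = fs, channel_names = labels, markers = markers,
                subject_id = if (is.null(subject_id)) patient else subject_id)
}
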