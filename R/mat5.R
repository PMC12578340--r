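# Minimal MAT-file (level 5) reader/writer.
#
# Scope: what the BCI Competition continuous-EEG containers need — numeric
# arrays, character arrays, cell arrays of strings, and (1x1) structs, in the
# uncompressed or zlib-compressed level-5 dialect. MAT v7.3 files are HDF5
# containers and are rejected with a clear error. The writer always emits
# uncompressed level-5 elements with double-precision data.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L; MI_UTF16 <- 17L
MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L
MX_SINGLE <- 7L; MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L
MX_UINT16 <- 11L; MX_INT32 <- 12L; MX_UINT32 <- 13L

# ---- writing ----------------------------------------------------------------

mat5_pad8 <- function(r) {
  p <- (8L - length(r) %% 8L) %% 8L
  if (p) c(r, raw(p)) else r
}

mat5_raw_int <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

mat5_subelement <- function(type, payload) {
  mat5_pad8(c(mat5_raw_int(type, 4L), mat5_raw_int(length(payload), 4L), payload))
}

mat5_flags <- function(mx_class) {
  mat5_subelement(MI_UINT32, c(mat5_raw_int(mx_class, 4L), raw(4)))
}

mat5_dims <- function(dims) {
  mat5_subelement(MI_INT32, mat5_raw_int(dims, 4L))
}

mat5_name <- function(name) {
  mat5_subelement(MI_INT8, if (nzchar(name)) charToRaw(name) else raw(0))
}

# Body of a miMATRIX element for one R object (column-major numeric array,
# single string, unnamed list -> cell, named list -> 1x1 struct).
mat5_matrix_body <- function(x, name) {
  if (is.character(x) && length(x) == 1L) {
    codes <- utf8ToInt(x)
    body <- c(mat5_flags(MX_CHAR), mat5_dims(c(1L, length(codes))),
              mat5_name(name),
              mat5_subelement(MI_UINT16, mat5_raw_int(codes, 2L)))
  } else if (is.numeric(x) || is.logical(x)) {
    dims <- if (is.null(dim(x))) c(1L, length(x)) else dim(x)
    body <- c(mat5_flags(MX_DOUBLE), mat5_dims(dims), mat5_name(name),
              mat5_subelement(MI_DOUBLE,
                              writeBin(as.numeric(x), raw(), size = 8L,
                                       endian = "little")))
  } else if (is.list(x) && is.null(names(x))) {
    cells <- lapply(x, mat5_element, name = "")
    body <- c(mat5_flags(MX_CELL), mat5_dims(c(1L, length(x))),
              mat5_name(name), do.call(c, c(cells, list(raw(0)))))
  } else if (is.list(x)) {
    fields <- names(x)
    if (any(nchar(fields) > 31L))
      format_error("struct field names are limited to 31 characters")
    name_bytes <- do.call(c, lapply(fields, function(f) {
      r <- raw(32); b <- charToRaw(f); r[seq_along(b)] <- b; r
    }))
    members <- lapply(x, mat5_element, name = "")
    body <- c(mat5_flags(MX_STRUCT), mat5_dims(c(1L, 1L)), mat5_name(name),
              mat5_subelement(MI_INT32, mat5_raw_int(32L, 4L)),
              mat5_subelement(MI_INT8, name_bytes),
              do.call(c, c(members, list(raw(0)))))
  } else {
    format_error("cannot encode objects of class ", class(x)[1L],
                 " in a MAT container")
  }
  body
}

mat5_element <- function(x, name) {
  body <- mat5_matrix_body(x, name)
  c(mat5_raw_int(MI_MATRIX, 4L), mat5_raw_int(length(body), 4L), body)
}

#' Write variables to a level-5 MAT container
#'
#' @param vars named list of variables. Numeric vectors/matrices, single
#'   strings, unnamed lists (written as cell arrays) and named lists (written
#'   as 1x1 structs) are supported.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_mat5()], [write_recording()]
#' @export
write_mat5 <- function(vars, path) {
  if (!is.list(vars) || is.null(names(vars)) || any(!nzchar(names(vars))))
    validation_error("vars must be a fully named list")
  desc <- sprintf("MATLAB 5.0 MAT-file, written by mieeg %s",
                  as.character(utils::packageVersion("mieeg")))
  header <- raw(116)
  db <- charToRaw(desc)
  header[seq_len(min(116L, length(db)))] <- db[seq_len(min(116L, length(db)))]
  header[header == as.raw(0)] <- charToRaw(" ")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(raw(8), con)                               # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                # version 0x0100
  writeBin(charToRaw("IM"), con)                      # little-endian marker
  for (nm in names(vars))
    writeBin(mat5_element(vars[[nm]], nm), con)
  invisible(path)
}

# ---- reading ----------------------------------------------------------------

mat5_cursor <- function(bytes, pos = 1L) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- pos
  env
}

cur_left <- function(cur) length(cur$bytes) - cur$pos + 1L

cur_take <- function(cur, n) {
  if (n > cur_left(cur)) format_error("truncated MAT element")
  out <- cur$bytes[seq.int(cur$pos, length.out = n)]
  cur$pos <- cur$pos + n
  out
}

cur_int <- function(cur, size, n = 1L, signed = TRUE) {
  readBin(cur_take(cur, size * n), "integer", n = n, size = size,
          signed = signed, endian = "little")
}

mat5_read_tag <- function(cur) {
  first <- cur_int(cur, 4L)
  small_len <- bitwAnd(bitwShiftR(first, 16L), 0xffffL)
  if (small_len != 0L) {
    list(type = bitwAnd(first, 0xffffL), nbytes = small_len, small = TRUE)
  } else {
    list(type = first, nbytes = cur_int(cur, 4L), small = FALSE)
  }
}

mat5_decode_numeric <- function(bytes, type) {
  switch(as.character(type),
    "1" = as.numeric(readBin(bytes, "integer", length(bytes), 1L, TRUE)),
    "2" = as.numeric(readBin(bytes, "integer", length(bytes), 1L, FALSE)),
    "3" = as.numeric(readBin(bytes, "integer", length(bytes) / 2L, 2L, TRUE,
                             endian = "little")),
    "4" = as.numeric(readBin(bytes, "integer", length(bytes) / 2L, 2L, FALSE,
                             endian = "little")),
    "5" = as.numeric(readBin(bytes, "integer", length(bytes) / 4L, 4L, TRUE,
                             endian = "little")),
    "6" = as.numeric(readBin(bytes, "integer", length(bytes) / 4L, 4L, TRUE,
                             endian = "little")),
    "7" = readBin(bytes, "double", length(bytes) / 4L, 4L, endian = "little"),
    "9" = readBin(bytes, "double", length(bytes) / 8L, 8L, endian = "little"),
    format_error("unsupported MAT data type ", type))
}

mat5_read_subelement <- function(cur) {
  tag <- mat5_read_tag(cur)
  bytes <- cur_take(cur, tag$nbytes)
  if (tag$small) {
    cur_take(cur, 4L - tag$nbytes)           # small elements pack into 8 bytes
  } else if (tag$type != MI_COMPRESSED) {    # compressed elements are unpadded
    pad <- (8L - tag$nbytes %% 8L) %% 8L
    if (pad <= cur_left(cur)) cur_take(cur, pad)
  }
  list(type = tag$type, bytes = bytes)
}

mat5_parse_matrix <- function(bytes) {
  cur <- mat5_cursor(bytes)
  flags <- mat5_read_subelement(cur)
  flags_word <- readBin(flags$bytes[1:4], "integer", 1L, 4L, endian = "little")
  mx_class <- bitwAnd(flags_word, 0xffL)
  dims_el <- mat5_read_subelement(cur)
  dims <- readBin(dims_el$bytes, "integer", length(dims_el$bytes) / 4L, 4L,
                  endian = "little")
  name_el <- mat5_read_subelement(cur)
  name <- rawToChar(name_el$bytes)
  value <-
    if (mx_class %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8, MX_INT16,
                        MX_UINT16, MX_INT32, MX_UINT32)) {
      re <- mat5_read_subelement(cur)
      v <- mat5_decode_numeric(re$bytes, re$type)
      if (length(dims) == 2L && any(dims == 1L)) {
        v
      } else {
        array(v, dim = dims)
      }
    } else if (mx_class == MX_CHAR) {
      ce <- mat5_read_subelement(cur)
      codes <- switch(as.character(ce$type),
        "16" = utf8ToInt(rawToChar(ce$bytes)),
        "1" = as.integer(ce$bytes),
        "2" = as.integer(ce$bytes),
        "4" = readBin(ce$bytes, "integer", length(ce$bytes) / 2L, 2L, FALSE,
                      endian = "little"),
        "17" = readBin(ce$bytes, "integer", length(ce$bytes) / 2L, 2L, FALSE,
                       endian = "little"),
        format_error("unsupported MAT char encoding ", ce$type))
      intToUtf8(codes[codes > 0L])
    } else if (mx_class == MX_CELL) {
      n <- prod(dims)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        el <- mat5_read_subelement(cur)
        if (el$type != MI_MATRIX) format_error("malformed cell array")
        out[[i]] <- mat5_parse_matrix(el$bytes)$value
      }
      out
    } else if (mx_class == MX_STRUCT) {
      fl <- mat5_read_subelement(cur)
      flen <- readBin(fl$bytes, "integer", 1L, 4L, endian = "little")
      fn <- mat5_read_subelement(cur)
      nfields <- length(fn$bytes) %/% flen
      fields <- vapply(seq_len(nfields), function(i) {
        b <- fn$bytes[seq.int((i - 1L) * flen + 1L, length.out = flen)]
        rawToChar(b[b != as.raw(0)])
      }, character(1))
      n_elem <- prod(dims)
      elems <- vector("list", n_elem)
      for (e in seq_len(n_elem)) {
        vals <- vector("list", nfields)
        names(vals) <- fields
        for (f in seq_len(nfields)) {
          el <- mat5_read_subelement(cur)
          if (el$type != MI_MATRIX) format_error("malformed struct field")
          vals[[f]] <- mat5_parse_matrix(el$bytes)$value
        }
        elems[[e]] <- vals
      }
      if (n_elem == 1L) elems[[1L]] else elems
    } else {
      format_error("unsupported MAT array class ", mx_class)
    }
  list(name = name, value = value, class = mx_class)
}

#' Read a level-5 MAT container
#'
#' Parses uncompressed and zlib-compressed level-5 MAT elements covering
#' numeric arrays, char arrays, cell arrays and structs. MAT v7.3 (HDF5)
#' files are rejected with an informative error.
#'
#' @param path path to a `.mat` file.
#' @return Named list of variables.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) format_error("file not found: ", path)
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 128L) format_error(path, " is not a MAT-file")
  if (identical(bytes[1:8], charToRaw("\x89HDF\r\n\x1a\n")))
    format_error(path, " is a MAT v7.3 (HDF5) container, which is not ",
                 "supported; save it as v5/v7 ('-v7') instead")
  header <- rawToChar(bytes[1:4])
  if (!startsWith(header, "MATL"))
    format_error(path, " lacks a MATLAB level-5 header")
  endian <- rawToChar(bytes[127:128])
  if (endian != "IM")
    format_error("big-endian MAT-files are not supported")
  cur <- mat5_cursor(bytes, 129L)
  out <- list()
  while (cur_left(cur) >= 8L) {
    el <- mat5_read_subelement(cur)
    if (el$type == MI_COMPRESSED) {
      inflated <- memDecompress(el$bytes, type = "gzip")
      inner <- mat5_cursor(inflated)
      el <- mat5_read_subelement(inner)
    }
    if (el$type != MI_MATRIX) next
    parsed <- mat5_parse_matrix(el$bytes)
    out[[parsed$name]] <- parsed$value
    attr(out[[parsed$name]], "mat_class") <- parsed$class
  }
  out
}
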