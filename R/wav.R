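#' Read a mono WAV file as a PCG record
#'
#' Reads RIFF/WAVE audio: PCM 8/16/24/32-bit integer and 32/64-bit IEEE
#' float encodings. Integer samples are rescaled to `[-1, 1)` by the type's
#' full-scale value; float samples are returned as stored. Multi-channel
#' audio is rejected — auscultation recordings are mono.
#'
#' @param path Path to a readable WAV file.
#' @param record_id Identifier for the record; defaults to the file name
#'   without extension.
#' @param site Auscultation site (see [pcg_record()]).
#' @return A [pcg_record()].
#' @export
read_record <- function(path, record_id = NULL, site = "unknown") {
  w <- read_wav(path)
  if (w$channels != 1L) {
    abort(sprintf("'%s' has %d channels; only mono PCG audio is supported.",
                  path, w$channels),
          class = "pcgseg_error_format")
  }
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pcg_record(w$samples, w$sampling_rate_hz, record_id = record_id, site = site)
}

#' Write a PCG record as a mono WAV file
#'
#' @param rec A [pcg_record()], or a numeric vector together with `rate`.
#' @param path Output file path.
#' @param encoding `"float32"` (default, lossless for pipeline output) or
#'   `"pcm16"`.
#' @param rate Sampling rate, only used when `rec` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path, encoding = c("float32", "pcm16"),
                         rate = NULL) {
  encoding <- match.arg(encoding)
  if (is.numeric(rec)) {
    if (is.null(rate)) abort("`rate` is required for a bare numeric vector.")
    rec <- pcg_record(rec, rate)
  }
  write_wav(rec$samples, rec$sampling_rate_hz, path, encoding = encoding)
  invisible(path)
}

# -- minimal RIFF/WAVE codec (mono-oriented; no compressed encodings) --------

read_wav <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "pcgseg_error_format")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file (missing RIFF header).", path),
          class = "pcgseg_error_format")
  }
  readBin(con, "integer", 1L, 4L, endian = "little")  # total size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    abort(sprintf("'%s' is not a WAVE file (missing WAVE tag).", path),
          class = "pcgseg_error_format")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1L, 2L,
                           signed = FALSE, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1L, 4L,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1L, 2L,
                       signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("'%s': missing fmt/data chunk.", path),
          class = "pcgseg_error_format")
  }
  bytes_per <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes_per
  samples <- switch(
    as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 8L) {
        (readBin(data_raw, "integer", n, 1L, signed = FALSE) - 128) / 128
      } else if (fmt$bits == 16L) {
        readBin(data_raw, "integer", n, 2L, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        m <- matrix(as.integer(data_raw), nrow = 3L)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (fmt$bits == 32L) {
        readBin(data_raw, "integer", n, 4L, endian = "little") / 2147483648
      } else {
        abort(sprintf("'%s': unsupported PCM bit depth %d.", path, fmt$bits),
              class = "pcgseg_error_format")
      }
    },
    "3" = {  # IEEE float
      if (fmt$bits == 32L) {
        readBin(data_raw, "double", n, 4L, endian = "little")
      } else if (fmt$bits == 64L) {
        readBin(data_raw, "double", n, 8L, endian = "little")
      } else {
        abort(sprintf("'%s': unsupported float bit depth %d.", path, fmt$bits),
              class = "pcgseg_error_format")
      }
    },
    abort(sprintf("'%s': unsupported WAV encoding (format tag %d).",
                  path, fmt$audio_format),
          class = "pcgseg_error_format")
  )
  if (fmt$channels < 1L) {
    abort(sprintf("'%s': invalid channel count.", path),
          class = "pcgseg_error_format")
  }
  if (fmt$channels > 1L) {
    # de-interleave so callers can report channel count; read_record rejects
    samples <- matrix(samples, nrow = fmt$channels)
  }
  list(samples = samples, sampling_rate_hz = fmt$sample_rate,
       channels = fmt$channels, bits = fmt$bits,
       encoding = if (fmt$audio_format == 3L) "float" else "pcm")
}

write_wav <- function(samples, rate, path, encoding = c("float32", "pcm16"),
                      channels = 1L) {
  encoding <- match.arg(encoding)
  samples <- as.double(samples)
  bits <- if (encoding == "float32") 32L else 16L
  fmt_tag <- if (encoding == "float32") 3L else 1L
  bytes_per <- bits %/% 8L
  data_size <- length(samples) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(as.integer(fmt_tag), con, 2L, endian = "little")
  writeBin(as.integer(channels), con, 2L, endian = "little")
  writeBin(as.integer(rate), con, 4L, endian = "little")
  writeBin(as.integer(rate * channels * bytes_per), con, 4L, endian = "little")
  writeBin(as.integer(channels * bytes_per), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (encoding == "float32") {
    writeBin(samples, con, 4L, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
    writeBin(q, con, 2L, endian = "little")
  }
  invisible(path)
}
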