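#' Audio waveform container
#'
#' A minimal container for a mono audio signal: samples (arbitrary units),
#' sampling rate in samples/s and a free-text label.
#'
#' @param samples Numeric vector of samples; must be finite.
#' @param rate Sampling rate in samples/s (> 0).
#' @param label Free-text label (e.g. sentence id).
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000, "a440")
#' duration(w)
#' @export
waveform <- function(samples, rate, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("waveform is empty", call. = FALSE)
  if (!all(is.finite(samples))) stop("waveform contains non-finite samples", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, rate = rate, label = as.character(label)[1]),
            class = "waveform")
}

#' @rdname waveform
#' @param w A `waveform` (or envelope) object.
#' @export
duration <- function(w) length(w$samples) / w$rate

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform '%s': %d samples @ %g Hz, %.3f s>\n",
              x$label, length(x$samples), x$rate, duration(x)))
  invisible(x)
}

# ---- WAV I/O -----------------------------------------------------------
# Minimal RIFF/WAVE reader and writer: PCM 16/24-bit and IEEE float-32,
# mono; stereo is mixed down to mono with a warning.

#' Read a WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float 32-bit formats. Stereo
#' files are mixed to mono (channel mean) with a warning. Samples are
#' returned scaled to \[-1, 1\] for integer formats.
#'
#' @param path Path to a `.wav` file.
#' @param label Label stored on the returned [waveform()]; defaults to the
#'   file name.
#' @return A [waveform()].
#' @export
read_wav <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: ", path, call. = FALSE)
  x <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) / 3
      m <- matrix(as.integer(data_raw), nrow = 3)
      v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$audio_format == 3) {
        readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
      } else stop("unsupported 32-bit PCM WAV", call. = FALSE)
    },
    stop("unsupported WAV bit depth: ", fmt$bits, call. = FALSE)
  )
  if (fmt$channels > 1) {
    warning("mixing ", fmt$channels, "-channel WAV to mono")
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  }
  waveform(x, fmt$sample_rate, label)
}

#' Write a WAV file
#'
#' @param w A [waveform()]; samples are clipped to \[-1, 1\] for integer
#'   formats.
#' @param path Output path.
#' @param bits Bit depth: 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16, 32))
  x <- w$samples
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(x) * bits / 8
  fmt_code <- if (bits == 32) 3L else 1L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + nbytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(w$rate), con, 4, endian = "little")
  writeBin(as.integer(w$rate * bits / 8), con, 4, endian = "little")
  writeBin(as.integer(bits / 8), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, 4, endian = "little")
  if (bits == 16) {
    xi <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(xi, con, 2, endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
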