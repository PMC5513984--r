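#' Audio buffer
#'
#' A minimal mono audio container: a numeric vector of amplitudes in
#' \[-1, 1\] plus a sampling rate. All synthesis in this package works at
#' 44,100 Hz by default so that staircase step sizes expressed in samples
#' (1,000 and 500) have their conventional millisecond values.
#'
#' @param samples numeric vector of amplitudes, all within \[-1, 1\].
#' @param rate sampling rate in samples per second (> 0).
#' @return an object of class `wrrc_audio` with elements `samples` and `rate`.
#' @export
audio_buffer <- function(samples, rate = 44100) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (any(!is.finite(samples)) || max(abs(samples)) > 1 + 1e-9)
    stop("amplitudes must be finite and within [-1, 1]", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "wrrc_audio")
}

#' @export
print.wrrc_audio <- function(x, ...) {
  cat(sprintf("<wrrc_audio> %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              max(abs(x$samples))))
  invisible(x)
}

#' @export
length.wrrc_audio <- function(x) length(x$samples)

#' Duration of an audio buffer in seconds
#' @param x a `wrrc_audio` object.
#' @return duration in seconds.
#' @export
audio_duration <- function(x) length(x$samples) / x$rate

#' Root-mean-square amplitude
#'
#' @param x a `wrrc_audio` object or numeric vector.
#' @param from,to optional window in seconds (clamped to the buffer).
#' @return RMS amplitude over the requested window.
#' @export
audio_rms <- function(x, from = NULL, to = NULL) {
  s <- if (inherits(x, "wrrc_audio")) x$samples else as.numeric(x)
  if (inherits(x, "wrrc_audio") && (!is.null(from) || !is.null(to))) {
    i0 <- if (is.null(from)) 1L else max(1L, floor(from * x$rate) + 1L)
    i1 <- if (is.null(to)) length(s) else min(length(s), ceiling(to * x$rate))
    if (i1 < i0) stop("empty RMS window", call. = FALSE)
    s <- s[i0:i1]
  }
  sqrt(mean(s^2))
}

#' Dominant spectral frequency by zero-padded FFT peak
#'
#' @param x a `wrrc_audio` object.
#' @param pad_to FFT length after zero padding (default 2^17, about 0.34 Hz
#'   resolution at 44,100 Hz).
#' @return frequency in Hz of the largest magnitude bin below Nyquist.
#' @export
spectral_peak <- function(x, pad_to = 2^17) {
  stopifnot(inherits(x, "wrrc_audio"))
  n <- max(pad_to, length(x$samples))
  s <- c(x$samples, rep(0, n - length(x$samples)))
  mag <- Mod(stats::fft(s))[seq_len(n %/% 2)]
  (which.max(mag) - 1L) * x$rate / n
}

# ---- WAV I/O -----------------------------------------------------------
# Minimal mono PCM16 RIFF/WAVE reader/writer. No audio package ships with
# the supported toolchain, and the format is 44 bytes of header plus raw
# little-endian samples, so it is implemented directly here.

#' Write a mono 16-bit PCM WAV file
#'
#' @param x a `wrrc_audio` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
wav_write <- function(x, path) {
  stopifnot(inherits(x, "wrrc_audio"))
  pcm <- as.integer(round(pmax(-1, pmin(1, x$samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(x$rate), con, size = 4, endian = "little")
  writeBin(as.integer(x$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file path produced by [wav_write()] (or any mono PCM16 WAV).
#' @return a `wrrc_audio` object.
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk", call. = FALSE)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM supported", call. = FALSE)
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      return(audio_buffer(pcm / 32767, rate = rate))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}
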