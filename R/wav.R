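#' Audio clips
#'
#' An `audio_clip` is the basic waveform container used throughout the
#' pipeline: a numeric sample vector (nominally in \[-1, 1\]), a sampling rate
#' in Hz, and a free-text provenance string.
#'
#' @param samples Numeric vector of finite samples.
#' @param rate Sampling rate in Hz (field recordings use 44100).
#' @param source Provenance string (file path or "synth:...").
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate = 44100, source = "unknown") {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    abort("samples must be a finite numeric vector")
  }
  stopifnot_scalar_number(rate, "rate")
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         source = as.character(source)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %d samples, %.0f Hz (%.3f s), source=%s>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$source))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

#' Duration of an audio clip in seconds
#' @param clip An [audio_clip()].
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$rate

#' Extract a time span from a clip
#'
#' Half-open span `[begin_s, end_s)`, converted to sample indices.
#'
#' @param clip An [audio_clip()].
#' @param begin_s,end_s Span in seconds.
#' @return An [audio_clip()] holding the span.
#' @export
clip_slice <- function(clip, begin_s, end_s) {
  if (end_s <= begin_s) abort("end_s must exceed begin_s")
  i0 <- max(1L, 1L + as.integer(round(begin_s * clip$rate)))
  i1 <- min(length(clip$samples), as.integer(round(end_s * clip$rate)))
  if (i1 < i0) abort("requested span is outside the clip")
  audio_clip(clip$samples[i0:i1], clip$rate,
             sprintf("%s[%.4f,%.4f)", clip$source, begin_s, end_s))
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM (16- or 24-bit). Stereo input
#' is down-mixed to mono with a warning; samples are rescaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) abort("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    abort("not a WAVE file")
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found")
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort("data chunk before fmt chunk")
      if (!fmt$audio_format %in% c(1L)) abort("only PCM WAV is supported")
      bytes <- fmt$bits %/% 8L
      n <- size %/% bytes
      if (fmt$bits == 16L) {
        x <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
        x <- x / 32768
      } else if (fmt$bits == 24L) {
        raw <- readBin(con, "raw", size)
        m <- matrix(as.integer(raw), nrow = 3)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        x <- v / 8388608
      } else {
        abort(sprintf("unsupported bit depth: %d", fmt$bits))
      }
      if (fmt$n_channels > 1L) {
        warn(sprintf("down-mixing %d channels to mono: %s",
                     fmt$n_channels, path))
        x <- colMeans(matrix(x, nrow = fmt$n_channels))
      }
      return(audio_clip(x, fmt$rate, source = path))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
}

#' Write a mono PCM 16-bit WAV file
#'
#' @param clip An [audio_clip()]; samples are clipped to \[-1, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  x <- pmax(-1, pmin(1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(clip$rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
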