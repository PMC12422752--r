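#' Zero-phase band-pass filtering
#'
#' Conditions a clip to the species band. Realized as cascaded Butterworth
#' order-4 high-pass and low-pass sections, each applied forward-backward
#' twice (`signal::filtfilt`), giving zero phase (syllable boundaries are not
#' shifted), pass-band ripple well under 1 dB, and more than 40 dB of
#' attenuation one octave outside the band.
#'
#' @param clip An [audio_clip()].
#' @param lo,hi Band edges in Hz (defaults 700 and 3900).
#' @return A filtered [audio_clip()].
#' @export
bandpass <- function(clip, lo = 700, hi = 3900) {
  nyq <- clip$rate / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    abort("need 0 < lo < hi < rate/2")
  }
  hp <- signal::butter(4, lo / nyq, type = "high")
  lp <- signal::butter(4, hi / nyq, type = "low")
  x <- clip$samples
  x <- signal::filtfilt(hp, signal::filtfilt(hp, x))
  x <- signal::filtfilt(lp, signal::filtfilt(lp, x))
  audio_clip(x, clip$rate, source = paste0(clip$source, "|bp"))
}

# Slaney-style mel scale (linear below 1 kHz, logarithmic above), as used by
# the standard audio toolchains.
hz_to_mel <- function(f) {
  m <- f / (200 / 3)
  logstep <- log(6.4) / 27
  ifelse(f >= 1000, 15 + log(f / 1000) / logstep, m)
}

mel_to_hz <- function(m) {
  logstep <- log(6.4) / 27
  ifelse(m >= 15, 1000 * exp(logstep * (m - 15)), m * 200 / 3)
}

mel_filterbank <- function(n_mels, n_fft, rate, fmin, fmax) {
  freqs <- seq(0, rate / 2, length.out = n_fft %/% 2 + 1)
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                       length.out = n_mels + 2))
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lower <- (freqs - pts[m]) / (pts[m + 1] - pts[m])
    upper <- (pts[m + 2] - freqs) / (pts[m + 2] - pts[m + 1])
    fb[m, ] <- pmax(0, pmin(lower, upper))
    # area normalization so bands carry comparable weight
    fb[m, ] <- fb[m, ] * 2 / (pts[m + 2] - pts[m])
  }
  fb
}

#' Mel-spectrogram presets
#'
#' The two parameterizations used throughout: `"motif"` (35 mel bands, frame
#' 512, hop 128) for whole-vocalization embeddings and `"syllable"` (50 mel
#' bands, frame 512, hop 64, fmax 3900 Hz) for frame-level syllable
#' comparison.
#'
#' @param preset `"motif"` or `"syllable"`.
#' @return Named list of parameters for [melspec()].
#' @export
melspec_preset <- function(preset = c("motif", "syllable")) {
  switch(match.arg(preset),
    motif = list(n_mels = 35L, frame_len = 512L, hop = 128L, fmax = 3900),
    syllable = list(n_mels = 50L, frame_len = 512L, hop = 64L, fmax = 3900)
  )
}

#' Magnitude mel-spectrogram
#'
#' Hann-windowed, center-padded short-time Fourier transform followed by a
#' triangular mel filterbank. Returns linear magnitudes (not power or dB); the
#' magnitude convention is fixed across the whole pipeline.
#'
#' @param clip An [audio_clip()].
#' @param n_mels Number of mel bands.
#' @param frame_len Frame length in samples.
#' @param hop Hop length in samples.
#' @param fmax Upper edge of the filterbank in Hz.
#' @param fmin Lower edge in Hz (default 0).
#' @param preset Optional preset name overriding the four parameters (see
#'   [melspec_preset()]).
#' @return A `melspec` object: an `n_mels x n_frames` matrix with attributes
#'   `rate`, `frame_len`, `hop`, `fmin`, `fmax` and `frame_times` (seconds, at
#'   frame centers).
#' @export
melspec <- function(clip, n_mels = 35L, frame_len = 512L, hop = 128L,
                    fmax = 3900, fmin = 0, preset = NULL) {
  if (!is.null(preset)) {
    p <- melspec_preset(preset)
    n_mels <- p$n_mels; frame_len <- p$frame_len
    hop <- p$hop; fmax <- p$fmax
  }
  x <- clip$samples
  if (length(x) < frame_len) abort("clip shorter than one frame")
  g <- frame_grid(length(x), frame_len, hop)
  pad <- frame_len %/% 2
  xp <- reflect_pad(x, pad)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(frame_len) - 1) / frame_len)
  frames <- vapply(g$centers,
                   function(s) xp[s:(s + frame_len - 1L)] * win,
                   numeric(frame_len))
  spec <- Mod(stats::mvfft(frames))[seq_len(frame_len %/% 2 + 1), ,
                                    drop = FALSE]
  fb <- mel_filterbank(n_mels, frame_len, clip$rate, fmin, fmax)
  vals <- fb %*% spec
  structure(vals,
            class = c("melspec", "matrix"),
            rate = clip$rate, frame_len = frame_len, hop = hop,
            fmin = fmin, fmax = fmax,
            frame_times = (g$centers - 1) / clip$rate)
}

#' @export
print.melspec <- function(x, ...) {
  cat(sprintf("<melspec: %d mel bands x %d frames, hop %d, fmax %.0f Hz>\n",
              nrow(x), ncol(x), attr(x, "hop"), attr(x, "fmax")))
  invisible(x)
}

keep_spec_attrs <- function(new_vals, spec) {
  attributes(new_vals) <- attributes(spec)
  new_vals
}

#' Median-clipping noise mask
#'
#' Image-style spectrogram denoiser: a cell is kept only if it exceeds
#' `factor` times the larger of its row (band) median and column (frame)
#' median; all other cells are zeroed (hard mask).
#'
#' @param spec A `melspec` (or plain matrix).
#' @param factor Clipping factor (default 3).
#' @return Masked spectrogram of the same class.
#' @export
median_clip <- function(spec, factor = 3.0) {
  m <- unclass(spec)
  if (length(m) == 0) return(spec)
  row_med <- apply(m, 1, median)
  col_med <- apply(m, 2, median)
  thr <- factor * pmax(matrix(row_med, nrow(m), ncol(m)),
                       matrix(col_med, nrow(m), ncol(m), byrow = TRUE))
  keep_spec_attrs(ifelse(m > thr, m, 0), spec)
}

#' Small-object removal
#'
#' Deletes 8-connected components of nonzero spectrogram cells whose area is
#' below `min_area`; larger components pass through untouched. Intended for
#' masked (post-clipping) spectrograms.
#'
#' @param spec A `melspec` (or plain matrix), typically after [median_clip()].
#' @param min_area Minimum component area in cells (>= 1).
#' @return Cleaned spectrogram of the same class.
#' @export
remove_small_objects <- function(spec, min_area = 5L) {
  if (min_area < 1) abort("min_area must be >= 1")
  m <- unclass(spec)
  if (length(m) == 0 || min_area == 1) return(spec)
  lab <- label_components_cpp(m != 0)
  sizes <- tabulate(lab)
  small <- which(sizes < min_area)
  if (length(small) > 0) m[lab %in% small] <- 0
  keep_spec_attrs(m, spec)
}
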