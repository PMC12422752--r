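#' Fundamental-frequency contour by zero-crossing analysis
#'
#' Estimates a per-frame pitch track from a band-passed clip. Within each
#' centered frame, zero-crossing instants are located with linear
#' interpolation between samples and the fundamental is estimated as
#' `(n_crossings - 1) / (2 * (t_last - t_first))`, i.e. crossings per unit
#' time refined to sub-sample precision. Frames whose RMS falls below
#' `voiced_threshold` times the clip's peak amplitude, with fewer than three
#' crossings, or whose estimate leaves `f_range` are marked unvoiced.
#'
#' @param clip A band-passed [audio_clip()].
#' @param frame_len Frame length in samples (default 512).
#' @param hop Hop in samples (default 64).
#' @param voiced_threshold Voicing threshold as a fraction of peak amplitude
#'   (default 0.05).
#' @param crossing_gate Crossings are only counted where the local signal
#'   envelope (short moving RMS) exceeds this fraction of its peak (default
#'   0.15); this rejects crossings contributed by filter ringing and
#'   background noise at syllable edges.
#' @param f_range Plausible fundamental range in Hz (default `c(700, 3900)`).
#' @return An `f0_contour` tibble with columns `time` (s, frame centers),
#'   `f0_hz`, `voiced`; attributes `method`, `rate`, `frame_len`, `hop`.
#' @export
f0_zcr <- function(clip, frame_len = 512L, hop = 64L,
                   voiced_threshold = 0.05, crossing_gate = 0.15,
                   f_range = c(700, 3900)) {
  x <- clip$samples
  if (length(x) < frame_len) abort("clip shorter than frame_len")
  rate <- clip$rate
  g <- frame_grid(length(x), frame_len, hop)
  pad <- frame_len %/% 2

  # sub-sample zero-crossing positions over the *unpadded* signal; edge
  # windows are clamped so the estimate never sees padding artifacts.
  # Crossings in regions whose local envelope (short moving RMS) is below the
  # voicing gate -- filter ringing tails, background noise -- are discarded.
  s <- x[-length(x)]
  s2 <- x[-1]
  idx <- which(s * s2 < 0)
  w <- 128L
  cs <- c(0, cumsum(x^2))
  ei0 <- pmax(1L, seq_along(x) - w %/% 2L)
  ei1 <- pmin(length(x), seq_along(x) + w %/% 2L)
  env_local <- sqrt((cs[ei1 + 1L] - cs[ei0]) / (ei1 - ei0 + 1L))
  gate <- crossing_gate * max(env_local)
  idx <- idx[env_local[idx] >= gate]
  cross <- idx + s[idx] / (s[idx] - s2[idx])  # position in samples

  starts <- pmax(1L, g$centers - pad)
  ends <- pmin(length(x), g$centers + pad - 1L)
  lo <- findInterval(starts - 1e-9, cross) + 1L
  hi <- findInterval(ends, cross)
  n_cross <- pmax(0L, hi - lo + 1L)
  f0 <- rep(NA_real_, g$n_frames)
  ok <- n_cross >= 3L
  span <- ifelse(ok, cross[pmax(hi, 1L)] - cross[pmax(lo, 1L)], NA_real_)
  f0[ok] <- (n_cross[ok] - 1) / 2 / (span[ok] / rate)

  env <- frame_rms(x, frame_len, hop)
  voiced <- ok & env >= voiced_threshold * max(abs(x)) &
    !is.na(f0) & f0 >= f_range[1] & f0 <= f_range[2]
  f0[!voiced] <- NA_real_
  # a frame's estimate refers to the midpoint of its measured crossing span
  # (identical to the frame center for interior frames, and the honest time
  # stamp for clamped edge windows)
  times <- (g$centers - 1) / rate
  mid <- ifelse(ok, (cross[pmax(hi, 1L)] + cross[pmax(lo, 1L)]) / 2 / rate,
                NA_real_)
  times[voiced] <- mid[voiced]
  structure(
    tibble(time = times, f0_hz = f0, voiced = voiced),
    class = c("f0_contour", "tbl_df", "tbl", "data.frame"),
    method = "zcr", rate = rate, frame_len = frame_len, hop = hop,
    clip_duration = length(x) / rate
  )
}

# YIN-style cumulative-mean-normalized difference pitch per frame.
# Returns NA where no dip falls below `threshold` in the tau search range.
yin_f0 <- function(x, rate, centers, frame_len, f_range, threshold = 0.15) {
  pad <- frame_len %/% 2
  xp <- reflect_pad(x, pad)
  tau_min <- max(2L, as.integer(floor(rate / f_range[2])))
  tau_max <- as.integer(ceiling(rate / f_range[1]))
  taus <- tau_min:tau_max
  n_frames <- length(centers)
  # difference function per frame via cumulative sums of squared lags
  w <- frame_len - tau_max  # correlation window, equal across taus
  if (w < 16) abort("frame_len too short for the YIN search range")
  d <- matrix(0, n_frames, length(taus))
  for (k in seq_along(taus)) {
    tau <- taus[k]
    z <- (xp[1:(length(xp) - tau)] - xp[(1 + tau):length(xp)])^2
    cz <- c(0, cumsum(z))
    starts <- centers
    ends <- starts + w - 1L
    d[, k] <- cz[ends + 1L] - cz[starts]
  }
  cmnd <- d / (t(apply(d, 1, cumsum)) / matrix(seq_along(taus), n_frames,
                                               length(taus), byrow = TRUE))
  cmnd[!is.finite(cmnd)] <- 1
  f0 <- rep(NA_real_, n_frames)
  for (i in seq_len(n_frames)) {
    below <- which(cmnd[i, ] < threshold)
    k <- if (length(below) > 0) {
      # first local minimum after the threshold crossing
      k0 <- below[1]
      while (k0 < length(taus) && cmnd[i, k0 + 1] < cmnd[i, k0]) k0 <- k0 + 1
      k0
    } else {
      which.min(cmnd[i, ])
    }
    tau <- taus[k]
    # parabolic interpolation around the minimum
    if (k > 1 && k < length(taus)) {
      y0 <- cmnd[i, k - 1]; y1 <- cmnd[i, k]; y2 <- cmnd[i, k + 1]
      denom <- y0 - 2 * y1 + y2
      if (abs(denom) > 1e-12) tau <- tau + 0.5 * (y0 - y2) / denom
    }
    if (length(below) > 0) f0[i] <- rate / tau
  }
  f0
}

#' Verify a zero-crossing pitch track with the YIN difference function
#'
#' Recomputes the pitch of every voiced frame using the cumulative-mean-
#' normalized difference function and reports where the two estimators agree
#' within `tol_pct` percent. Disagreeing frames are flagged, not altered.
#'
#' @param clip The same band-passed [audio_clip()] used for [f0_zcr()].
#' @param contour An `f0_contour` from [f0_zcr()].
#' @param tol_pct Relative agreement tolerance in percent (default 10).
#' @return A list (`f0_verification`): `agreement` (fraction of voiced frames
#'   agreeing), `frames` (tibble: time, f0_zcr, f0_yin, agree), `tol_pct`.
#'   Empty report when no frames are voiced.
#' @export
f0_verify_yin <- function(clip, contour, tol_pct = 10) {
  rate <- attr(contour, "rate")
  frame_len <- attr(contour, "frame_len")
  voiced_idx <- which(contour$voiced)
  if (length(voiced_idx) == 0) {
    return(structure(list(agreement = NA_real_,
                          frames = tibble(time = numeric(), f0_zcr = numeric(),
                                          f0_yin = numeric(), agree = logical()),
                          tol_pct = tol_pct),
                     class = "f0_verification"))
  }
  centers <- 1L + as.integer(round(contour$time * rate))
  f0y <- yin_f0(clip$samples, rate, centers[voiced_idx], frame_len,
                f_range = c(700, 3900))
  f0z <- contour$f0_hz[voiced_idx]
  agree <- !is.na(f0y) & abs(f0y - f0z) <= tol_pct / 100 * f0z
  structure(
    list(agreement = mean(agree),
         frames = tibble(time = contour$time[voiced_idx], f0_zcr = f0z,
                         f0_yin = f0y, agree = agree),
         tol_pct = tol_pct),
    class = "f0_verification"
  )
}

#' @export
print.f0_verification <- function(x, ...) {
  cat(sprintf("<f0 verification: %.1f%% of %d voiced frames agree within %g%%>\n",
              100 * x$agreement, nrow(x$frames), x$tol_pct))
  invisible(x)
}

#' Fit a Legendre polynomial to a pitch contour
#'
#' Frame times are mapped affinely to \[-1, 1\] over the syllable's span and
#' the voiced contour samples are fit by least squares in the Legendre basis;
#' the coefficients (in Hz) are the syllable's feature vector. The span
#' defaults to the full extent of the analyzed clip (a demarcated syllable),
#' so that coefficients parameterize the syllable's duration rather than the
#' slightly narrower region where voicing was detected; when the extent is
#' unknown the voiced-frame range is used.
#'
#' @param contour An `f0_contour` (from [f0_zcr()]) or a tibble/data frame
#'   with `time`, `f0_hz`, `voiced` columns.
#' @param order Polynomial order K (default 4, giving K+1 coefficients).
#' @param span Optional `c(begin_s, end_s)` the polynomial is parameterized
#'   over.
#' @return A `legendre_feature` list: `coeffs` (length K+1),
#'   `rms_residual_hz`, `duration_s`, `n_voiced`.
#' @export
fit_legendre <- function(contour, order = 4L, span = NULL) {
  v <- contour$voiced & !is.na(contour$f0_hz)
  n <- sum(v)
  if (n < order + 1) {
    abort(sprintf(
      "need at least %d voiced frames for an order-%d fit, have %d (short by %d)",
      order + 1, order, n, order + 1 - n))
  }
  t <- contour$time[v]
  y <- contour$f0_hz[v]
  if (is.null(span)) {
    dur <- attr(contour, "clip_duration")
    span <- if (is.null(dur)) range(t) else c(0, dur)
  }
  u <- linear_map(t, span, c(-1, 1))
  B <- legendre_basis(u, order)
  fit <- stats::lm.fit(B, y)
  coeffs <- unname(fit$coefficients)
  # robust refit: pitch trackers occasionally emit gross per-frame errors at
  # syllable edges; iteratively drop residuals far outside the robust scale
  keep <- rep(TRUE, n)
  for (i in 1:3) {
    r <- y - drop(B %*% coeffs)
    thr <- max(4 * stats::mad(r[keep]), 10)
    keep_new <- abs(r) <= thr
    if (sum(keep_new) < order + 1 || identical(keep_new, keep)) break
    keep <- keep_new
    coeffs <- unname(stats::lm.fit(B[keep, , drop = FALSE], y[keep])$coefficients)
  }
  resid <- (y - drop(B %*% coeffs))[keep]
  structure(
    list(coeffs = coeffs, rms_residual_hz = sqrt(mean(resid^2)),
         duration_s = diff(span), n_voiced = n, n_used = sum(keep)),
    class = "legendre_feature"
  )
}

#' @export
print.legendre_feature <- function(x, ...) {
  cat(sprintf("<legendre_feature: order %d, coeffs [%s] Hz, residual %.1f Hz>\n",
              length(x$coeffs) - 1,
              paste(sprintf("%.0f", x$coeffs), collapse = ", "),
              x$rms_residual_hz))
  invisible(x)
}

#' Whole-motif mel-filterbank embedding
#'
#' The motif span is cut from the clip, converted to a motif-preset
#' mel-spectrogram (35 bands), median-clipped, linearly resampled along time
#' to exactly 34 frames, flattened band-major to a length-1190 vector, and
#' max-normalized to \[0, 1\]. Silent motifs return the zero vector (flagged
#' via the `silent` attribute).
#'
#' @param clip An [audio_clip()] containing the motif (band-passed).
#' @param motif Optional one-row tibble/list with `begin_s`, `end_s`; `NULL`
#'   uses the whole clip.
#' @param n_frames_out Number of time frames after resampling (default 34).
#' @param clip_factor Median-clipping factor (default 3).
#' @return Numeric vector of length `35 * n_frames_out` (class
#'   `motif_embedding`).
#' @export
motif_embedding <- function(clip, motif = NULL, n_frames_out = 34L,
                            clip_factor = 3.0) {
  seg <- if (is.null(motif)) clip else clip_slice(clip, motif$begin_s,
                                                  motif$end_s)
  sp <- melspec(seg, preset = "motif")
  sp <- median_clip(sp, clip_factor)
  m <- unclass(sp)
  nf <- ncol(m)
  out <- if (nf == 1) {
    matrix(m, nrow(m), n_frames_out)
  } else {
    t(apply(m, 1, function(row) {
      approx(seq_len(nf), row, n = n_frames_out)$y
    }))
  }
  v <- as.vector(t(out))  # band-major: all frames of band 1, then band 2, ...
  mx <- max(v)
  silent <- mx <= 0
  if (!silent) v <- v / mx else v[] <- 0
  structure(v, class = "motif_embedding", silent = silent)
}

#' Acoustic summary of a motif
#'
#' Concatenates the motif's syllable spans (removing inter-syllable gaps),
#' estimates the fundamental-frequency contour of the concatenated signal by
#' zero-crossing analysis (verified with YIN), and summarizes: min/max/mean
#' fundamental over voiced frames, bandwidth = max - min, and the
#' amplitude-weighted spectral centroid of the band-limited magnitude
#' spectrum.
#'
#' @param clip A band-passed [audio_clip()] (whole file).
#' @param syllables Tibble of syllable segments (`begin_s`, `end_s`),
#'   absolute within `clip`.
#' @param f_range Analysis band in Hz (default `c(700, 3900)`).
#' @return One-row tibble: `f0_min`, `f0_max`, `f0_mean`, `bandwidth`,
#'   `spectral_centroid`, `yin_agreement`.
#' @export
acoustic_summary <- function(clip, syllables, f_range = c(700, 3900)) {
  if (nrow(syllables) < 1) abort("need at least one syllable")
  pieces <- purrr::map(seq_len(nrow(syllables)), function(i) {
    clip_slice(clip, syllables$begin_s[i], syllables$end_s[i])$samples
  })
  cat_clip <- audio_clip(unlist(pieces), clip$rate,
                         source = paste0(clip$source, "|concat"))
  contour <- f0_zcr(cat_clip, f_range = f_range)
  if (!any(contour$voiced)) abort("all frames unvoiced")
  ver <- f0_verify_yin(cat_clip, contour)
  f0 <- contour$f0_hz[contour$voiced]

  spec <- Mod(fft(cat_clip$samples))
  n <- length(spec)
  freqs <- (seq_len(n) - 1) / n * cat_clip$rate
  band <- freqs >= f_range[1] & freqs <= f_range[2]
  centroid <- sum(freqs[band] * spec[band]) / sum(spec[band])

  tibble(
    f0_min = min(f0), f0_max = max(f0), f0_mean = mean(f0),
    bandwidth = max(f0) - min(f0), spectral_centroid = centroid,
    yin_agreement = ver$agreement
  )
}
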