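#' Detect candidate vocal windows by in-band energy
#'
#' Slides 0.5 s windows (eighth-window hop) over a band-passed clip, keeps
#' windows whose RMS exceeds the noise floor by more than `thresh_db`, and
#' merges overlapping hits. The noise floor is the 10th percentile of RMS
#' over short (50 ms) frames, which stays uncontaminated by vocalizations
#' even in clips barely longer than one window.
#'
#' @param clip A band-passed [audio_clip()].
#' @param win_s Window length in seconds (default 0.5).
#' @param thresh_db Threshold above the noise floor in dB (default 10).
#' @return Tibble of candidate windows (`begin_s`, `end_s`); empty for clips
#'   shorter than `win_s` or pure silence.
#' @export
detect_candidates <- function(clip, win_s = 0.5, thresh_db = 10) {
  n <- length(clip$samples)
  win <- as.integer(round(win_s * clip$rate))
  if (n < win) return(tibble(begin_s = numeric(), end_s = numeric()))
  hop <- max(1L, win %/% 8L)
  starts <- seq(1L, n - win + 1L, by = hop)
  cs <- c(0, cumsum(clip$samples^2))
  wrms <- sqrt((cs[starts + win] - cs[starts]) / win)
  fine <- as.integer(round(0.05 * clip$rate))
  fstarts <- seq(1L, max(1L, n - fine + 1L), by = max(1L, fine %/% 2L))
  frms <- sqrt((cs[pmin(n + 1L, fstarts + fine)] - cs[fstarts]) /
                 pmin(fine, n - fstarts + 1L))
  floor_rms <- quantile(frms, 0.10, names = FALSE)
  thr <- max(floor_rms, 1e-12) * 10^(thresh_db / 20)
  hit <- wrms > thr
  if (!any(hit)) return(tibble(begin_s = numeric(), end_s = numeric()))
  # merge overlapping / adjacent hit windows
  b <- starts[hit]
  e <- b + win - 1L
  merged_b <- b[1]; merged_e <- e[1]
  out_b <- c(); out_e <- c()
  for (i in seq_along(b)[-1]) {
    if (b[i] <= merged_e + 1L) {
      merged_e <- max(merged_e, e[i])
    } else {
      out_b <- c(out_b, merged_b); out_e <- c(out_e, merged_e)
      merged_b <- b[i]; merged_e <- e[i]
    }
  }
  out_b <- c(out_b, merged_b); out_e <- c(out_e, merged_e)
  tibble(begin_s = (out_b - 1) / clip$rate, end_s = out_e / clip$rate)
}

# Per-frame zero-crossing counts (plain counts, for the endpoint detector).
frame_zcr_counts <- function(x, frame_len, hop) {
  g <- frame_grid(length(x), frame_len, hop)
  pad <- frame_len %/% 2
  xp <- reflect_pad(x, pad)
  sgn <- sign(xp)
  sgn[sgn == 0] <- 1
  ch <- c(0, cumsum(abs(diff(sgn)) > 0))
  starts <- g$centers
  ends <- pmin(starts + frame_len - 2L, length(ch) - 1L)
  ch[ends + 1L] - ch[starts]
}

#' Demarcate motif endpoints inside a candidate window
#'
#' Classic isolated-word endpoint detection: short-time energy with a
#' lower/upper threshold pair derived from the window's noise statistics
#' locates the energy core and walks outward to the lower threshold, then a
#' zero-crossing-rate pass may extend the boundaries through low-energy
#' voiced fringes. The candidate window is widened by `context_s` of noise
#' context before analysis.
#'
#' @param clip A band-passed [audio_clip()].
#' @param window One-row tibble/list with `begin_s`, `end_s` from
#'   [detect_candidates()].
#' @param frame_len,hop Analysis frame and hop in samples.
#' @param context_s Noise context appended on both sides (seconds).
#' @return One-row tibble (`begin_s`, `end_s`, `clamped`) with boundaries
#'   absolute in the clip, or `NULL` when no frame exceeds the upper
#'   threshold ("no call").
#' @export
demarcate_motif <- function(clip, window, frame_len = 512L, hop = 64L,
                            context_s = 0.25) {
  rate <- clip$rate
  w0 <- max(0, window$begin_s - context_s)
  w1 <- min(clip_duration(clip), window$end_s + context_s)
  seg <- clip_slice(clip, w0, w1)
  E <- frame_rms(seg$samples, frame_len, hop)^2
  imn <- max(quantile(E, 0.10, names = FALSE), 1e-20)
  imx <- max(E)
  itl <- min(imn + 0.03 * (imx - imn), 4 * imn)
  itu <- 5 * itl
  above_u <- which(E > itu)
  if (length(above_u) == 0) {
    inform(sprintf("no call in window [%.2f, %.2f]s", window$begin_s,
                   window$end_s))
    return(NULL)
  }
  # walk outward from the energy core to the lower threshold
  b <- above_u[1]
  while (b > 1 && E[b - 1] > itl) b <- b - 1
  e <- above_u[length(above_u)]
  while (e < length(E) && E[e + 1] > itl) e <- e + 1

  # zero-crossing extension through voiced fringes (up to 250 ms out)
  zc <- frame_zcr_counts(seg$samples, frame_len, hop)
  noise_frames <- c(seq_len(max(1L, b - 1L)),
                    seq(min(length(zc), e + 1L), length(zc)))
  izct <- mean(zc[noise_frames]) + 2 * sd(zc[noise_frames])
  reach <- as.integer(round(0.25 * rate / hop))
  scan_b <- seq(max(1L, b - reach), b)
  hits <- scan_b[zc[scan_b] > izct & E[scan_b] > imn * 2]
  if (length(hits) >= 3) b <- hits[1]
  scan_e <- seq(e, min(length(zc), e + reach))
  hits <- scan_e[zc[scan_e] > izct & E[scan_e] > imn * 2]
  if (length(hits) >= 3) e <- hits[length(hits)]

  frame_time <- function(i) (i - 1) * hop / rate
  begin_s <- w0 + frame_time(b) - frame_len / 2 / rate
  end_s <- w0 + frame_time(e) + frame_len / 2 / rate
  clamped <- FALSE
  if (begin_s < w0) { begin_s <- w0; clamped <- TRUE }
  if (end_s > w1) { end_s <- w1; clamped <- TRUE }
  dur <- end_s - begin_s
  if (dur < 0.3 || dur > 2.5) {
    inform(sprintf("motif duration %.2fs outside the typical 0.3-2.5s range",
                   dur))
  }
  tibble(begin_s = begin_s, end_s = end_s, clamped = clamped)
}

#' Split a demarcated motif into syllables
#'
#' The in-band energy envelope (syllable-preset mel-spectrogram, summed over
#' bands) is median-smoothed and thresholded at `peak - drop_db`; maximal
#' supra-threshold runs separated by gaps of at least `gap_min_s` become
#' syllables (shorter gaps are merged). Segments are returned ordered,
#' non-overlapping and absolute within the clip.
#'
#' @param clip A band-passed [audio_clip()].
#' @param motif One-row tibble/list with `begin_s`, `end_s`.
#' @param drop_db Threshold below the envelope peak in dB (default 20).
#' @param gap_min_s Minimum silent gap separating syllables (default 0.015).
#' @param smooth Median-smoothing length in frames (default 5).
#' @return Tibble of syllable segments: `begin_s`, `end_s`, `index_in_motif`.
#' @export
split_syllables <- function(clip, motif, drop_db = 20, gap_min_s = 0.015,
                            smooth = 5L) {
  seg <- clip_slice(clip, motif$begin_s, motif$end_s)
  sp <- melspec(seg, preset = "syllable")
  hop <- attr(sp, "hop")
  rate <- attr(sp, "rate")
  energy <- colSums(unclass(sp)^2)
  env_db <- 10 * log10(energy + 1e-20)
  if (length(env_db) > smooth) {
    env_db <- stats::runmed(env_db, smooth)
  }
  thr <- max(env_db) - drop_db
  above <- env_db >= thr
  # merge sub-threshold gaps shorter than gap_min_s
  gap_frames <- as.integer(ceiling(gap_min_s * rate / hop))
  r <- rle(above)
  idx_end <- cumsum(r$lengths)
  idx_beg <- idx_end - r$lengths + 1L
  interior <- which(!r$values & r$lengths < gap_frames &
                      seq_along(r$values) > 1 &
                      seq_along(r$values) < length(r$values))
  above[unlist(purrr::map(interior, function(i) idx_beg[i]:idx_end[i]))] <- TRUE
  r <- rle(above)
  idx_end <- cumsum(r$lengths)
  idx_beg <- idx_end - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0) abort("no supra-threshold energy in motif")
  times <- attr(sp, "frame_times")
  half <- hop / 2 / rate
  out <- tibble(
    begin_s = motif$begin_s + pmax(0, times[idx_beg[runs]] - half),
    end_s = motif$begin_s +
      pmin(clip_duration(seg), times[idx_end[runs]] + half),
    index_in_motif = seq_along(runs) - 1L
  )
  n_syl <- nrow(out)
  if (n_syl > 5) {
    inform(sprintf("%d syllables found (outside the typical 1-5 range)", n_syl))
  }
  stopifnot(all(diff(out$begin_s) > 0), all(out$end_s > out$begin_s),
            all(head(out$end_s, -1) <= tail(out$begin_s, -1) + 1e-9))
  out
}

#' Segment every file of a corpus
#'
#' Runs band-pass conditioning, candidate detection, endpoint demarcation and
#' syllable splitting over a set of clips (or WAV paths), returning the
#' standard segment-table dialect. Externally produced segment tables can be
#' used instead of this function anywhere downstream.
#'
#' @param clips Named list of [audio_clip()] objects, or character vector of
#'   WAV paths.
#' @param populations Optional named character vector mapping file ->
#'   population.
#' @return Tibble: `file`, `begin_s`, `end_s`, `unit_type` (motif/syllable),
#'   `label` (NA), `population`.
#' @export
segment_corpus <- function(clips, populations = NULL) {
  if (is.character(clips)) {
    paths <- clips
    clips <- purrr::map(paths, read_wav)
    names(clips) <- basename(paths)
  }
  rows <- purrr::imap(clips, function(clip, fname) {
    bp <- bandpass(clip)
    cands <- detect_candidates(bp)
    pop <- if (is.null(populations)) NA_character_ else
      unname(populations[fname])
    motif_rows <- list()
    syl_rows <- list()
    for (i in seq_len(nrow(cands))) {
      m <- demarcate_motif(bp, cands[i, ])
      if (is.null(m)) next
      syls <- split_syllables(bp, m)
      motif_rows[[length(motif_rows) + 1L]] <-
        tibble(file = fname, begin_s = m$begin_s, end_s = m$end_s,
               unit_type = "motif", label = NA_character_, population = pop)
      syl_rows[[length(syl_rows) + 1L]] <-
        tibble(file = fname, begin_s = syls$begin_s, end_s = syls$end_s,
               unit_type = "syllable", label = NA_character_, population = pop)
    }
    dplyr::bind_rows(c(motif_rows, syl_rows))
  })
  dplyr::bind_rows(rows)
}

#' Score detected segments against a ground-truth table
#'
#' A true motif counts as detected when some detected motif in the same file
#' matches both boundaries within `tol_s`; for matched motifs the detected
#' syllable count is compared with truth.
#'
#' @param segments Segment table from [segment_corpus()].
#' @param truth Truth table from [synth_corpus()].
#' @param tol_s Boundary tolerance in seconds (default 0.025).
#' @return List: `detection_rate`, `boundary_mae_s`,
#'   `syllable_count_accuracy`, `per_motif` tibble.
#' @export
evaluate_segmentation <- function(segments, truth, tol_s = 0.025) {
  true_motifs <- dplyr::filter(truth, .data$unit_type == "motif")
  per <- purrr::map(seq_len(nrow(true_motifs)), function(i) {
    tm <- true_motifs[i, ]
    det <- dplyr::filter(segments, .data$file == tm$file,
                         .data$unit_type == "motif")
    if (nrow(det) == 0) {
      return(tibble(file = tm$file, detected = FALSE, err_begin = NA_real_,
                    err_end = NA_real_, n_syl_true = NA_integer_,
                    n_syl_det = NA_integer_))
    }
    j <- which.min(abs(det$begin_s - tm$begin_s) + abs(det$end_s - tm$end_s))
    err_b <- abs(det$begin_s[j] - tm$begin_s)
    err_e <- abs(det$end_s[j] - tm$end_s)
    n_true <- sum(truth$file == tm$file & truth$unit_type == "syllable")
    n_det <- sum(segments$file == tm$file & segments$unit_type == "syllable")
    tibble(file = tm$file, detected = err_b <= tol_s && err_e <= tol_s,
           err_begin = err_b, err_end = err_e,
           n_syl_true = n_true, n_syl_det = n_det)
  }) |> dplyr::bind_rows()
  list(
    detection_rate = mean(per$detected),
    boundary_mae_s = mean(c(per$err_begin, per$err_end), na.rm = TRUE),
    syllable_count_accuracy = mean(per$n_syl_true == per$n_syl_det,
                                   na.rm = TRUE),
    per_motif = per
  )
}
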