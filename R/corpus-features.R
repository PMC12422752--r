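# Corpus-level feature extraction: one row per vocal unit, tidy tables ready
# for clustering and similarity analysis.

bandpassed_clips <- function(clips) {
  if (is.character(clips)) {
    paths <- clips
    clips <- purrr::map(paths, read_wav)
    names(clips) <- basename(paths)
  }
  purrr::map(clips, bandpass)
}

#' Motif embedding table for a corpus
#'
#' Band-passes each file once and computes the length-1190 mel-filterbank
#' embedding ([motif_embedding()]) for every motif segment.
#'
#' @param clips Named list of [audio_clip()] (or WAV paths); names must match
#'   the segment table's `file` column.
#' @param motifs Segment tibble filtered to motif rows (`file`, `begin_s`,
#'   `end_s`, optionally `label`, `population`).
#' @param already_bandpassed Set `TRUE` when `clips` are filtered already.
#' @return Tibble: `file`, `label`, `population`, `begin_s`, `end_s`,
#'   `embedding` (list-column of numeric vectors).
#' @export
motif_features <- function(clips, motifs, already_bandpassed = FALSE) {
  bp <- if (already_bandpassed) clips else bandpassed_clips(clips)
  purrr::map(seq_len(nrow(motifs)), function(i) {
    row <- motifs[i, ]
    emb <- motif_embedding(bp[[row$file]], row)
    tibble(file = row$file,
           label = row$label %||% NA_character_,
           population = row$population %||% NA_character_,
           begin_s = row$begin_s, end_s = row$end_s,
           embedding = list(as.numeric(emb)))
  }) |> dplyr::bind_rows()
}

#' Legendre coefficient table for a corpus of syllables
#'
#' For each syllable segment: slice, zero-crossing pitch track, Legendre fit.
#' Syllables with too few voiced frames for the fit are dropped with a
#' message.
#'
#' @param clips Named list of [audio_clip()] (or WAV paths).
#' @param syllables Segment tibble filtered to syllable rows.
#' @param order Legendre order K (default 4).
#' @param already_bandpassed Set `TRUE` when `clips` are filtered already.
#' @return Tibble: `file`, `label`, `population`, `begin_s`, `end_s`,
#'   `c0..cK`, `rms_residual_hz`, `n_voiced`.
#' @export
syllable_features <- function(clips, syllables, order = 4L,
                              already_bandpassed = FALSE) {
  bp <- if (already_bandpassed) clips else bandpassed_clips(clips)
  dropped <- 0L
  rows <- purrr::map(seq_len(nrow(syllables)), function(i) {
    row <- syllables[i, ]
    seg <- clip_slice(bp[[row$file]], row$begin_s, row$end_s)
    feat <- tryCatch({
      contour <- f0_zcr(seg)
      fit_legendre(contour, order = order)
    }, error = function(e) NULL)
    if (is.null(feat)) {
      dropped <<- dropped + 1L
      return(NULL)
    }
    coef_tbl <- as_tibble(as.list(setNames(feat$coeffs,
                                           paste0("c", 0:order))))
    dplyr::bind_cols(
      tibble(file = row$file, label = row$label %||% NA_character_,
             population = row$population %||% NA_character_,
             begin_s = row$begin_s, end_s = row$end_s),
      coef_tbl,
      tibble(rms_residual_hz = feat$rms_residual_hz,
             n_voiced = feat$n_voiced)
    )
  })
  if (dropped > 0) {
    inform(sprintf("%d syllable(s) dropped (too few voiced frames)", dropped))
  }
  dplyr::bind_rows(rows)
}

#' Syllable-preset spectrogram representations for DTW
#'
#' @param clips Named list of [audio_clip()] (or WAV paths).
#' @param syllables Segment tibble filtered to syllable rows.
#' @param already_bandpassed Set `TRUE` when `clips` are filtered already.
#' @return Named list of `melspec` objects; names are
#'   `<file>#<index>` syllable ids aligned with the returned `labels`
#'   attribute (tibble: id, type_label, population).
#' @export
syllable_reps <- function(clips, syllables, already_bandpassed = FALSE) {
  bp <- if (already_bandpassed) clips else bandpassed_clips(clips)
  ids <- sprintf("%s#%d", syllables$file, seq_len(nrow(syllables)))
  reps <- purrr::map(seq_len(nrow(syllables)), function(i) {
    row <- syllables[i, ]
    melspec(clip_slice(bp[[row$file]], row$begin_s, row$end_s),
            preset = "syllable")
  })
  names(reps) <- ids
  attr(reps, "labels") <- tibble(
    id = ids,
    type_label = syllables$label %||% NA_character_,
    population = syllables$population %||% NA_character_
  )
  reps
}
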