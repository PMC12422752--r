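#' Cosine frame-distance matrix between two syllable spectrograms
#'
#' Entry (i, j) is the cosine distance `1 - <X(i), Y(j)> / (|X(i)||Y(j)|)`
#' between the i-th column of `mel_x` and the j-th column of `mel_y`
#' (syllable-preset mel-spectrograms). All-zero frames are assigned distance
#' 1 to everything (flagged via the `zero_frames` attribute).
#'
#' @param mel_x,mel_y `melspec` objects (or matrices) with equal band counts.
#' @return An `N_X x N_Y` matrix of distances in \[0, 2\].
#' @export
frame_distance_matrix <- function(mel_x, mel_y) {
  x <- unclass(mel_x); y <- unclass(mel_y)
  if (nrow(x) != nrow(y)) abort("mel band counts differ")
  d <- cosine_frame_dist_cpp(x, y)
  zx <- colSums(x^2) == 0
  zy <- colSums(y^2) == 0
  if (any(zx) || any(zy)) {
    attr(d, "zero_frames") <- list(x = which(zx), y = which(zy))
  }
  d
}

#' Band-constrained dynamic time warping distance
#'
#' Aligns two frame sequences through the cumulative-cost recurrence
#' `D(i,j) = d(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))` restricted to a
#' Sakoe-Chiba band of half-width `radius * max(N_X, N_Y)` frames centered on
#' the resampled diagonal, and normalizes the optimal path cost by the total
#' frame count: `dist = D(N_X, N_Y) / (N_X + N_Y)`. A band too narrow to
#' connect the corners is widened to the minimum feasible width with a
#' warning.
#'
#' @param d Local-cost matrix, e.g. from [frame_distance_matrix()].
#' @param radius Band radius as a fraction of the longer sequence (default
#'   0.35).
#' @return A `dtw_result` list: `dist`, `cost` (unnormalized), `path`
#'   (two-column index matrix), `n_x`, `n_y`, `radius`.
#' @export
dtw_distance <- function(d, radius = 0.35) {
  d <- unclass(d)
  if (length(d) == 0) abort("empty local-cost matrix")
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  nx <- nrow(d); ny <- ncol(d)
  half <- radius * max(nx, ny)
  res <- dtw_band_cpp(d, half)
  if (!res$feasible) {
    while (!res$feasible) {
      half <- max(half * 1.5, half + 1)
      res <- dtw_band_cpp(d, half)
    }
    warn(sprintf("band too narrow to connect corners; widened to %.1f frames",
                 half))
  }
  structure(
    list(dist = res$cost / (nx + ny), cost = res$cost, path = res$path,
         n_x = nx, n_y = ny, radius = radius),
    class = "dtw_result"
  )
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result: dist %.4f (%d x %d frames, radius %.2f)>\n",
              x$dist, x$n_x, x$n_y, x$radius))
  invisible(x)
}

# Local-cost matrix for a pair of syllable representations: cosine distance
# between mel-spectrogram columns, or absolute difference between f0 samples
# when the representation is a 1-D contour.
local_cost <- function(rep_x, rep_y) {
  if (is.matrix(rep_x) || inherits(rep_x, "melspec")) {
    frame_distance_matrix(rep_x, rep_y)
  } else {
    abs(outer(as.numeric(rep_x), as.numeric(rep_y), "-"))
  }
}

#' Syllable DTW similarity
#'
#' End-to-end similarity between two syllable clips: syllable-preset
#' mel-spectrograms, cosine frame distances, band-constrained DTW,
#' frame-count-normalized cost. Lower is more similar (0 = identical).
#' Setting `representation = "f0"` swaps in the fundamental-frequency contour
#' with absolute-difference local cost behind the same alignment.
#'
#' @param clip_x,clip_y Band-passed [audio_clip()]s holding one syllable
#'   each.
#' @param radius Sakoe-Chiba radius (default 0.35).
#' @param representation `"mel"` (default) or `"f0"`.
#' @return A `dtw_result` (see [dtw_distance()]).
#' @export
syllable_similarity <- function(clip_x, clip_y, radius = 0.35,
                                representation = c("mel", "f0")) {
  representation <- match.arg(representation)
  rep_of <- function(clip) {
    if (representation == "mel") {
      melspec(clip, preset = "syllable")
    } else {
      ct <- f0_zcr(clip)
      ct$f0_hz[ct$voiced]
    }
  }
  dtw_distance(local_cost(rep_of(clip_x), rep_of(clip_y)), radius = radius)
}

#' Pairwise DTW distance matrix over a syllable set
#'
#' @param reps Named list of syllable representations (`melspec` objects or
#'   f0 contour vectors); names are the syllable ids.
#' @param radius Sakoe-Chiba radius (default 0.35).
#' @return A [dist_matrix()] of kind `"acoustic"`.
#' @export
pairwise_matrix <- function(reps, radius = 0.35) {
  n <- length(reps)
  if (n < 2) abort("need at least 2 syllables")
  ids <- names(reps) %||% as.character(seq_len(n))
  if (anyDuplicated(ids)) abort("duplicate syllable ids")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- dtw_distance(local_cost(reps[[i]], reps[[j]]),
                                         radius = radius)$dist
    }
  }
  dist_matrix(d, ids = ids, kind = "acoustic")
}

#' Same-type versus different-type syllable contrast
#'
#' Partitions syllable pairs into "same type, different population" and
#' "different type, same population", summarizes both distance distributions,
#' and tests their difference with Kruskal-Wallis + Dunn. The expectation for
#' a shared-inventory species is that the first group is markedly more
#' similar (smaller distances) than the second.
#'
#' @param dm A [dist_matrix()] over syllables (from [pairwise_matrix()]).
#' @param labels Tibble with columns `id`, `type_label`, `population`
#'   matching the matrix ids.
#' @return A `group_contrast` list: `summary` (tibble of group means/SDs/n),
#'   `test` (a [kruskal_dunn()] result or NULL when degenerate), `pairs`
#'   (tibble of pair distances and groups).
#' @export
group_contrast <- function(dm, labels) {
  ids <- rownames(dm)
  lab <- labels[match(ids, labels$id), ]
  if (any(is.na(lab$id))) abort("labels missing for some matrix ids")
  if (length(unique(lab$type_label)) < 2) abort("need >= 2 type labels")
  if (length(unique(lab$population)) < 2) abort("need >= 2 populations")
  pr <- which(upper.tri(dm), arr.ind = TRUE)
  same_type <- lab$type_label[pr[, 1]] == lab$type_label[pr[, 2]]
  same_pop <- lab$population[pr[, 1]] == lab$population[pr[, 2]]
  grp <- dplyr::case_when(
    same_type & !same_pop ~ "same_type_cross_pop",
    !same_type & same_pop ~ "diff_type_within_pop",
    TRUE ~ NA_character_
  )
  pairs <- tibble(
    id1 = ids[pr[, 1]], id2 = ids[pr[, 2]],
    distance = dm[pr], group = grp
  ) |> dplyr::filter(!is.na(.data$group))
  for (g in c("same_type_cross_pop", "diff_type_within_pop")) {
    if (!any(pairs$group == g)) abort(sprintf("empty partition: %s", g))
  }
  summary <- pairs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$distance), sd = sd(.data$distance),
                     n = dplyr::n(), .groups = "drop")
  test <- if (all(summary$sd == 0) || length(unique(pairs$distance)) == 1) {
    inform("degenerate contrast: all distances identical; test skipped")
    NULL
  } else {
    kruskal_dunn(tibble(value = pairs$distance, group = pairs$group))
  }
  structure(list(summary = summary, test = test, pairs = pairs),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat("<group_contrast>\n")
  print(x$summary)
  if (!is.null(x$test)) {
    cat(sprintf("Kruskal-Wallis H = %.2f, p = %.3g\n", x$test$H, x$test$p))
  }
  invisible(x)
}

#' @export
tidy.group_contrast <- function(x, ...) x$summary
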