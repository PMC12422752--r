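#' Syllable templates
#'
#' A syllable template defines a harmonic tone whose fundamental-frequency
#' contour is a Legendre polynomial over the syllable's normalized time axis
#' \[-1, 1\]. Harmonics are stacked at integer multiples of the fundamental
#' with 1/k amplitude decay. The contour must stay inside the species band
#' (700-3900 Hz) and the duration inside \[0.05, 0.6\] s.
#'
#' @param id Template identifier.
#' @param legendre_coeffs Contour coefficients in Hz (see [legendre_eval()]).
#' @param duration_s Duration in seconds, in \[0.05, 0.6\].
#' @param n_harmonics Number of harmonics (>= 1).
#' @param amp_envelope `"flat"` (rectangular with short cosine ramps) or
#'   `"hann"`.
#' @return A `syllable_template` object.
#' @export
syllable_template <- function(id, legendre_coeffs, duration_s,
                              n_harmonics = 3L,
                              amp_envelope = c("flat", "hann")) {
  amp_envelope <- match.arg(amp_envelope)
  if (!is.numeric(duration_s) || length(duration_s) != 1 ||
      duration_s < 0.05 || duration_s > 0.6) {
    abort("duration_s must lie in [0.05, 0.6] seconds")
  }
  if (n_harmonics < 1) abort("n_harmonics must be >= 1")
  f0 <- legendre_eval(legendre_coeffs, seq(-1, 1, length.out = 512))
  if (any(f0 < 700) || any(f0 > 3900)) {
    abort(sprintf(
      "contour of template '%s' leaves the 700-3900 Hz band (range %.0f-%.0f)",
      id, min(f0), max(f0)), class = "vocrep_range_error")
  }
  structure(
    list(id = as.character(id), legendre_coeffs = as.numeric(legendre_coeffs),
         duration_s = duration_s, n_harmonics = as.integer(n_harmonics),
         amp_envelope = amp_envelope),
    class = "syllable_template"
  )
}

#' Motif grammars
#'
#' An ordered arrangement of 1-5 syllables from a shared inventory, with a
#' silent gap at each junction. The syllable count range reflects typical
#' motif structure in the studied species; longer arrangements can be built
#' by raising `max_len`.
#'
#' @param id Motif identifier.
#' @param syllable_ids Ordered character vector of template ids (1-5 by
#'   default).
#' @param gap_s Gap durations in seconds: scalar (recycled) or one value per
#'   junction.
#' @param max_len Upper bound on the number of syllables (default 5).
#' @return A `motif_grammar` object.
#' @export
motif_grammar <- function(id, syllable_ids, gap_s = 0.06, max_len = 5L) {
  len <- length(syllable_ids)
  if (len < 1 || len > max_len) {
    abort(sprintf("motif must have 1-%d syllables, got %d", max_len, len))
  }
  n_gap <- max(0L, len - 1L)
  if (length(gap_s) == 1) gap_s <- rep(gap_s, n_gap)
  if (length(gap_s) != n_gap) abort("need one gap per junction")
  if (any(gap_s < 0)) abort("gap_s must be >= 0")
  structure(
    list(id = as.character(id), syllable_ids = as.character(syllable_ids),
         gap_s = as.numeric(gap_s)),
    class = "motif_grammar"
  )
}

#' Synthesize one syllable
#'
#' Renders the template as an additive harmonic stack: the instantaneous
#' frequency of the fundamental follows the Legendre contour exactly (phase is
#' the integral of the contour), harmonics sit at integer multiples with 1/k
#' amplitude decay, and harmonics that would exceed Nyquist are dropped.
#'
#' @param template A [syllable_template()].
#' @param rate Sampling rate in Hz.
#' @return An [audio_clip()] of `round(duration_s * rate)` samples with peak
#'   amplitude 0.9.
#' @export
synth_syllable <- function(template, rate = 44100) {
  n <- as.integer(round(template$duration_s * rate))
  u <- if (n == 1) 0 else seq(-1, 1, length.out = n)
  f0 <- legendre_eval(template$legendre_coeffs, u)
  if (any(f0 < 700) || any(f0 > 3900)) {
    abort("contour leaves the 700-3900 Hz band", class = "vocrep_range_error")
  }
  phase <- 2 * pi * cumsum(f0) / rate
  x <- numeric(n)
  for (k in seq_len(template$n_harmonics)) {
    if (k * max(f0) < 0.95 * rate / 2) x <- x + sin(k * phase) / k
  }
  env <- switch(template$amp_envelope,
    hann = sin(pi * (seq_len(n) - 0.5) / n)^2,
    flat = {
      ramp <- min(n %/% 2L, as.integer(round(0.005 * rate)))
      e <- rep(1, n)
      if (ramp > 0) {
        r <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
        e[seq_len(ramp)] <- r
        e[n + 1L - seq_len(ramp)] <- r
      }
      e
    })
  x <- x * env
  x <- 0.9 * x / max(abs(x))
  audio_clip(x, rate, source = sprintf("synth:%s", template$id))
}

#' Synthesize a motif from a grammar
#'
#' Concatenates the grammar's syllables with silent gaps and returns both the
#' waveform and a ground-truth syllable segment table. Boundaries are derived
#' from sample counts, so truth durations are sample-exact.
#'
#' @param grammar A [motif_grammar()].
#' @param inventory List of [syllable_template()] objects (or a list named by
#'   id).
#' @param rate Sampling rate in Hz.
#' @return A list with elements `clip` ([audio_clip()]) and `segments`
#'   (tibble: `begin_s`, `end_s`, `label`, `index_in_motif`).
#' @export
synth_motif <- function(grammar, inventory, rate = 44100) {
  inv <- inventory_by_id(inventory)
  missing <- setdiff(grammar$syllable_ids, names(inv))
  if (length(missing) > 0) {
    abort(sprintf("unknown syllable id(s): %s",
                  paste(missing, collapse = ", ")))
  }
  pieces <- list()
  rows <- list()
  pos <- 0L  # samples emitted so far
  for (i in seq_along(grammar$syllable_ids)) {
    syl <- synth_syllable(inv[[grammar$syllable_ids[i]]], rate)
    n <- length(syl$samples)
    rows[[i]] <- tibble(
      begin_s = pos / rate, end_s = (pos + n) / rate,
      label = grammar$syllable_ids[i], index_in_motif = i - 1L
    )
    pieces[[length(pieces) + 1L]] <- syl$samples
    pos <- pos + n
    if (i < length(grammar$syllable_ids)) {
      gap_n <- as.integer(round(grammar$gap_s[i] * rate))
      pieces[[length(pieces) + 1L]] <- numeric(gap_n)
      pos <- pos + gap_n
    }
  }
  list(
    clip = audio_clip(unlist(pieces), rate,
                      source = sprintf("synth:%s", grammar$id)),
    segments = dplyr::bind_rows(rows)
  )
}

inventory_by_id <- function(inventory) {
  if (inherits(inventory, "syllable_template")) inventory <- list(inventory)
  setNames(inventory, vapply(inventory, function(t) t$id, character(1)))
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise is scaled so that the ratio of signal RMS (measured over
#' `signal_span`, or the whole clip) to noise RMS equals `snr_db`.
#'
#' @param clip An [audio_clip()].
#' @param snr_db Target signal-to-noise ratio in dB; `Inf` adds nothing.
#' @param signal_span Optional `c(begin_s, end_s)` over which signal RMS is
#'   measured (e.g. the voiced region).
#' @param seed Optional integer seed.
#' @return A noisy [audio_clip()].
#' @export
add_noise <- function(clip, snr_db, signal_span = NULL, seed = NULL) {
  if (is.infinite(snr_db)) return(clip)
  x <- clip$samples
  sig <- if (is.null(signal_span)) x else {
    clip_slice(clip, signal_span[1], signal_span[2])$samples
  }
  noise_sd <- rms(sig) / 10^(snr_db / 20)
  noisy <- with_seed_if(seed, x + rnorm(length(x), sd = noise_sd))
  audio_clip(noisy, clip$rate, source = paste0(clip$source, "+noise"))
}

#' Corpus specification
#'
#' Describes a synthetic study: a shared syllable inventory, per-population
#' motif grammars, renditions per motif, noise level, and rendition-to-
#' rendition variability (duration and pitch jitter, mimicking natural
#' variation between repeats of the same motif).
#'
#' @param populations Named list: population name -> list of
#'   [motif_grammar()].
#' @param shared_inventory List of [syllable_template()].
#' @param calls_per_motif Renditions per motif (>= 1).
#' @param snr_db Signal-to-noise ratio of each file in dB.
#' @param sample_rate Hz.
#' @param seed Integer seed; the corpus is bit-reproducible given the seed.
#' @param pad_s Leading/trailing silence around each motif (seconds).
#' @param duration_jitter Relative half-range of per-rendition syllable/gap
#'   duration scaling (0.05 = +-5%).
#' @param f0_jitter Relative half-range of per-rendition pitch scaling.
#' @return A `corpus_spec` object.
#' @export
corpus_spec <- function(populations, shared_inventory, calls_per_motif = 10L,
                        snr_db = 15, sample_rate = 44100, seed = 1L,
                        pad_s = 0.3, duration_jitter = 0.05,
                        f0_jitter = 0.02) {
  if (calls_per_motif < 1) abort("calls_per_motif must be >= 1")
  if (snr_db < -10) {
    warn("snr_db below -10 dB: downstream stages are not expected to work")
  }
  inv <- inventory_by_id(shared_inventory)
  for (pop in names(populations)) {
    for (g in populations[[pop]]) {
      missing <- setdiff(g$syllable_ids, names(inv))
      if (length(missing) > 0) {
        abort(sprintf("grammar '%s' references unknown syllable id(s): %s",
                      g$id, paste(missing, collapse = ", ")))
      }
    }
  }
  structure(
    list(populations = populations, shared_inventory = inv,
         calls_per_motif = as.integer(calls_per_motif), snr_db = snr_db,
         sample_rate = sample_rate, seed = as.integer(seed), pad_s = pad_s,
         duration_jitter = duration_jitter, f0_jitter = f0_jitter),
    class = "corpus_spec"
  )
}

#' Generate a synthetic call corpus with ground truth
#'
#' Each output file embeds one motif rendition in leading/trailing silence
#' plus white Gaussian noise at the spec's SNR (measured over the motif span).
#' Renditions of a motif differ by small duration and pitch jitter. The truth
#' table records population, motif, syllable labels and sample-exact
#' boundaries.
#'
#' @param spec A [corpus_spec()].
#' @param dir Output directory for WAV files; `NULL` keeps clips in memory
#'   only.
#' @return A list with `truth` (segment tibble: file, begin_s, end_s,
#'   unit_type, label, population) and `clips` (named list of [audio_clip()]).
#' @export
synth_corpus <- function(spec, dir = NULL) {
  if (!inherits(spec, "corpus_spec")) abort("spec must be a corpus_spec")
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  rate <- spec$sample_rate
  truth <- list()
  clips <- list()
  file_idx <- 0L
  with_seed_if(spec$seed, {
    for (pop in names(spec$populations)) {
      for (g in spec$populations[[pop]]) {
        for (r in seq_len(spec$calls_per_motif)) {
          file_idx <- file_idx + 1L
          dj <- runif(1, 1 - spec$duration_jitter, 1 + spec$duration_jitter)
          fj <- runif(1, 1 - spec$f0_jitter, 1 + spec$f0_jitter)
          jinv <- lapply(spec$shared_inventory, function(tpl) {
            syllable_template(
              tpl$id, tpl$legendre_coeffs * fj,
              min(0.6, max(0.05, tpl$duration_s * dj)),
              tpl$n_harmonics, tpl$amp_envelope)
          })
          jg <- motif_grammar(g$id, g$syllable_ids, g$gap_s * dj)
          m <- synth_motif(jg, jinv, rate)
          pad_n <- as.integer(round(spec$pad_s * rate))
          x <- c(numeric(pad_n), m$clip$samples, numeric(pad_n))
          clip <- audio_clip(x, rate, source = sprintf("%s_%s_r%02d", pop,
                                                       g$id, r))
          motif_begin <- pad_n / rate
          motif_end <- (pad_n + length(m$clip$samples)) / rate
          clip <- add_noise(clip, spec$snr_db,
                            signal_span = c(motif_begin, motif_end))
          fname <- sprintf("%s_%s_r%02d.wav", pop, g$id, r)
          truth[[file_idx]] <- dplyr::bind_rows(
            tibble(file = fname, begin_s = motif_begin, end_s = motif_end,
                   unit_type = "motif", label = g$id, population = pop),
            dplyr::mutate(m$segments,
                          file = fname,
                          begin_s = .data$begin_s + motif_begin,
                          end_s = .data$end_s + motif_begin,
                          unit_type = "syllable", population = pop,
                          index_in_motif = NULL) |>
              dplyr::select("file", "begin_s", "end_s", "unit_type",
                            "label", "population")
          )
          if (!is.null(dir)) write_wav(clip, file.path(dir, fname))
          clips[[fname]] <- clip
        }
      }
    }
  })
  list(truth = dplyr::bind_rows(truth), clips = clips)
}

#' Default syllable inventory
#'
#' Eight harmonic-tone templates spanning the species band with varied contour
#' shapes (up/down sweeps, chevrons, U-shapes, inflected contours), shared by
#' all populations.
#'
#' @return A list of [syllable_template()] objects.
#' @export
default_inventory <- function() {
  list(
    syllable_template("s1", c(1500, 600, 0, 0, 0), 0.14),
    syllable_template("s2", c(2600, -700, 0, 0, 0), 0.22),
    syllable_template("s3", c(2200, 0, -500, 0, 0), 0.18),
    syllable_template("s4", c(1600, 0, 500, 0, 0), 0.26),
    syllable_template("s5", c(3000, 300, 0, 0, 0), 0.12),
    syllable_template("s6", c(1200, 0, 0, 300, 0), 0.30),
    syllable_template("s7", c(2000, 400, 250, -200, 0), 0.20),
    syllable_template("s8", c(2500, -300, -250, 0, 200), 0.16)
  )
}

#' Default two-population motif grammars
#'
#' Seven motifs per population built from the shared eight-syllable inventory;
#' motif sets are population-disjoint apart from one deliberately shared motif
#' (`mSH`), mirroring the mostly distinct repertoires with occasional overlap
#' seen in wild populations.
#'
#' @return Named list (population -> list of [motif_grammar()]).
#' @export
default_grammars <- function() {
  shared <- motif_grammar("mSH", c("s3", "s5", "s8", "s1"), 0.07)
  list(
    pop1 = list(
      motif_grammar("m01", c("s1", "s3", "s5"), 0.06),
      motif_grammar("m02", c("s2", "s4", "s6", "s8"), 0.05),
      motif_grammar("m03", c("s7", "s1", "s2"), 0.08),
      motif_grammar("m04", c("s4", "s8", "s3", "s6"), 0.06),
      motif_grammar("m05", c("s5", "s7", "s2", "s1", "s4"), 0.05),
      motif_grammar("m06", c("s6", "s2", "s7"), 0.07),
      shared
    ),
    pop2 = list(
      motif_grammar("m07", c("s5", "s1", "s3"), 0.06),
      motif_grammar("m08", c("s8", "s6", "s4", "s2"), 0.05),
      motif_grammar("m09", c("s2", "s1", "s7"), 0.08),
      motif_grammar("m10", c("s6", "s3", "s8", "s4"), 0.06),
      motif_grammar("m11", c("s4", "s1", "s2", "s7", "s5"), 0.05),
      motif_grammar("m12", c("s7", "s2", "s6"), 0.07),
      shared
    )
  )
}

#' Default synthetic study conditions
#'
#' Two populations, the eight shared templates of [default_inventory()],
#' seven motifs per population with one shared (13 distinct motifs), ten
#' renditions per motif at 15 dB SNR.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [corpus_spec()].
#' @return A [corpus_spec()].
#' @export
default_corpus_spec <- function(seed = 1L, ...) {
  corpus_spec(default_grammars(), default_inventory(), seed = seed, ...)
}
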