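tone <- function(f, dur = 0.5, rate = 44100) {
  audio_clip(sin(2 * pi * f * seq(0, dur, length.out = dur * rate)), rate)
}

test_that("f0_zcr tracks tones and chirps and rejects silence", {
  ct <- f0_zcr(tone(1000))
  expect_gt(sum(ct$voiced), 100)
  expect_lt(max(abs(ct$f0_hz[ct$voiced] - 1000) / 1000), 0.02)

  rate <- 44100
  t <- seq(0, 1, length.out = rate)
  chirp <- audio_clip(sin(2 * pi * cumsum(1000 + 1000 * t) / rate), rate)
  ctc <- f0_zcr(chirp)
  v <- which(ctc$voiced)
  expect_equal(ctc$f0_hz[v[1]], 1000, tolerance = 0.03)
  expect_equal(ctc$f0_hz[v[length(v)]], 2000, tolerance = 0.03)

  silent <- f0_zcr(audio_clip(numeric(22050), 44100))
  expect_false(any(silent$voiced))
  expect_error(f0_zcr(audio_clip(numeric(100), 44100)), "frame_len")
})

test_that("YIN verification agrees on clean tones and flags octave traps", {
  clip <- tone(1500)
  rep <- f0_verify_yin(clip, f0_zcr(clip))
  expect_equal(rep$agreement, 1.0)

  # weak fundamental + strong octave: ZCR follows 1800 Hz, YIN the 900 Hz
  # period -> disagreement must be flagged
  rate <- 44100
  t <- seq(0, 0.5, length.out = 0.5 * rate)
  x <- 0.25 * sin(2 * pi * 900 * t) + sin(2 * pi * 1800 * t)
  trap <- audio_clip(x, rate)
  rep2 <- f0_verify_yin(trap, f0_zcr(trap))
  expect_lt(rep2$agreement, 1.0)
  expect_gt(sum(!rep2$frames$agree), 0)

  # unvoiced input gives an empty report
  rep3 <- f0_verify_yin(audio_clip(numeric(22050), 44100),
                        f0_zcr(audio_clip(numeric(22050), 44100)))
  expect_true(is.na(rep3$agreement))
  expect_equal(nrow(rep3$frames), 0)
})

test_that("fit_legendre recovers exact and noisy polynomial contours", {
  cc <- c(2000, 300, -150, 80, 40)
  tt <- seq(0, 0.3, length.out = 120)
  exact <- tibble::tibble(time = tt,
                          f0_hz = legendre_eval(cc, seq(-1, 1,
                                                        length.out = 120)),
                          voiced = TRUE)
  fit <- fit_legendre(exact)
  expect_lt(max(abs(fit$coeffs - cc) / abs(cc)), 1e-6)

  const <- tibble::tibble(time = tt, f0_hz = rep(2000, 120), voiced = TRUE)
  expect_equal(fit_legendre(const)$coeffs, c(2000, 0, 0, 0, 0),
               tolerance = 1e-9)

  set.seed(5)
  noisy <- exact
  noisy$f0_hz <- noisy$f0_hz + rnorm(120, 0, 20)
  fitn <- fit_legendre(noisy)
  expect_lt(max(abs(fitn$coeffs - cc)), 15)
  expect_equal(fitn$rms_residual_hz, 20, tolerance = 0.35)

  few <- exact[1:3, ]
  expect_error(fit_legendre(few), "short by")
})

test_that("audio round-trip recovers template coefficients within 2%", {
  set.seed(21)
  for (i in 1:8) {
    tpl <- random_template(sprintf("rt%d", i))
    syl <- synth_syllable(tpl)
    noisy <- add_noise(syl, 20, seed = 100 + i)
    fit <- fit_legendre(f0_zcr(bandpass(noisy)))
    rel <- abs(fit$coeffs - tpl$legendre_coeffs) / abs(tpl$legendre_coeffs)
    expect_lt(max(rel), 0.02)
  }
})

test_that("motif embeddings have fixed length and documented invariances", {
  fix <- small_corpus_fixture()
  f <- names(fix$bp)[1]
  motif <- fix$corpus$truth[fix$corpus$truth$file == f &
                              fix$corpus$truth$unit_type == "motif", ]
  emb <- motif_embedding(fix$bp[[f]], motif)
  expect_length(emb, 1190)
  expect_true(all(emb >= 0 & emb <= 1))

  # gain invariance
  louder <- fix$bp[[f]]
  louder$samples <- louder$samples * 4
  expect_equal(as.numeric(motif_embedding(louder, motif)), as.numeric(emb),
               tolerance = 1e-10)

  # a ±10% slower rendition of the same motif keeps high cosine similarity
  inv <- default_inventory()
  g <- motif_grammar("m", c("s1", "s3", "s5"), 0.06)
  slow_inv <- lapply(inv, function(tpl) {
    syllable_template(tpl$id, tpl$legendre_coeffs, tpl$duration_s * 1.1,
                      tpl$n_harmonics, tpl$amp_envelope)
  })
  e1 <- as.numeric(motif_embedding(bandpass(synth_motif(g, inv)$clip)))
  e2 <- as.numeric(motif_embedding(bandpass(
    synth_motif(motif_grammar("m", c("s1", "s3", "s5"), 0.066),
                slow_inv)$clip)))
  cosine <- sum(e1 * e2) / sqrt(sum(e1^2) * sum(e2^2))
  expect_gt(cosine, 0.95)

  # silence yields a flagged zero vector
  z <- motif_embedding(audio_clip(numeric(22050), 44100))
  expect_true(all(z == 0))
  expect_true(attr(z, "silent"))
})

test_that("acoustic summaries are correct for tones and gap-invariant", {
  clip <- tone(1500, dur = 0.8)
  syl <- tibble::tibble(begin_s = c(0.1, 0.5), end_s = c(0.3, 0.7))
  s <- acoustic_summary(clip, syl)
  expect_equal(s$f0_min, 1500, tolerance = 0.02)
  expect_equal(s$f0_max, 1500, tolerance = 0.02)
  expect_lt(s$bandwidth, 40)
  expect_equal(s$spectral_centroid, 1500, tolerance = 0.05)
  expect_true(s$f0_min <= s$f0_mean && s$f0_mean <= s$f0_max)

  # gap removal is exact: the same two syllable waveforms, stored with and
  # without an interleaved silent gap, summarize identically
  rate <- 44100
  s1 <- sin(2 * pi * 1400 * seq(0, 0.2, length.out = 0.2 * rate))
  s2 <- sin(2 * pi * 1800 * seq(0, 0.2, length.out = 0.2 * rate))
  with_gap <- audio_clip(c(s1, numeric(0.2 * rate), s2), rate)
  no_gap <- audio_clip(c(s1, s2), rate)
  sg <- acoustic_summary(with_gap,
                         tibble::tibble(begin_s = c(0, 0.4),
                                        end_s = c(0.2, 0.6)))
  sn <- acoustic_summary(no_gap,
                         tibble::tibble(begin_s = c(0, 0.2),
                                        end_s = c(0.2, 0.4)))
  expect_equal(sg$f0_mean, sn$f0_mean, tolerance = 1e-12)
  expect_equal(sg$spectral_centroid, sn$spectral_centroid, tolerance = 1e-12)
  expect_equal(sg$bandwidth, sn$bandwidth, tolerance = 1e-12)

  rate <- 44100
  t <- seq(0, 0.6, length.out = 0.6 * rate)
  chirp <- audio_clip(sin(2 * pi * cumsum(1000 + 1000 * t / 0.6) / rate), rate)
  sc <- acoustic_summary(chirp, tibble::tibble(begin_s = 0, end_s = 0.6))
  expect_equal(sc$f0_min, 1000, tolerance = 0.05)
  expect_equal(sc$f0_max, 2000, tolerance = 0.05)
  expect_equal(sc$bandwidth, 1000, tolerance = 0.1)

  expect_error(acoustic_summary(audio_clip(numeric(44100), 44100),
                                tibble::tibble(begin_s = 0.1, end_s = 0.5)),
               "unvoiced")
})
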