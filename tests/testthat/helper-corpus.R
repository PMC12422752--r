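# Shared synthetic-corpus fixtures, generated once per test session. The
# default corpus mirrors the package's standard study conditions (2
# populations, 8 shared templates, 13 distinct motifs, 10 renditions each,
# 15 dB SNR).

.corpus_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.corpus_cache[[key]])) .corpus_cache[[key]] <- builder()
  .corpus_cache[[key]]
}

default_corpus_fixture <- function() {
  cached("default", function() {
    corpus <- synth_corpus(default_corpus_spec(seed = 1L))
    bp <- lapply(corpus$clips, bandpass)
    segments <- suppressMessages(segment_corpus(corpus$clips))
    pops <- corpus$truth$population[match(names(corpus$clips),
                                          corpus$truth$file)]
    names(pops) <- names(corpus$clips)
    list(corpus = corpus, bp = bp, segments = segments, populations = pops)
  })
}

small_corpus_fixture <- function() {
  cached("small", function() {
    spec <- default_corpus_spec(seed = 3L, calls_per_motif = 2L)
    corpus <- synth_corpus(spec)
    bp <- lapply(corpus$clips, bandpass)
    list(corpus = corpus, bp = bp)
  })
}

# A reusable pair of syllable spectrograms for similarity tests.
syllable_pair_fixture <- function() {
  cached("pair", function() {
    inv <- default_inventory()
    s1 <- bandpass(synth_syllable(inv[[1]]))
    s2 <- bandpass(synth_syllable(inv[[2]]))
    list(a = melspec(s1, preset = "syllable"),
         b = melspec(s2, preset = "syllable"))
  })
}
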