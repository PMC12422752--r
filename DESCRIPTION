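Package: vocrep
Title: Automated Analysis of Avian Vocal Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the vocal repertoires of songbird
    populations from field or synthetic recordings: band-pass conditioning
    and mel-spectrogram noise masking, energy-based motif and syllable
    segmentation, fundamental-frequency contours with Legendre-polynomial
    features, unsupervised repertoire clustering with an entropy-based
    homogeneity score, band-constrained dynamic time warping for syllable
    similarity, permutation inference (Kruskal-Wallis with Dunn post hoc,
    PERMANOVA, Mantel) on distance matrices, and microsatellite
    population-genetic summaries (allele frequencies, heterozygosity, Nei
    distance, Fst, Hardy-Weinberg tests). Includes a synthetic-corpus
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
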