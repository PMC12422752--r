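#' Read a genotype table
#'
#' Long format: columns `individual`, `population`, `locus`, `allele1`,
#' `allele2` (alleles as integer fragment lengths; 0 = missing). Wide
#' (GenAlEx-like) format: `individual`, `population`, then two columns per
#' locus named `<locus>` and `<locus>.2` (or any pair of adjacent columns per
#' locus).
#'
#' @param path CSV path.
#' @param format `"long"` (default) or `"wide"`.
#' @return Tibble in long format with missing alleles as `NA`.
#' @export
read_genotypes <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (format == "wide") {
    locus_cols <- setdiff(names(df), c("individual", "population"))
    if (length(locus_cols) %% 2 != 0) {
      abort("wide layout needs two columns per locus")
    }
    loci <- locus_cols[seq(1, length(locus_cols), by = 2)]
    df <- purrr::map(seq_along(loci), function(i) {
      tibble(individual = df$individual, population = df$population,
             locus = sub("\\.1$", "", loci[i]),
             allele1 = df[[locus_cols[2 * i - 1]]],
             allele2 = df[[locus_cols[2 * i]]])
    }) |> dplyr::bind_rows()
  }
  df |>
    dplyr::mutate(allele1 = dplyr::na_if(as.integer(.data$allele1), 0L),
                  allele2 = dplyr::na_if(as.integer(.data$allele2), 0L))
}

called <- function(gt) {
  dplyr::filter(gt, !is.na(.data$allele1), !is.na(.data$allele2))
}

#' Allele frequencies per population and locus
#'
#' Gene-count frequencies; genotypes with a missing allele are excluded from
#' the denominator, and a population-locus combination with no called
#' genotypes is absent from the output (logged).
#'
#' @param gt Long-format genotype tibble (see [read_genotypes()]).
#' @return Tibble: `population`, `locus`, `allele`, `freq`, `n` (called
#'   genotypes).
#' @export
allele_freqs <- function(gt) {
  if (nrow(gt) == 0) abort("empty genotype table")
  all_combos <- dplyr::distinct(gt, .data$population, .data$locus)
  cc <- called(gt)
  out <- cc |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::count(.data$population, .data$locus, .data$allele) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(freq = .data$n / sum(.data$n), n = sum(.data$n) / 2) |>
    dplyr::ungroup()
  dropped <- dplyr::anti_join(all_combos, out, by = c("population", "locus"))
  if (nrow(dropped) > 0) {
    inform(sprintf("no called genotypes for %d population x locus combination(s)",
                   nrow(dropped)))
  }
  out
}

#' Expected and observed heterozygosity
#'
#' `He = 1 - sum p_a^2` from allele frequencies; `Ho` = fraction of called
#' genotypes with two different alleles.
#'
#' @param freqs Output of [allele_freqs()].
#' @param gt The genotype table the frequencies came from.
#' @return Tibble: `population`, `locus`, `He`, `Ho`, `n`.
#' @export
heterozygosity <- function(freqs, gt) {
  he <- freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(He = 1 - sum(.data$freq^2), n = .data$n[1],
                     .groups = "drop")
  ho <- called(gt) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(Ho = mean(.data$allele1 != .data$allele2),
                     .groups = "drop")
  dplyr::left_join(he, ho, by = c("population", "locus")) |>
    dplyr::select("population", "locus", "He", "Ho", "n")
}

freq_vectors <- function(freqs, pop, loc) {
  f <- freqs[freqs$population == pop & freqs$locus == loc, ]
  setNames(f$freq, f$allele)
}

#' Nei's standard genetic distance between two populations
#'
#' `D = -ln(J_ab / sqrt(J_a J_b))` where the J terms are arithmetic means
#' over shared loci of `sum p_a p_b`, `sum p_a^2` and `sum p_b^2`. Loci typed
#' in only one population are dropped from the averages (logged). Populations
#' with no shared alleles anywhere return `Inf`.
#'
#' @param freqs Output of [allele_freqs()].
#' @param pop_a,pop_b Population names.
#' @return Nei (1972) standard distance (>= 0, possibly `Inf`).
#' @export
nei_distance <- function(freqs, pop_a, pop_b) {
  loci_a <- unique(freqs$locus[freqs$population == pop_a])
  loci_b <- unique(freqs$locus[freqs$population == pop_b])
  shared <- intersect(loci_a, loci_b)
  if (length(shared) == 0) abort("no locus typed in both populations")
  if (length(shared) < length(union(loci_a, loci_b))) {
    inform(sprintf("dropping %d locus/loci not typed in both populations",
                   length(union(loci_a, loci_b)) - length(shared)))
  }
  j <- purrr::map(shared, function(loc) {
    pa <- freq_vectors(freqs, pop_a, loc)
    pb <- freq_vectors(freqs, pop_b, loc)
    alleles <- union(names(pa), names(pb))
    pa <- pa[alleles]; pa[is.na(pa)] <- 0
    pb <- pb[alleles]; pb[is.na(pb)] <- 0
    c(jab = sum(pa * pb), ja = sum(pa^2), jb = sum(pb^2))
  })
  jm <- colMeans(do.call(rbind, j))
  if (jm["jab"] == 0) return(Inf)
  unname(-log(jm["jab"] / sqrt(jm["ja"] * jm["jb"])))
}

#' Wright's fixation index from expected heterozygosities
#'
#' Per locus, `Fst = (Ht - mean Hs) / Ht` with `Hs` the within-population
#' expected heterozygosities and `Ht` the expected heterozygosity of the
#' pooled (unweighted mean) allele frequencies; the overall value averages
#' over polymorphic loci. Loci monomorphic everywhere are excluded (logged).
#'
#' @param freqs Output of [allele_freqs()].
#' @return List: `per_locus` (tibble: locus, Hs, Ht, Fst), `overall`.
#' @export
fst <- function(freqs) {
  pops <- unique(freqs$population)
  if (length(pops) < 2) abort("need >= 2 populations")
  per <- purrr::map(unique(freqs$locus), function(loc) {
    fl <- dplyr::filter(freqs, .data$locus == loc)
    pops_here <- unique(fl$population)
    alleles <- unique(fl$allele)
    pmat <- vapply(pops_here, function(p) {
      v <- freq_vectors(fl, p, loc)[as.character(alleles)]
      v[is.na(v)] <- 0
      v
    }, numeric(length(alleles)))
    pmat <- matrix(pmat, nrow = length(alleles))
    hs <- mean(1 - colSums(pmat^2))
    pbar <- rowMeans(pmat)
    ht <- 1 - sum(pbar^2)
    tibble(locus = loc, Hs = hs, Ht = ht,
           Fst = if (ht > 0) (ht - hs) / ht else NA_real_)
  }) |> dplyr::bind_rows()
  if (any(is.na(per$Fst))) {
    inform(sprintf("%d monomorphic locus/loci excluded from overall Fst",
                   sum(is.na(per$Fst))))
  }
  list(per_locus = per, overall = mean(per$Fst, na.rm = TRUE))
}

#' Chi-square test of Hardy-Weinberg proportions
#'
#' Observed genotype counts against HWE expectations from the sample allele
#' frequencies; df = g(g-1)/2 for g alleles. Monomorphic loci are skipped.
#'
#' @param gt Genotype tibble.
#' @param population,locus Which population x locus to test.
#' @return List: `chi2`, `df`, `p`, `n`; or `NULL` (with a message) when the
#'   locus is monomorphic in that population.
#' @export
hwe_chisq <- function(gt, population, locus) {
  cc <- called(gt)
  cc <- cc[cc$population == population & cc$locus == locus, ]
  n <- nrow(cc)
  if (n < 5) inform(sprintf("only %d called genotypes; HWE test is weak", n))
  alleles <- sort(unique(c(cc$allele1, cc$allele2)))
  g <- length(alleles)
  if (g < 2) {
    inform("monomorphic locus: HWE test skipped")
    return(NULL)
  }
  p <- vapply(alleles, function(a) {
    (sum(cc$allele1 == a) + sum(cc$allele2 == a)) / (2 * n)
  }, numeric(1))
  names(p) <- alleles
  # observed and expected counts per unordered genotype
  chi2 <- 0
  for (i in seq_len(g)) {
    for (j in i:g) {
      obs <- sum((cc$allele1 == alleles[i] & cc$allele2 == alleles[j]) |
                   (cc$allele1 == alleles[j] & cc$allele2 == alleles[i] &
                      i != j))
      expct <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
      if (expct > 0) chi2 <- chi2 + (obs - expct)^2 / expct
    }
  }
  df <- g * (g - 1) / 2
  list(chi2 = unname(chi2), df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       n = n)
}

#' Genetic distance matrix over all populations
#'
#' @param freqs Output of [allele_freqs()].
#' @return A [dist_matrix()] of kind `"genetic"` (Nei standard distance).
#' @export
genetic_dist_matrix <- function(freqs) {
  pops <- sort(unique(freqs$population))
  n <- length(pops)
  if (n < 2) abort("need >= 2 populations")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- nei_distance(freqs, pops[i], pops[j])
    }
  }
  dist_matrix(d, ids = pops, kind = "genetic")
}

#' Simulate microsatellite genotypes for diverged populations
#'
#' Populations drift from shared ancestral allele frequencies under a
#' Balding-Nichols model: population frequencies are Dirichlet-distributed
#' around the ancestral frequencies with concentration `(1 - divergence) /
#' divergence`, so larger `divergence` (0..1) yields more differentiated
#' populations.
#'
#' @param n_pops Number of populations.
#' @param n_per_pop Individuals per population.
#' @param n_loci Number of loci.
#' @param n_alleles Alleles per locus.
#' @param divergence Drift parameter in (0, 1); may be a vector with one
#'   value per population.
#' @param positions Optional per-population positions in \[0, 1\] along a
#'   geographic axis. When given, population frequencies interpolate between
#'   two drifted endpoint profiles (isolation by distance): pairwise genetic
#'   distance then grows with pairwise positional distance.
#' @param seed Integer seed.
#' @return Long-format genotype tibble.
#' @export
sim_genotypes <- function(n_pops = 2L, n_per_pop = 30L, n_loci = 5L,
                          n_alleles = 6L, divergence = 0.1,
                          positions = NULL, seed = 1L) {
  if (any(divergence <= 0 | divergence >= 1)) {
    abort("divergence must lie in (0, 1)")
  }
  if (!is.null(positions) && length(positions) != n_pops) {
    abort("need one position per population")
  }
  divergence <- rep_len(divergence, n_pops)
  with_seed_if(seed, {
    rows <- list()
    for (loc in seq_len(n_loci)) {
      anc <- rgamma(n_alleles, 1)
      anc <- anc / sum(anc)
      ends <- NULL
      if (!is.null(positions)) {
        theta <- (1 - divergence[1]) / divergence[1]
        ends <- replicate(2, {
          e <- rgamma(n_alleles, anc * theta)
          e / sum(e)
        })
      }
      for (p in seq_len(n_pops)) {
        if (is.null(positions)) {
          theta <- (1 - divergence[p]) / divergence[p]
          pf <- rgamma(n_alleles, anc * theta)
          pf <- pf / sum(pf)
        } else {
          w <- positions[p]
          pf <- (1 - w) * ends[, 1] + w * ends[, 2]
        }
        draws <- matrix(sample.int(n_alleles, 2 * n_per_pop, replace = TRUE,
                                   prob = pf), ncol = 2)
        rows[[length(rows) + 1L]] <- tibble(
          individual = sprintf("p%d_i%02d", p, seq_len(n_per_pop)),
          population = sprintf("pop%d", p),
          locus = sprintf("L%02d", loc),
          allele1 = 100L + 2L * draws[, 1],
          allele2 = 100L + 2L * draws[, 2]
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
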