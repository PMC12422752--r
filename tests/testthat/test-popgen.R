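toy_gt <- function() {
  tibble::tibble(
    individual = c("i1", "i2"),
    population = "p1",
    locus = "L1",
    allele1 = c(100L, 100L),
    allele2 = c(100L, 102L)
  )
}

test_that("allele frequencies use gene counts and drop missing genotypes", {
  freqs <- allele_freqs(toy_gt())
  expect_equal(freqs$freq[freqs$allele == 100], 0.75)
  expect_equal(freqs$freq[freqs$allele == 102], 0.25)
  expect_equal(unique(freqs$n), 2)

  gt <- toy_gt()
  gt$allele1[2] <- NA
  f2 <- allele_freqs(gt)
  expect_equal(f2$freq[f2$allele == 100], 1)

  gt_all_na <- toy_gt()
  gt_all_na$allele1 <- NA_integer_
  expect_message(f3 <- allele_freqs(gt_all_na), "no called")
  expect_equal(nrow(f3), 0)
  expect_error(allele_freqs(toy_gt()[0, ]), "empty")
})

test_that("heterozygosity matches direct formulas", {
  gt <- toy_gt()
  freqs <- allele_freqs(gt)
  h <- heterozygosity(freqs, gt)
  expect_equal(h$He, 1 - (0.75^2 + 0.25^2))  # = 0.375
  expect_equal(h$Ho, 0.5)

  mono <- gt
  mono$allele2 <- 100L
  hm <- heterozygosity(allele_freqs(mono), mono)
  expect_equal(hm$He, 0)
  expect_equal(hm$Ho, 0)

  # two alleles at 0.5/0.5
  even <- tibble::tibble(individual = c("a", "b"), population = "p",
                         locus = "L", allele1 = c(100L, 102L),
                         allele2 = c(102L, 100L))
  expect_equal(heterozygosity(allele_freqs(even), even)$He, 0.5)
})

test_that("Nei distance reproduces hand arithmetic and its invariants", {
  mk <- function(p1_a, p2_a) {
    tibble::tibble(
      population = rep(c("p1", "p2"), each = 2),
      locus = "L1",
      allele = c(100, 102, 100, 102),
      freq = c(p1_a, 1 - p1_a, p2_a, 1 - p2_a),
      n = 50
    )
  }
  f <- mk(0.8, 0.2)
  d <- nei_distance(f, "p1", "p2")
  expect_equal(d, -log(0.32 / 0.68), tolerance = 1e-12)
  expect_equal(d, 0.7537718, tolerance = 1e-6)
  expect_equal(nei_distance(f, "p2", "p1"), d, tolerance = 1e-12)
  expect_equal(nei_distance(mk(0.8, 0.8), "p1", "p2"), 0, tolerance = 1e-12)

  disjoint <- tibble::tibble(
    population = rep(c("p1", "p2"), each = 1),
    locus = "L1", allele = c(100, 104), freq = c(1, 1), n = 10
  )
  expect_equal(nei_distance(disjoint, "p1", "p2"), Inf)
})

test_that("Fst matches the worked example and stays within [0, 1]", {
  f <- tibble::tibble(
    population = rep(c("p1", "p2"), each = 2),
    locus = "L1", allele = c(100, 102, 100, 102),
    freq = c(1, 0, 0.5, 0.5), n = 20
  )
  res <- fst(f)
  expect_equal(res$per_locus$Hs, 0.25)
  expect_equal(res$per_locus$Ht, 0.375)
  expect_equal(res$overall, 1 / 3, tolerance = 1e-12)

  same <- f
  same$freq <- c(0.5, 0.5, 0.5, 0.5)
  expect_equal(fst(same)$overall, 0, tolerance = 1e-12)

  fixed <- f
  fixed$freq <- c(1, 0, 0, 1)
  expect_equal(fst(fixed)$overall, 1, tolerance = 1e-12)

  set.seed(71)
  gt <- sim_genotypes(n_pops = 3, divergence = 0.2, seed = 5)
  res2 <- fst(allele_freqs(gt))
  expect_true(all(res2$per_locus$Fst >= 0 & res2$per_locus$Fst <= 1,
                  na.rm = TRUE))
})

test_that("HWE chi-square rejects an all-heterozygote sample", {
  het <- tibble::tibble(
    individual = sprintf("i%02d", 1:50), population = "p", locus = "L",
    allele1 = 100L, allele2 = 102L
  )
  res <- hwe_chisq(het, "p", "L")
  expect_equal(res$chi2, 50, tolerance = 1e-12)  # expected 12.5/25/12.5
  expect_equal(res$df, 1)
  expect_lt(res$p, 0.001)

  # near-exact HWE proportions: tiny statistic
  hwe <- tibble::tibble(
    individual = sprintf("i%03d", 1:100), population = "p", locus = "L",
    allele1 = c(rep(100L, 25), rep(100L, 50), rep(102L, 25)),
    allele2 = c(rep(100L, 25), rep(102L, 50), rep(102L, 25))
  )
  res2 <- hwe_chisq(hwe, "p", "L")
  expect_lt(res2$chi2, 1e-10)
  expect_gt(res2$p, 0.99)

  mono <- dplyr::mutate(het, allele2 = 100L)
  expect_message(res3 <- hwe_chisq(mono, "p", "L"), "monomorphic")
  expect_null(res3)
})

test_that("simulated divergence drives Nei distance monotonically", {
  thetas <- c(0.02, 0.05, 0.1, 0.2, 0.35, 0.6)
  cors <- vapply(1:5, function(s) {
    d <- vapply(thetas, function(th) {
      gt <- sim_genotypes(n_pops = 2, n_per_pop = 30, n_loci = 10,
                          divergence = th, seed = 1000 + s)
      nei_distance(allele_freqs(gt), "pop1", "pop2")
    }, numeric(1))
    cor(d, thetas, method = "spearman")
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
})

test_that("genotype readers handle long and wide layouts", {
  long_path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    individual = c("i1", "i1"), population = "p1",
    locus = c("L1", "L2"), allele1 = c(100L, 0L), allele2 = c(102L, 104L)
  ), long_path)
  gt <- read_genotypes(long_path)
  expect_true(is.na(gt$allele1[2]))

  wide_path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    individual = c("i1", "i2"), population = "p1",
    L1 = c(100L, 102L), L1.2 = c(102L, 102L),
    L2 = c(104L, 0L), L2.2 = c(104L, 106L)
  ), wide_path)
  gtw <- read_genotypes(wide_path, format = "wide")
  expect_equal(nrow(gtw), 4)
  expect_setequal(unique(gtw$locus), c("L1", "L2"))
  expect_true(is.na(gtw$allele1[gtw$individual == "i2" & gtw$locus == "L2"]))

  # genetic distance matrix round-trips through the square-CSV dialect
  freqs <- allele_freqs(sim_genotypes(n_pops = 3, divergence = 0.3, seed = 2))
  gd <- genetic_dist_matrix(freqs)
  p <- withr::local_tempfile(fileext = ".csv")
  write_dist_csv(gd, p)
  back <- read_dist_csv(p, kind = "genetic")
  expect_equal(unclass(back), unclass(gd), tolerance = 1e-12,
               ignore_attr = TRUE)
})
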