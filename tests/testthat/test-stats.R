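test_that("Kruskal-Wallis + Dunn reproduce rank arithmetic", {
  gs <- tibble::tibble(value = c(1, 2, 3, 11, 12, 13, 21, 22, 23),
                       group = rep(c("a", "b", "c"), each = 3))
  res <- kruskal_dunn(gs)
  expect_equal(res$H, 7.2, tolerance = 1e-12)  # maximal H for n = 9, no ties
  expect_lt(res$p, 0.05)
  expect_equal(nrow(res$pairwise), 3)
  # extreme groups differ most
  ac <- res$pairwise[res$pairwise$group1 == "a" & res$pairwise$group2 == "c", ]
  expect_equal(abs(ac$z), max(abs(res$pairwise$z)))
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p))

  # identical values: H = 0 under the tie-correction guard
  flat <- tibble::tibble(value = rep(5, 9), group = rep(c("a", "b", "c"), 3))
  res0 <- kruskal_dunn(flat)
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)

  expect_error(kruskal_dunn(tibble::tibble(value = 1:3, group = rep("a", 3))),
               "2 non-empty")
  expect_equal(glance(res)$H, 7.2)
})

test_that("Kruskal-Wallis type-I error is calibrated under the null", {
  set.seed(31)
  rejections <- vapply(1:1000, function(i) {
    gs <- tibble::tibble(value = rnorm(24), group = rep(c("a", "b", "c"), 8))
    kruskal_dunn(gs)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("PERMANOVA separates planted groups and matches vegan", {
  set.seed(41)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  dm <- dist_matrix(as.matrix(dist(x)), ids = sprintf("i%02d", 1:40))
  groups <- rep(c("a", "b"), each = 20)
  res <- permanova(dm, groups, n_perm = 999, seed = 8)
  expect_lte(res$p, 0.001)
  expect_gt(res$pseudo_F, 10)

  # observed pseudo-F equals vegan's
  veg <- vegan::adonis2(as.dist(unclass(dm)) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(res$pseudo_F, veg$F[1], tolerance = 1e-10)

  # equal distances: exchangeable null, p near 1
  deq <- dist_matrix(matrix(1, 12, 12) - diag(12),
                     ids = sprintf("e%02d", 1:12))
  req <- permanova(deq, rep(c("a", "b"), 6), n_perm = 499, seed = 3)
  expect_true(is.finite(req$pseudo_F))
  expect_gt(req$p, 0.5)

  expect_error(permanova(dm, rep("a", 40)), ">= 2 groups")
})

test_that("PERMANOVA p is reproducible and reorder-invariant", {
  set.seed(42)
  x <- matrix(rnorm(60), 20, 3)
  dm <- dist_matrix(as.matrix(dist(x)), ids = sprintf("i%02d", 1:20))
  g <- rep(c("a", "b"), 10)
  p1 <- permanova(dm, g, n_perm = 499, seed = 7)$p
  p2 <- permanova(dm, g, n_perm = 499, seed = 7)$p
  expect_identical(p1, p2)
  ord <- sample(20)
  p3 <- permanova(dist_matrix(unclass(dm)[ord, ord],
                              ids = rownames(dm)[ord]), g[ord],
                  n_perm = 499, seed = 7)$p
  expect_equal(p1, p3, tolerance = 0.05)
})

test_that("Mantel r is exact for linear relations; p matches enumeration", {
  set.seed(51)
  x <- matrix(rnorm(12), 4)
  a <- as.matrix(dist(x))
  rownames(a) <- colnames(a) <- letters[1:4]
  dma <- dist_matrix(a, kind = "acoustic")
  dmb2 <- dist_matrix(2 * a, kind = "genetic")
  res <- mantel_test(dma, dmb2)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_true(res$exact)
  expect_equal(res$n_perm, 24)
  expect_equal(res$p, mantel_exact_oracle(a, 2 * a), tolerance = 1e-12)
  expect_equal(res$p, 1 / 24, tolerance = 1e-12)  # smallest attainable at n=4

  anti <- max(a) + 1 - a
  diag(anti) <- 0
  res_neg <- mantel_test(dma, dist_matrix(anti, kind = "genetic"))
  expect_equal(res_neg$r, -1, tolerance = 1e-12)

  # random 4x4 pairs: exact p equals the brute-force oracle
  for (i in 1:20) {
    b <- as.matrix(dist(matrix(rnorm(12), 4)))
    dimnames(b) <- dimnames(a)
    got <- mantel_test(dma, dist_matrix(b, kind = "genetic"))
    expect_equal(got$p, mantel_exact_oracle(a, b), tolerance = 1e-12)
  }

  # symmetry in the statistic
  b <- as.matrix(dist(matrix(rnorm(12), 4)))
  dimnames(b) <- dimnames(a)
  expect_equal(mantel_test(dma, dist_matrix(b))$r,
               mantel_test(dist_matrix(b), dma)$r, tolerance = 1e-12)

  bad <- dist_matrix(b, ids = c("x", "y", "z", "w"))
  expect_error(mantel_test(dma, bad), "ids differ")
  flat <- dist_matrix(matrix(1, 4, 4) - diag(4), ids = letters[1:4])
  expect_error(mantel_test(dma, flat), "zero variance")
})

test_that("Mantel agrees with vegan on larger matrices", {
  set.seed(61)
  a <- as.matrix(dist(matrix(rnorm(30), 10)))
  b <- as.matrix(dist(matrix(rnorm(30), 10)))
  ids <- sprintf("s%02d", 1:10)
  dimnames(a) <- dimnames(b) <- list(ids, ids)
  got <- mantel_test(dist_matrix(a), dist_matrix(b), n_perm = 9999, seed = 5)
  veg <- vegan::mantel(as.dist(a), as.dist(b), permutations = 9999)
  expect_equal(got$r, unname(veg$statistic), tolerance = 1e-10)
  expect_equal(got$p, veg$signif, tolerance = 0.02)
})
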