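make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
            centers[i, ], "+")
    }))
    list(x = m, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

test_that("PCA reduction captures planted low-rank structure", {
  set.seed(2)
  basis <- matrix(rnorm(10 * 100), 10, 100)
  scores <- matrix(rnorm(60 * 10), 60, 10) %*% basis
  x <- scores + matrix(rnorm(6000, sd = 1e-3), 60, 100)
  red <- reduce_pca(x, dims = 10)
  expect_gte(sum(attr(red, "explained_variance")), 0.99)
  expect_equal(ncol(red), 10)

  expect_error(reduce_pca(x[1:10, ], dims = 10), "more than")
  red9 <- reduce_pca(x[1:10, ], dims = 9)
  expect_equal(nrow(red9), 10)

  # duplicated data spans the same subspace (up to sign)
  red2 <- reduce_pca(rbind(x, x), dims = 3)
  v1 <- abs(cor(red[, 1:3][[1]], red2[1:60, ][[1]]))
  expect_gt(v1, 0.999)
})

test_that("k-means recovers separated blobs and is seed-deterministic", {
  blobs <- make_blobs(30, diag(3) * 10)
  cl <- cluster_kmeans(blobs$x, k = 3, seed = 11)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, blobs$labels), 1)
  expect_gt(cl$mean_silhouette, 0.7)
  cl2 <- cluster_kmeans(blobs$x, k = 3, seed = 11)
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(cluster_kmeans(blobs$x, k = 1), ">= 2")
  expect_error(cluster_kmeans(blobs$x[1:4, ], k = 10), "exceeds")

  g <- glance(cl)
  expect_equal(g$k, 3)
  expect_equal(sum(tidy(cl)$size), 90)
})

test_that("silhouette-based k selection finds the planted cluster count", {
  centers <- matrix(rnorm(6 * 4, sd = 8), 6, 4)
  blobs <- make_blobs(15, centers, sd = 0.4, seed = 3)
  sel <- select_k(blobs$x, k_range = 2:10, seed = 5)
  expect_equal(sel$k_best, 6)
  sil_at <- function(k) sel$curve$silhouette[sel$curve$k == k]
  expect_gt(sil_at(6), sil_at(2))
  expect_gt(sil_at(6), sil_at(10))
  expect_error(select_k(blobs$x, k_range = integer(0)), "empty")

  # a single blob: no structure, k* falls at the range minimum
  single <- make_blobs(40, matrix(0, 1, 4), sd = 1, seed = 8)
  sel1 <- select_k(single$x, k_range = 2:6, seed = 5)
  expect_lt(max(sel1$curve$silhouette), 0.35)
})

test_that("homogeneity matches its definition on worked examples", {
  expect_equal(homogeneity(c("A", "A", "B", "B"), c(0, 0, 1, 1)), 1)
  expect_equal(homogeneity(c("A", "A", "B", "B"), c(0, 1, 0, 1)), 0)
  h <- homogeneity(c("A", "A", "B"), c(0, 1, 1))
  expect_equal(h, 1 - (2 / 3 * log(2)) / (-(2 / 3) * log(2 / 3) -
                                            (1 / 3) * log(1 / 3)),
               tolerance = 1e-12)
  expect_equal(h, 0.2740174, tolerance = 1e-6)
  # single-class convention
  expect_equal(homogeneity(c("A", "A"), c(0, 1)), 1)
  expect_error(homogeneity(character(0), integer(0)), "empty")
})

test_that("homogeneity equals brute force and is relabeling-invariant", {
  set.seed(13)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    classes <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
    clusters <- sample(seq_len(sample(2:5, 1)), n, replace = TRUE)
    h <- homogeneity(classes, clusters)
    expect_lt(abs(h - homogeneity_oracle(classes, clusters)), 1e-12)
    expect_gte(h, -1e-12)
    expect_lte(h, 1 + 1e-12)
    # invariance to relabeling either side
    perm <- sample(100)
    expect_equal(homogeneity(classes, perm[clusters]), h, tolerance = 1e-12)
    cls_map <- setNames(sample(LETTERS), letters)
    expect_equal(homogeneity(cls_map[classes], clusters), h,
                 tolerance = 1e-12)
  }
})

test_that("qc_sample caps draws at cluster size and pins the centroid item", {
  blobs <- make_blobs(10, diag(2) * 12, seed = 4)
  cl <- cluster_kmeans(blobs$x, k = 2, seed = 2)
  man <- qc_sample(cl, n_random = 30, n_central = 30, seed = 6)
  counts <- table(man$cluster, man$kind)
  expect_true(all(counts == 10))  # capped at cluster size
  # nearest-to-centroid is first central item
  for (k in 1:2) {
    central <- man[man$cluster == k & man$kind == "central", ]
    expect_equal(central$dist_to_centroid, sort(central$dist_to_centroid))
  }
  man2 <- qc_sample(cl, n_random = 30, n_central = 30, seed = 6)
  expect_identical(man, man2)
})
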