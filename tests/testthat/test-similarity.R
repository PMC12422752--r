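test_that("cosine frame distances match hand-computed values", {
  x <- cbind(c(1, 1, 0), c(1, 0, 0))
  y <- cbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  d <- frame_distance_matrix(x, y)
  expect_equal(d[1, 1], 0, tolerance = 1e-12)          # identical columns
  expect_equal(d[2, 2], 1, tolerance = 1e-12)          # orthogonal columns
  expect_equal(d[2, 1], 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_true(all(d[, 3] == 1))                        # zero column convention
  expect_equal(attr(d, "zero_frames")$y, 3)
  expect_error(frame_distance_matrix(x, matrix(1, 4, 2)), "band counts")
})

test_that("banded DTW reproduces worked single-cell and identity cases", {
  expect_equal(dtw_distance(matrix(1, 1, 1))$dist, 0.5)

  p <- syllable_pair_fixture()
  self <- dtw_distance(frame_distance_matrix(p$a, p$a))
  expect_equal(self$dist, 0, tolerance = 1e-12)
  expect_true(all(self$path[, 1] == self$path[, 2]))  # diagonal path
})

test_that("banded DTW equals exhaustive path enumeration (radius 1)", {
  set.seed(17)
  for (i in 1:200) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    d <- matrix(runif(nx * ny), nx, ny)
    got <- dtw_distance(d, radius = 1.0)
    expect_lt(abs(got$cost - dtw_enum_oracle(d)), 1e-12)
    expect_equal(got$dist, got$cost / (nx + ny))
    # path is monotone and connects the corners
    expect_equal(got$path[1, ], c(1, 1))
    expect_equal(got$path[nrow(got$path), ], c(nx, ny))
    expect_true(all(diff(got$path[, 1]) >= 0))
    expect_true(all(diff(got$path[, 2]) >= 0))
  }
})

test_that("DTW is symmetric, band-monotone and scale-invariant", {
  p <- syllable_pair_fixture()
  d_ab <- frame_distance_matrix(p$a, p$b)
  d_ba <- frame_distance_matrix(p$b, p$a)
  expect_equal(d_ab, t(d_ba), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(dtw_distance(d_ab)$dist, dtw_distance(d_ba)$dist,
               tolerance = 1e-10)

  # widening the band never increases the distance
  radii <- c(0.1, 0.2, 0.35, 0.6, 1.0)
  dists <- vapply(radii, function(r) dtw_distance(d_ab, radius = r)$dist,
                  numeric(1))
  expect_true(all(diff(dists) <= 1e-12))

  # cosine local cost is invariant to uniform positive rescaling
  d_scaled <- frame_distance_matrix(unclass(p$a) * 7, unclass(p$b) * 0.2)
  expect_equal(dtw_distance(d_scaled)$dist, dtw_distance(d_ab)$dist,
               tolerance = 1e-10)

  # an infeasibly narrow band is widened with a warning
  skinny <- matrix(runif(40), 2, 20)
  expect_warning(res <- dtw_distance(skinny, radius = 0.01), "widened")
  expect_true(is.finite(res$dist))
})

test_that("pairwise matrices are symmetric with zero diagonal", {
  fix <- small_corpus_fixture()
  syls <- dplyr::filter(fix$corpus$truth, unit_type == "syllable")
  pick <- syls[1:6, ]
  reps <- syllable_reps(fix$bp, pick, already_bandpassed = TRUE)
  reps$dup <- reps[[1]]  # exact copy: distance 0 off-diagonal
  dm <- pairwise_matrix(reps)
  expect_equal(nrow(dm), 7)
  expect_true(all(diag(dm) == 0))
  expect_equal(unclass(dm), t(unclass(dm)), tolerance = 1e-12)
  expect_lt(dm[1, 7], 1e-12)
  expect_error(pairwise_matrix(reps[c(1, 1)]), "duplicate")
  expect_error(pairwise_matrix(reps[1]), "at least 2")
})

test_that("the f0-contour representation drops into the same alignment", {
  inv <- default_inventory()
  a <- bandpass(synth_syllable(inv[[1]]))
  b <- bandpass(synth_syllable(inv[[2]]))
  r_mel <- syllable_similarity(a, b)
  r_f0 <- syllable_similarity(a, b, representation = "f0")
  expect_gt(r_mel$dist, 0)
  expect_gt(r_f0$dist, 0)
  expect_equal(syllable_similarity(a, a, representation = "f0")$dist, 0,
               tolerance = 1e-12)
})

test_that("group_contrast separates shared from population-specific types", {
  fix <- small_corpus_fixture()
  syls <- dplyr::filter(fix$corpus$truth, unit_type == "syllable")
  pick <- syls |>
    dplyr::group_by(population, label) |>
    dplyr::slice_head(n = 2) |>
    dplyr::ungroup()
  reps <- syllable_reps(fix$bp, pick, already_bandpassed = TRUE)
  dm <- pairwise_matrix(reps)
  gc_res <- group_contrast(dm, attr(reps, "labels"))
  sm <- gc_res$summary
  same <- sm$mean[sm$group == "same_type_cross_pop"]
  diff <- sm$mean[sm$group == "diff_type_within_pop"]
  expect_lt(same, diff)
  expect_lt(gc_res$test$p, 0.001)

  # degenerate case: all syllables identical
  reps_same <- setNames(rep(reps[1], 4), paste0("r", 1:4))
  dm0 <- pairwise_matrix(reps_same)
  lab0 <- tibble::tibble(id = paste0("r", 1:4),
                         type_label = c("a", "a", "b", "b"),
                         population = c("p", "q", "p", "q"))
  expect_message(gc0 <- group_contrast(dm0, lab0), "degenerate")
  expect_null(gc0$test)
  expect_lt(max(abs(gc0$summary$mean)), 1e-12)
})
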