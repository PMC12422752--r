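# Extract a numeric feature matrix from a tibble with an `embedding`
# list-column, a tibble of numeric columns, or a plain matrix.
feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    if ("embedding" %in% names(x)) {
      return(do.call(rbind, x$embedding))
    }
    num <- vapply(x, is.numeric, logical(1))
    return(as.matrix(x[, num, drop = FALSE]))
  }
  abort("cannot interpret `x` as a feature matrix")
}

#' Principal-component reduction of feature vectors
#'
#' Mean-centered projection onto the leading principal axes (default 10, the
#' dimensionality used for repertoire clustering).
#'
#' @param x Feature matrix, tibble of numeric columns, or tibble with an
#'   `embedding` list-column (rows = vocalizations).
#' @param dims Number of components to keep (default 10).
#' @return Tibble with columns `PC1..PCdims` plus any non-numeric metadata
#'   columns of `x`; attribute `explained_variance` holds the per-component
#'   variance fractions.
#' @export
reduce_pca <- function(x, dims = 10L) {
  m <- feature_matrix(x)
  if (nrow(m) <= dims) {
    abort(sprintf("need more than %d items for %d components, have %d",
                  dims, dims, nrow(m)))
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = dims)
  scores <- pc$x[, seq_len(dims), drop = FALSE]
  out <- as_tibble(scores, .name_repair = "minimal")
  names(out) <- paste0("PC", seq_len(dims))
  if (is.data.frame(x)) {
    meta <- x[, !vapply(x, is.numeric, logical(1)) &
                names(x) != "embedding", drop = FALSE]
    meta$embedding <- NULL
    out <- dplyr::bind_cols(meta, out)
  }
  attr(out, "explained_variance") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(dims)]
  out
}

# k-means++ seeding: spread initial centroids with probability proportional
# to squared distance from the nearest chosen centroid.
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(0, k, ncol(m))
  i <- sample.int(n, 1)
  centers[1, ] <- m[i, ]
  d2 <- rowSums(sweep(m, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- d2 / sum(d2)
    i <- sample.int(n, 1, prob = p)
    centers[j + 1, ] <- m[i, ]
    d2 <- pmin(d2, rowSums(sweep(m, 2, centers[j + 1, ])^2))
  }
  centers
}

# Mean silhouette width over all points; singleton clusters score 0.
silhouette_mean <- function(m, labels) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(ks[ks != labels[i]], function(k) {
      mean(d[i, labels == k])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' K-means clustering of reduced feature vectors
#'
#' Best-of-`restarts` k-means with k-means++ seeding, deterministic given the
#' seed. The mean silhouette width of the solution is computed alongside.
#'
#' @param reduced Output of [reduce_pca()] (or any numeric matrix/tibble).
#' @param k Number of clusters (>= 2, <= number of items).
#' @param seed Integer seed.
#' @param restarts Number of random restarts (default 10).
#' @return A `repertoire_clustering` object: `cluster` (integer labels,
#'   1..k), `centroids`, `inertia` (total within-cluster sum of squares),
#'   `mean_silhouette`, `k`, `data` (the input tibble with a `cluster`
#'   column).
#' @export
cluster_kmeans <- function(reduced, k, seed = 1L, restarts = 10L) {
  m <- feature_matrix(reduced)
  if (k < 2) abort("k must be >= 2")
  if (k > nrow(m)) abort("k exceeds the number of items")
  best <- NULL
  with_seed_if(seed, {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(m, k)
      fit <- suppressWarnings(
        kmeans(m, centers = init, iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  data <- if (is.data.frame(reduced)) reduced else
    as_tibble(m, .name_repair = "unique_quiet")
  data$cluster <- best$cluster
  structure(
    list(cluster = best$cluster, centroids = best$centers,
         inertia = best$tot.withinss,
         mean_silhouette = silhouette_mean(m, best$cluster),
         k = k, data = data, features = m),
    class = "repertoire_clustering"
  )
}

#' @export
print.repertoire_clustering <- function(x, ...) {
  cat(sprintf(
    "<repertoire_clustering: k=%d, n=%d, mean silhouette %.3f, inertia %.1f>\n",
    x$k, length(x$cluster), x$mean_silhouette, x$inertia))
  invisible(x)
}

#' @export
tidy.repertoire_clustering <- function(x, ...) {
  tibble(cluster = sort(unique(x$cluster))) |>
    dplyr::mutate(size = as.integer(table(x$cluster)[as.character(.data$cluster)]))
}

#' @export
glance.repertoire_clustering <- function(x, ...) {
  tibble(k = x$k, n = length(x$cluster), inertia = x$inertia,
         mean_silhouette = x$mean_silhouette)
}

#' Choose the cluster count by silhouette score
#'
#' Fits k-means across `k_range`, picks the k maximizing mean silhouette
#' (ties broken toward smaller k), and returns the silhouette and inertia
#' curves so the elbow can be inspected.
#'
#' @param reduced Output of [reduce_pca()].
#' @param k_range Candidate cluster counts (default 10:30).
#' @param seed Integer seed.
#' @param restarts Restarts per k (default 10).
#' @return A `k_selection` list: `k_best`, `curve` (tibble: k, silhouette,
#'   inertia), `model` (the fitted [cluster_kmeans()] at `k_best`).
#' @export
select_k <- function(reduced, k_range = 10:30, seed = 1L, restarts = 10L) {
  if (length(k_range) == 0) abort("k_range is empty")
  m <- feature_matrix(reduced)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(m)) abort("k_range exceeds the item count")
  fits <- purrr::map(seq_along(k_range), function(i) {
    cluster_kmeans(reduced, k_range[i], seed = seed + i, restarts = restarts)
  })
  curve <- tibble(
    k = k_range,
    silhouette = vapply(fits, function(f) f$mean_silhouette, numeric(1)),
    inertia = vapply(fits, function(f) f$inertia, numeric(1))
  )
  best_i <- which.max(curve$silhouette)  # which.max takes the first maximum
  structure(
    list(k_best = k_range[best_i], curve = curve, model = fits[[best_i]]),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection: k*=%d (silhouette %.3f) over k in [%d, %d]>\n",
              x$k_best, max(x$curve$silhouette), min(x$curve$k),
              max(x$curve$k)))
  invisible(x)
}

#' Entropy-based cluster homogeneity
#'
#' `h = 1 - H(C|K) / H(C)` with `H(C|K) = -sum_{c,k} (n_ck/N) log(n_ck/n_k)`
#' and `H(C)` the class entropy (natural log; `0 log 0 := 0`). Measures
#' whether each cluster contains members of a single class: 1 for pure
#' clusters, 0 when clusters mirror the class marginals. A single-class
#' input has `H(C) = 0` and returns 1 by convention.
#'
#' @param class_labels Class assignment per item (e.g. population).
#' @param cluster_labels Cluster assignment per item.
#' @return Homogeneity in \[0, 1\].
#' @export
homogeneity <- function(class_labels, cluster_labels) {
  if (length(class_labels) == 0) abort("empty input")
  if (length(class_labels) != length(cluster_labels)) {
    abort("label vectors must have equal length")
  }
  n_ck <- table(class_labels, cluster_labels)
  N <- sum(n_ck)
  n_c <- rowSums(n_ck)
  n_k <- colSums(n_ck)
  p_c <- n_c / N
  h_c <- -sum(ifelse(p_c > 0, p_c * log(p_c), 0))
  if (h_c == 0) return(1)
  frac <- sweep(n_ck, 2, n_k, "/")
  h_ck <- -sum(ifelse(n_ck > 0, n_ck / N * log(frac), 0))
  1 - h_ck / h_c
}

#' Sample vocalizations per cluster for manual audit
#'
#' For each cluster, draws `n_random` members uniformly without replacement
#' and lists the `n_central` members closest to the cluster centroid (both
#' capped at the cluster size); the manifest supports human visual/auditory
#' quality control of the clustering.
#'
#' @param model A [cluster_kmeans()] result.
#' @param n_random,n_central Sample sizes per cluster (defaults 30).
#' @param seed Integer seed for the random draw.
#' @param ids Optional item identifiers (default row numbers; pass file
#'   names).
#' @return Tibble: `cluster`, `kind` (random/central), `id`,
#'   `dist_to_centroid`.
#' @export
qc_sample <- function(model, n_random = 30L, n_central = 30L, seed = 1L,
                      ids = NULL) {
  m <- model$features
  if (is.null(ids)) ids <- seq_len(nrow(m))
  rows <- with_seed_if(seed, purrr::map(sort(unique(model$cluster)), function(k) {
    members <- which(model$cluster == k)
    dists <- sqrt(rowSums(sweep(m[members, , drop = FALSE], 2,
                                model$centroids[k, ])^2))
    rnd <- sample(members, min(n_random, length(members)))
    ctr <- members[order(dists)][seq_len(min(n_central, length(members)))]
    dplyr::bind_rows(
      tibble(cluster = k, kind = "random", id = ids[rnd],
             dist_to_centroid = dists[match(rnd, members)]),
      tibble(cluster = k, kind = "central", id = ids[ctr],
             dist_to_centroid = sort(dists)[seq_along(ctr)])
    )
  }))
  dplyr::bind_rows(rows)
}
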