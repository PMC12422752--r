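# Independent brute-force oracles. These deliberately avoid the package's own
# algorithms: plain recursion and direct formula evaluation only.

# Exhaustive enumeration of all monotone warping paths (steps right, down,
# diagonal) from (1,1) to (nx,ny); returns the minimal total cost.
dtw_enum_oracle <- function(d) {
  nx <- nrow(d)
  ny <- ncol(d)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(d[1, 1])
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    d[i, j] + best
  }
  rec(nx, ny)
}

# Direct-entropy homogeneity: loops over classes and clusters, no shared code
# with vocrep::homogeneity().
homogeneity_oracle <- function(classes, clusters) {
  N <- length(classes)
  h_c <- 0
  for (c in unique(classes)) {
    p <- sum(classes == c) / N
    h_c <- h_c - p * log(p)
  }
  if (h_c == 0) return(1)
  h_ck <- 0
  for (k in unique(clusters)) {
    nk <- sum(clusters == k)
    for (c in unique(classes)) {
      nck <- sum(classes == c & clusters == k)
      if (nck > 0) h_ck <- h_ck - (nck / N) * log(nck / nk)
    }
  }
  1 - h_ck / h_c
}

# Cell-by-cell median clipping.
median_clip_oracle <- function(m, factor = 3) {
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      thr <- factor * max(median(m[i, ]), median(m[, j]))
      if (!(m[i, j] > thr)) out[i, j] <- 0
    }
  }
  out
}

# 8-connected components by breadth-first search over a logical matrix;
# returns the list of component sizes for nonzero cells.
component_sizes_oracle <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  sizes <- integer(0)
  for (i0 in seq_len(nrow(mask))) {
    for (j0 in seq_len(ncol(mask))) {
      if (!mask[i0, j0] || seen[i0, j0]) next
      queue <- list(c(i0, j0))
      seen[i0, j0] <- TRUE
      size <- 0L
      while (length(queue) > 0) {
        cur <- queue[[1]]
        queue <- queue[-1]
        size <- size + 1L
        for (di in -1:1) for (dj in -1:1) {
          ni <- cur[1] + di
          nj <- cur[2] + dj
          if (ni < 1 || nj < 1 || ni > nrow(mask) || nj > ncol(mask)) next
          if (mask[ni, nj] && !seen[ni, nj]) {
            seen[ni, nj] <- TRUE
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
      sizes <- c(sizes, size)
    }
  }
  sizes
}

# All permutations of 1..n by plain recursion (independent of pracma).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in perms_oracle(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Exact Mantel p by enumeration: fraction of relabelings whose upper-triangle
# correlation is >= the observed one.
mantel_exact_oracle <- function(a, b) {
  ut <- upper.tri(a)
  r_obs <- cor(a[ut], b[ut])
  rs <- vapply(perms_oracle(nrow(a)), function(p) {
    cor(a[ut], b[p, p][ut])
  }, numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# Helper to build a random syllable template whose contour respects the band.
random_template <- function(id, c0_range = c(1800, 2600),
                            ck_range = c(200, 450),
                            dur_range = c(0.3, 0.55)) {
  repeat {
    c0 <- runif(1, c0_range[1], c0_range[2])
    ck <- runif(4, ck_range[1], ck_range[2]) * sample(c(-1, 1), 4, TRUE)
    f <- legendre_eval(c(c0, ck), seq(-1, 1, length.out = 512))
    if (min(f) >= 900 && max(f) <= 3700) {
      return(syllable_template(id, c(c0, ck),
                               runif(1, dur_range[1], dur_range[2])))
    }
  }
}
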