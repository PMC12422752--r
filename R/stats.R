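#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (chi-square reference) for >= 2 groups,
#' followed by Dunn's z for every pair of groups with multiplicity
#' adjustment.
#'
#' @param gs Tibble/data frame with columns `value` (numeric) and `group`.
#' @param adjust `"bonferroni"` (default) or `"holm"`.
#' @return A `kw_dunn` list: `H`, `df`, `p`, `pairwise` (tibble: group1,
#'   group2, z, p, p_adj), `adjust`.
#' @export
kruskal_dunn <- function(gs, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  value <- gs$value
  group <- as.factor(gs$group)
  if (any(table(group) == 0) || nlevels(group) < 2) {
    abort("need >= 2 non-empty groups")
  }
  n <- length(value)
  if (n < 5) abort("need a total sample size of at least 5")
  kw <- suppressWarnings(kruskal.test(value, group))
  H <- unname(kw$statistic)
  if (!is.finite(H)) H <- 0  # all values identical: tie correction degenerate
  p <- unname(kw$p.value)
  if (!is.finite(p)) p <- 1

  r <- rank(value)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, group, mean)
  sizes <- tapply(r, group, length)
  lev <- levels(group)
  combs <- utils::combn(lev, 2)
  z <- vapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[a] + 1 / sizes[b]))
    if (se == 0) return(0)
    (mean_rank[a] - mean_rank[b]) / se
  }, numeric(1))
  p_pair <- 2 * pnorm(-abs(z))
  structure(
    list(H = H, df = nlevels(group) - 1L, p = p,
         pairwise = tibble(group1 = combs[1, ], group2 = combs[2, ], z = z,
                           p = p_pair, p_adj = p.adjust(p_pair, adjust)),
         adjust = adjust),
    class = "kw_dunn"
  )
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n", x$H, x$df, x$p))
  cat(sprintf("Dunn post hoc (%s adjustment):\n", x$adjust))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.kw_dunn <- function(x, ...) x$pairwise

#' @export
glance.kw_dunn <- function(x, ...) tibble(H = x$H, df = x$df, p = x$p)

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F is
#' computed from the among/within decomposition of squared distances
#' (`SS_total = sum d^2 / n`, `SS_within = sum_g (within-group d^2)/n_g`) and
#' its null distribution by permuting group labels. The p-value uses the +1
#' convention and is never exactly zero.
#'
#' @param dm A [dist_matrix()] (or symmetric matrix).
#' @param groups Group label per row of `dm` (>= 2 groups).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return A `permanova_result` list: `pseudo_F`, `p`, `df`, `n_perm`,
#'   `seed`.
#' @export
permanova <- function(dm, groups, n_perm = 9999L, seed = 1L) {
  d <- unclass(as.matrix(dm))
  n <- nrow(d)
  groups <- as.factor(groups)
  if (length(groups) != n) abort("one group label per matrix row required")
  a <- nlevels(groups)
  if (a < 2) abort("need >= 2 groups")
  if (n - a < 1) abort("no within-group degrees of freedom")
  M <- d^2
  sst <- sum(M[upper.tri(M)]) / n
  ssw_of <- function(g) {
    sum(vapply(levels(g), function(lv) {
      idx <- which(g == lv)
      sum(M[idx, idx]) / (2 * length(idx))
    }, numeric(1)))
  }
  ssw <- ssw_of(groups)
  f_of <- function(ssw) ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  f_obs <- f_of(ssw)

  # permutation null, vectorized in blocks: for indicator matrix Z of one
  # group, diag(Z' M Z) = colSums(Z * (M %*% Z))
  exceed <- 0L
  with_seed_if(seed, {
    block <- 500L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      perms <- replicate(b, sample.int(n))
      ssw_p <- numeric(b)
      for (lv in levels(groups)) {
        members <- which(groups == lv)
        Z <- matrix(0, n, b)
        Z[cbind(as.vector(perms[members, ]), rep(seq_len(b),
                                                 each = length(members)))] <- 1
        ssw_p <- ssw_p + colSums(Z * (M %*% Z)) / (2 * length(members))
      }
      exceed <- exceed + sum(f_of(ssw_p) >= f_obs - 1e-12)
      done <- done + b
    }
  })
  structure(
    list(pseudo_F = f_obs, p = (1 + exceed) / (1 + n_perm),
         df = c(between = a - 1L, within = n - a), n_perm = n_perm,
         seed = seed),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), p = %.4g (%d perms)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p, x$n_perm))
  invisible(x)
}

#' @export
glance.permanova_result <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, df_between = x$df[1], df_within = x$df[2],
         p = x$p, n_perm = x$n_perm)
}

all_permutations <- function(n) {
  p <- pracma::perms(seq_len(n))
  lapply(seq_len(nrow(p)), function(i) p[i, ])
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with significance from
#' joint row/column permutations of one matrix. For n <= 6 entities all n!
#' permutations are enumerated exactly (24 for the four-population case,
#' making 1/24 ~ 0.042 the smallest attainable p); larger problems use seeded
#' random permutations with the +1 convention.
#'
#' @param dm_a,dm_b [dist_matrix()] objects with identical ids in identical
#'   order.
#' @param n_perm Number of random permutations when n > 6 (default 9999).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default; positive association) or
#'   `"two.sided"`.
#' @return A `mantel_result` list: `r`, `p`, `n`, `exact` (logical),
#'   `n_perm`.
#' @export
mantel_test <- function(dm_a, dm_b, n_perm = 9999L, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- as.matrix(dm_a); b <- as.matrix(dm_b)
  n <- nrow(a)
  if (n < 3) abort("need at least 3 entities")
  if (!identical(dim(a), dim(b))) abort("matrix dimensions differ")
  ida <- rownames(a); idb <- rownames(b)
  if (!is.null(ida) && !is.null(idb) && !identical(ida, idb)) {
    abort("matrix ids differ or are ordered differently")
  }
  ut <- upper.tri(a)
  va <- a[ut]; vb <- b[ut]
  if (sd(va) == 0 || sd(vb) == 0) abort("zero variance in a distance triangle")
  r_obs <- cor(va, vb)
  stat <- function(p) cor(va, b[p, p][ut])
  exact <- factorial(n) <= 720
  side <- function(r) {
    if (alternative == "greater") r >= r_obs - 1e-12
    else abs(r) >= abs(r_obs) - 1e-12
  }
  if (exact) {
    rs <- vapply(all_permutations(n), stat, numeric(1))
    p <- mean(side(rs))
    n_used <- factorial(n)
  } else {
    rs <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
      stat(sample.int(n))
    }, numeric(1)))
    p <- (1 + sum(side(rs))) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(
    list(r = r_obs, p = p, n = n, exact = exact, n_perm = n_used,
         alternative = alternative),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.3f, p = %.4g (%s, n = %d, %s)\n", x$r, x$p,
              if (x$exact) sprintf("exact over %d permutations", x$n_perm)
              else sprintf("%d random permutations", x$n_perm),
              x$n, x$alternative))
  invisible(x)
}

#' @export
glance.mantel_result <- function(x, ...) {
  tibble(r = x$r, p = x$p, n = x$n, exact = x$exact, n_perm = x$n_perm)
}
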