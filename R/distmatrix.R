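#' Distance-matrix container
#'
#' A symmetric zero-diagonal matrix with unique ids and a semantic kind
#' (acoustic, genetic, geographic, ...), the common currency of the
#' statistical layer.
#'
#' @param d Symmetric numeric matrix with zero diagonal.
#' @param ids Row/column identifiers (default existing dimnames).
#' @param kind Free-text kind tag.
#' @return A `dist_matrix` (matrix subclass).
#' @export
dist_matrix <- function(d, ids = rownames(d), kind = "acoustic") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  if (anyDuplicated(ids)) abort("ids must be unique")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-8) abort("diagonal must be zero")
  if (any(d < -1e-12)) abort("distances must be non-negative")
  dimnames(d) <- list(ids, ids)
  structure(d, class = c("dist_matrix", "matrix"), kind = kind)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix (%s): %d x %d>\n", attr(x, "kind"), nrow(x),
              ncol(x)))
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.dist_matrix <- function(x, ...) {
  ids <- rownames(x)
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  tibble(item1 = ids[pairs[, 1]], item2 = ids[pairs[, 2]],
         distance = x[pairs])
}

#' Write / read a distance matrix as square CSV with id headers
#'
#' @param x A [dist_matrix()].
#' @param path CSV path.
#' @return `path` (write) or a [dist_matrix()] (read).
#' @export
write_dist_csv <- function(x, path) {
  df <- as.data.frame(unclass(x))
  df <- cbind(id = rownames(x), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_dist_csv
#' @param kind Kind tag to attach on read.
#' @export
read_dist_csv <- function(path, kind = "acoustic") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  dist_matrix(m, ids = df[[1]], kind = kind)
}
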