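# Legendre polynomial basis on [-1, 1], by the Bonnet recurrence.
# Returns a length(x) x (order + 1) matrix with columns P0 .. P_order.
legendre_basis <- function(x, order) {
  if (order < 0) abort("order must be >= 0")
  B <- matrix(0, length(x), order + 1L)
  B[, 1] <- 1
  if (order >= 1) B[, 2] <- x
  if (order >= 2) {
    for (n in 1:(order - 1L)) {
      B[, n + 2L] <- ((2 * n + 1) * x * B[, n + 1L] - n * B[, n]) / (n + 1)
    }
  }
  B
}

#' Evaluate a Legendre-coefficient frequency contour
#'
#' The pitch contour of a syllable is parameterized as
#' `f0(u) = sum_k c_k P_k(u)` with `u` the syllable's time axis mapped
#' affinely to \[-1, 1\] and `P_k` the Legendre polynomials.
#'
#' @param coeffs Numeric vector of coefficients (Hz scale), `c_0 .. c_K`.
#' @param x Evaluation points in \[-1, 1\].
#' @return Numeric vector of contour values in Hz.
#' @export
legendre_eval <- function(coeffs, x) {
  drop(legendre_basis(x, length(coeffs) - 1L) %*% coeffs)
}
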