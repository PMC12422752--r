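# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state when `seed` is non-NULL.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Frame start indices (1-based) for a centered short-time analysis:
# the signal is reflection-padded by frame_len/2 on both sides and frames are
# taken every `hop` samples, giving 1 + floor(n / hop) frames whose centers sit
# at samples 1, 1 + hop, ... (librosa-style centering).
frame_grid <- function(n, frame_len, hop) {
  if (n < 1) abort("empty signal")
  n_frames <- 1L + n %/% hop
  centers <- 1L + hop * (seq_len(n_frames) - 1L)
  list(n_frames = n_frames, centers = centers)
}

reflect_pad <- function(x, pad) {
  n <- length(x)
  if (pad == 0) return(x)
  # mirror indices around the edges (edge sample not repeated); clamp for
  # signals shorter than the pad
  left <- x[pmax(1L, pmin(n, seq(pad + 1L, 2L)))]
  right <- x[pmax(1L, pmin(n, seq(n - 1L, n - pad)))]
  c(left, x, right)
}

# Root-mean-square of a vector.
rms <- function(x) sqrt(mean(x^2))

# Per-frame RMS on the centered frame grid, via cumulative sums.
frame_rms <- function(x, frame_len, hop) {
  g <- frame_grid(length(x), frame_len, hop)
  pad <- frame_len %/% 2
  xp <- reflect_pad(x, pad)
  cs <- c(0, cumsum(xp^2))
  starts <- g$centers  # position of frame start within padded signal
  ends <- pmin(starts + frame_len - 1L, length(xp))
  sqrt((cs[ends + 1L] - cs[starts]) / (ends - starts + 1L))
}

linear_map <- function(x, from, to) {
  if (diff(range(from)) == 0) return(rep(mean(to), length(x)))
  (x - from[1]) / (from[2] - from[1]) * (to[2] - to[1]) + to[1]
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}
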