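# Internal helpers shared across stages.

CHANNEL_NAMES <- c(
  "right_fcr", "right_edc", "left_fcr", "left_edc",
  "right_rhomboideus", "right_trapezius", "left_rhomboideus", "left_trapezius"
)
N_CHANNELS <- 8L
REFERENCE_CHANNEL <- 8L
RIGHT_CHANNELS <- c(1L, 2L, 5L, 6L)
LEFT_CHANNELS <- c(3L, 4L, 7L, 8L)

#' @noRd
derive_seed <- function(seed, k) {
  # deterministic 32-bit sub-seed splitter so stages can be re-run in isolation
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

#' @noRd
gaussian_kernel <- function(width, sigma = width / 6) {
  stopifnot(width >= 3)
  t <- seq_len(width) - (width + 1) / 2
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

# Centered convolution with reflective edge padding; FFT-based for long kernels.
#' @noRd
conv_reflect <- function(x, kernel) {
  n <- length(x)
  w <- length(kernel)
  h <- w %/% 2
  if (n <= w) stop("signal shorter than kernel (", n, " <= ", w, ")")
  left <- x[(h + 1):2]
  right <- x[(n - 1):(n - h)]
  xp <- c(left, x, right)
  np <- length(xp)
  m <- stats::nextn(np + w)
  fx <- stats::fft(c(xp, numeric(m - np)))
  fk <- stats::fft(c(kernel, numeric(m - w)))
  y <- Re(stats::fft(fx * fk, inverse = TRUE)) / m
  # full convolution index of centered output: offset h (kernel center) + pad h
  y[(2 * h + 1):(2 * h + n)]
}

#' @noRd
type7_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
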