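# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministic seed spawning so that independent stochastic stages (one per
#' subject, region, or grid cell) get reproducible, distinct RNG streams from
#' a single master seed. Uses a multiplicative congruential step on the
#' Mersenne-prime modulus 2^31 - 1, so derived seeds stay valid R integers.
#'
#' @param seed master seed (integer).
#' @param k child index (integer, any nonnegative value).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.double(seed) %% m + 1)
  # two LCG steps decorrelate consecutive k
  s <- (s * 48271 + as.double(k)) %% m
  s <- (s * 69621 + 1) %% m
  as.integer(s %% (m - 1) + 1)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Z-score a time series
#'
#' Centers to mean zero and scales to unit sample variance.
#'
#' @param x numeric vector.
#' @return standardized numeric vector.
#' @export
zscore <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("zscore: need a numeric vector of length >= 2")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zscore: degenerate signal (zero variance)")
  }
  (x - mean(x)) / s
}

# Analytic signal via the frequency-domain Hilbert construction: zero the
# negative frequencies, double the positive ones, keep DC (and Nyquist).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Row medians excluding the diagonal (stored as NA by convention).
offdiag_row_median <- function(mat) {
  diag(mat) <- NA_real_
  apply(mat, 1, median, na.rm = TRUE)
}

upper_tri_vec <- function(mat) mat[upper.tri(mat)]

is_symmetric_num <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
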