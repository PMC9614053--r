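# Internal helpers shared across modules.

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

#' Shift a signal by an integer number of samples
#'
#' Positive `n` delays the signal (prepends zeros); negative `n` advances it.
#' Length is preserved.
#'
#' @param x numeric vector.
#' @param n integer shift in samples.
#' @return shifted numeric vector of the same length.
#' @keywords internal
shift_samples <- function(x, n) {
  len <- length(x)
  n <- as.integer(n)
  if (n == 0L || len == 0L) return(x)
  out <- numeric(len)
  if (n > 0L) {
    if (n < len) out[(n + 1L):len] <- x[1L:(len - n)]
  } else {
    m <- -n
    if (m < len) out[1L:(len - m)] <- x[(m + 1L):len]
  }
  out
}

# FFT-based causal convolution of each column of `mat` with kernel `h`,
# truncated to nrow(mat) (same "start" alignment as filtering).
conv_columns <- function(h, mat) {
  if (is.vector(mat)) mat <- matrix(mat, ncol = 1L)
  n <- nrow(mat)
  m <- length(h)
  nf <- nextn(n + m - 1L, 2L)
  H <- fft(c(h, rep(0, nf - m)))
  X <- mvfft(rbind(mat, matrix(0, nf - n, ncol(mat))))
  Y <- Re(mvfft(X * H, inverse = TRUE)) / nf
  Y[seq_len(n), , drop = FALSE]
}

# Exponential-window smoother (first-order lowpass) for vectors or matrices.
# alpha = 1 - exp(-1 / (tau * fs)).
ema_smooth <- function(x, tau, fs) {
  alpha <- 1 - exp(-1 / (tau * fs))
  if (is.matrix(x)) {
    ema_columns(x, alpha)
  } else {
    drop(ema_columns(matrix(x, ncol = 1L), alpha))
  }
}

rms <- function(x) sqrt(mean(x^2))

# Lag-optimized normalized cross-correlation between two equal-length signals.
best_lag_correlation <- function(x, y, max_lag) {
  cc <- stats::ccf(y, x, lag.max = max_lag, plot = FALSE)
  i <- which.max(abs(cc$acf))
  list(correlation = cc$acf[i], lag = cc$lag[i])
}

# Deterministic child seeds (kept well below .Machine$integer.max).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483629)
}
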