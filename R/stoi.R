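# Short-time objective intelligibility (STOI), classic variant: both signals
# are resampled to 10 kHz, silent frames (40 dB below the loudest clean
# frame) are removed, short-time one-third-octave band envelopes are
# compared by correlation over 384 ms segments after clip-limited
# normalization, and the correlations averaged.

stoi_fs <- 10000L
stoi_frame <- 256L
stoi_hop <- 128L
stoi_nfft <- 512L
stoi_nbands <- 15L
stoi_seg <- 30L      # analysis segment length in frames (384 ms)
stoi_beta <- -15     # signal-to-distortion clip bound, dB
stoi_dyn_range <- 40 # silent-frame energy range, dB

stoi_band_matrix <- function() {
  cf <- 150 * 2^((seq_len(stoi_nbands) - 1) / 3)
  lo <- cf * 2^(-1 / 6)
  hi <- cf * 2^(1 / 6)
  f <- (0:(stoi_nfft / 2)) * stoi_fs / stoi_nfft
  A <- matrix(0, stoi_nbands, length(f))
  for (j in seq_len(stoi_nbands)) {
    A[j, f >= lo[j] & f < hi[j]] <- 1
  }
  A
}

stoi_frames <- function(x) {
  n_frames <- max(0L, (length(x) - stoi_frame) %/% stoi_hop + 1L)
  idx <- outer(seq_len(stoi_frame), (seq_len(n_frames) - 1L) * stoi_hop, "+")
  matrix(x[idx], nrow = stoi_frame)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

stoi_remove_silence <- function(x, y) {
  w <- hann_window(stoi_frame)
  X <- stoi_frames(x) * w
  Y <- stoi_frames(y) * w
  energy <- 20 * log10(sqrt(colSums(X^2)) + 1e-300)
  keep <- energy > max(energy) - stoi_dyn_range
  X <- X[, keep, drop = FALSE]
  Y <- Y[, keep, drop = FALSE]
  # overlap-add the retained frames back into continuous signals
  n_out <- stoi_hop * (ncol(X) - 1L) + stoi_frame
  xo <- numeric(n_out)
  yo <- numeric(n_out)
  for (m in seq_len(ncol(X))) {
    at <- (m - 1L) * stoi_hop + seq_len(stoi_frame)
    xo[at] <- xo[at] + X[, m]
    yo[at] <- yo[at] + Y[, m]
  }
  list(x = xo, y = yo)
}

stoi_band_envelopes <- function(x) {
  w <- hann_window(stoi_frame)
  F <- stoi_frames(x) * w
  F <- rbind(F, matrix(0, stoi_nfft - stoi_frame, ncol(F)))
  S <- mvfft(F)[seq_len(stoi_nfft / 2 + 1L), , drop = FALSE]
  sqrt(stoi_band_matrix() %*% (abs(S)^2))
}

#' Short-time objective intelligibility score
#'
#' Intrusive intelligibility measure in `[0, 1]` comparing a degraded signal
#' to its clean reference. Binaural inputs are scored per ear and averaged.
#'
#' @param reference clean signal: numeric vector or `[n x 2]` matrix.
#' @param estimate degraded/processed signal of the same shape.
#' @param fs sample rate of both signals in Hz.
#' @return scalar score, higher is more intelligible.
#' @export
stoi_score <- function(reference, estimate, fs) {
  if (is.matrix(reference) || is.matrix(estimate)) {
    abort_if(!is.matrix(reference) || !is.matrix(estimate) ||
               !identical(dim(reference), dim(estimate)),
             "reference and estimate must have identical shapes")
    return(mean(vapply(seq_len(ncol(reference)), function(j) {
      stoi_score(reference[, j], estimate[, j], fs)
    }, numeric(1))))
  }
  abort_if(length(reference) != length(estimate),
           "reference and estimate must have equal length")
  x <- resample_audio(reference, fs, stoi_fs)
  y <- resample_audio(estimate, fs, stoi_fs)
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]
  y <- y[seq_len(n)]
  abort_if(n < stoi_frame, "signals too short for STOI")
  sig <- stoi_remove_silence(x, y)
  X <- stoi_band_envelopes(sig$x)
  Y <- stoi_band_envelopes(sig$y)
  M <- ncol(X)
  abort_if(M < stoi_seg, "too few non-silent frames for STOI")
  clip <- 10^(-stoi_beta / 20)
  d_sum <- 0
  d_n <- 0L
  for (m in stoi_seg:M) {
    at <- (m - stoi_seg + 1L):m
    Xs <- X[, at, drop = FALSE]
    Ys <- Y[, at, drop = FALSE]
    for (j in seq_len(stoi_nbands)) {
      xj <- Xs[j, ]
      yj <- Ys[j, ]
      ny <- sqrt(sum(yj^2))
      alpha <- if (ny > 0) sqrt(sum(xj^2)) / ny else 0
      yj <- pmin(alpha * yj, (1 + clip) * xj)
      sx <- sd(xj)
      sy <- sd(yj)
      d <- if (sx > 0 && sy > 0) {
        sum((xj - mean(xj)) * (yj - mean(yj))) / ((stoi_seg - 1) * sx * sy)
      } else if (sx == 0 && sy == 0) 1 else 0
      d_sum <- d_sum + d
      d_n <- d_n + 1L
    }
  }
  d_sum / d_n
}
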