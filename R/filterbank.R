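#' Gammatone ERB filterbank specification
#'
#' Describes the peripheral analysis stage: a bank of 4th-order gammatone
#' filters with equivalent-rectangular-bandwidth (ERB) spacing. The bandwidth
#' of the filter centred at `fc` is `((fc/Q)^x + b^x)^(1/x)`; with the default
#' order `x = 1` this is the familiar `fc/Q + b` ERB rule.
#'
#' @param n_channels number of frequency channels (default 64).
#' @param f_min lowest center frequency in Hz (default 200).
#' @param f_max highest center frequency in Hz (default 20000).
#' @param Q asymptotic filter quality factor (default 9.26449).
#' @param b_min minimum bandwidth in Hz (default 24.7).
#' @param order_x order of the bandwidth combination rule (default 1).
#' @param gammatone_order order of the gammatone filters (default 4).
#' @param fs sample rate in Hz (default 44100).
#' @return an object of class `filterbank_spec`.
#' @examples
#' spec <- filterbank_spec()
#' erb_bandwidth(1000, spec)
#' @export
filterbank_spec <- function(n_channels = 64L, f_min = 200, f_max = 20000,
                            Q = 9.26449, b_min = 24.7, order_x = 1,
                            gammatone_order = 4L, fs = 44100) {
  abort_if(n_channels < 1, "n_channels must be >= 1")
  abort_if(!(f_min > 0 && f_min < f_max), "need 0 < f_min < f_max")
  abort_if(f_max >= fs / 2, "f_max must be below the Nyquist frequency fs/2")
  abort_if(Q <= 0 || b_min <= 0, "Q and b_min must be positive")
  structure(
    list(n_channels = as.integer(n_channels), f_min = f_min, f_max = f_max,
         Q = Q, b_min = b_min, order_x = order_x,
         gammatone_order = as.integer(gammatone_order), fs = fs),
    class = "filterbank_spec"
  )
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat(sprintf(
    "<filterbank_spec> %d gammatone channels, %.0f-%.0f Hz (ERB-spaced), fs = %.0f Hz\n",
    x$n_channels, x$f_min, x$f_max, x$fs))
  invisible(x)
}

#' Equivalent rectangular bandwidth at a center frequency
#'
#' @param fc center frequency in Hz (non-negative).
#' @param spec a [filterbank_spec()].
#' @return bandwidth in Hz.
#' @export
erb_bandwidth <- function(fc, spec = filterbank_spec()) {
  abort_if(any(fc < 0), "fc must be non-negative")
  ((fc / spec$Q)^spec$order_x + spec$b_min^spec$order_x)^(1 / spec$order_x)
}

# ERB-rate (number of ERBs below f), the integral of 1/erb(f) df for the
# order-1 bandwidth rule; its inverse gives ERB-rate-uniform spacing.
erb_number <- function(f, spec) spec$Q * log(1 + f / (spec$Q * spec$b_min))
erb_number_inverse <- function(E, spec) spec$Q * spec$b_min * (exp(E / spec$Q) - 1)

#' ERB-rate-spaced center frequencies
#'
#' `n_channels` frequencies uniformly spaced on the ERB-rate scale, with the
#' first equal to `f_min` and the last equal to `f_max`.
#'
#' @inheritParams erb_bandwidth
#' @return numeric vector of center frequencies in Hz, strictly increasing.
#' @export
erb_center_frequencies <- function(spec = filterbank_spec()) {
  if (spec$n_channels == 1L) return(spec$f_min)
  E <- seq(erb_number(spec$f_min, spec), erb_number(spec$f_max, spec),
           length.out = spec$n_channels)
  f <- erb_number_inverse(E, spec)
  f[1] <- spec$f_min
  f[spec$n_channels] <- spec$f_max
  f
}

# Design the complex all-pole gammatone bank. Each channel is a cascade of
# `gammatone_order` identical complex one-pole resonators; the 1.019 factor
# maps the ERB to the pole bandwidth of the 4th-order gammatone. Channels are
# normalized to unit magnitude at their center frequency, and aligned with a
# per-channel causal delay plus phase rotation so that impulse responses peak
# coherently at a common latency; this makes the plain (unweighted) channel
# sum a good reconstruction of the input while leaving interaural cues and
# envelopes untouched (both ears use the identical design).
filterbank_design <- function(spec) {
  key <- paste0("fbdesign_", paste(unlist(spec), collapse = "_"))
  if (!is.null(the[[key]])) return(the[[key]])
  cf <- erb_center_frequencies(spec)
  bw <- 1.019 * erb_bandwidth(cf, spec)
  lambda <- exp(-2 * pi * bw / spec$fs)
  a <- lambda * exp(1i * 2 * pi * cf / spec$fs)
  w <- 2 * pi * cf / spec$fs
  H <- (1 / (1 - a * exp(-1i * w)))^spec$gammatone_order
  gain <- 1 / abs(H)
  # complex impulse response of the cascade: h[n] = C(n+p-1, p-1) a^n
  p <- spec$gammatone_order
  nir <- 0:(ceiling(0.030 * spec$fs) - 1L)
  K <- length(cf)
  peak <- integer(K)
  phase <- numeric(K)
  for (k in seq_len(K)) {
    hc <- choose(nir + p - 1, p - 1) * a[k]^nir
    i <- which.max(abs(hc))
    peak[k] <- i - 1L
    phase[k] <- -Arg(hc[i])
  }
  d0 <- max(peak)
  g <- gain * exp(1i * phase)
  design <- list(pole_re = Re(a), pole_im = Im(a), gain_re = Re(g),
                 gain_im = Im(g), delay = as.integer(d0 - peak),
                 latency = d0, center_freqs = cf, order = p)
  the[[key]] <- design
  design
}

#' Decompose a mono waveform into gammatone subbands
#'
#' Filters the input through the gammatone ERB filterbank, returning one
#' narrowband signal per channel. Filtering is causal; all channels share a
#' common group latency so their unweighted sum approximates the input.
#'
#' @param audio numeric vector sampled at `spec$fs` (pass `fs` to resample).
#' @param spec a [filterbank_spec()].
#' @param fs sample rate of `audio` if different from `spec$fs`; the input is
#'   then resampled with a polyphase anti-aliasing resampler.
#' @return numeric matrix `[n_samples x n_channels]` with attributes
#'   `center_freqs` and `fs`.
#' @export
gammatone_analyze <- function(audio, spec = filterbank_spec(), fs = NULL) {
  abort_if(!is.numeric(audio), "audio must be numeric")
  if (!is.null(fs) && fs != spec$fs) {
    audio <- resample_audio(audio, fs, spec$fs)
  }
  d <- filterbank_design(spec)
  out <- gammatone_cascade(as.numeric(audio), d$pole_re, d$pole_im,
                           d$gain_re, d$gain_im, d$delay, d$order)
  attr(out, "center_freqs") <- d$center_freqs
  attr(out, "fs") <- spec$fs
  out
}

#' Binaural subband decomposition
#'
#' Applies [gammatone_analyze()] to both ears of a stereo waveform.
#'
#' @param stereo numeric matrix `[n_samples x 2]` (left, right).
#' @inheritParams gammatone_analyze
#' @return object of class `subbands`: list with matrices `left`, `right`
#'   (`[n_samples x n_channels]`), `fs`, and `center_freqs`.
#' @export
analyze_binaural <- function(stereo, spec = filterbank_spec(), fs = NULL) {
  abort_if(!is.matrix(stereo) || ncol(stereo) != 2L,
           "stereo must be an [n x 2] matrix")
  L <- gammatone_analyze(stereo[, 1L], spec, fs)
  R <- gammatone_analyze(stereo[, 2L], spec, fs)
  structure(list(left = unclass_mat(L), right = unclass_mat(R), fs = spec$fs,
                 center_freqs = attr(L, "center_freqs"), spec = spec),
            class = "subbands")
}

unclass_mat <- function(x) {
  attr(x, "center_freqs") <- NULL
  attr(x, "fs") <- NULL
  x
}

#' @export
print.subbands <- function(x, ...) {
  cat(sprintf("<subbands> %d samples x %d channels per ear, fs = %.0f Hz\n",
              nrow(x$left), ncol(x$left), x$fs))
  invisible(x)
}

#' Resample audio with anti-aliasing
#'
#' Thin wrapper over a polyphase FIR resampler, using the rational
#' approximation of the rate ratio.
#'
#' @param x numeric vector or `[n x 2]` matrix.
#' @param fs_in,fs_out sample rates in Hz.
#' @return resampled signal.
#' @export
resample_audio <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  fr <- frac_approx(fs_out / fs_in)
  if (is.matrix(x)) {
    apply(x, 2, function(col) signal::resample(col, fr$p, fr$q))
  } else {
    signal::resample(x, fr$p, fr$q)
  }
}

frac_approx <- function(r, max_den = 1000L) {
  # continued-fraction rational approximation of r
  best <- c(1L, 1L)
  err <- Inf
  for (q in 1:max_den) {
    p <- round(r * q)
    e <- abs(r - p / q)
    if (e < err - 1e-15) {
      best <- c(p, q)
      err <- e
      if (e < 1e-12) break
    }
  }
  list(p = best[1], q = best[2])
}
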