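#' Parameters for binaural cue extraction
#'
#' Both the running interaural correlation and the energy envelopes use
#' first-order exponential windows. The floor (in dB re unit energy) guards
#' digital silence: with both normalizers floored, silence yields 0
#' correlation and 0 dB ILD. Because correlation and ILD are formed as
#' normalized products and ratios, the resulting cues are invariant to the
#' overall stimulus level.
#'
#' @param corr_time_constant exponential window of the correlation, seconds
#'   (default 0.005).
#' @param env_time_constant exponential window of the energy envelope,
#'   seconds (default 0.005).
#' @param env_floor silence guard in dB (default -100); the energy floor is
#'   `10^(env_floor/10)`.
#' @param log_envelope logical; kept for config round-tripping (ILD is always
#'   computed on a log scale).
#' @return object of class `cue_params`.
#' @export
cue_params <- function(corr_time_constant = 0.005, env_time_constant = 0.005,
                       env_floor = -100, log_envelope = TRUE) {
  abort_if(corr_time_constant <= 0 || env_time_constant <= 0,
           "time constants must be positive")
  structure(list(corr_time_constant = corr_time_constant,
                 env_time_constant = env_time_constant,
                 env_floor = env_floor, log_envelope = isTRUE(log_envelope)),
            class = "cue_params")
}

env_floor_energy <- function(params) 10^(params$env_floor / 10)

default_cue_params <- cue_params

#' Running energy envelope of a subband
#'
#' The squared signal smoothed with a first-order exponential filter of time
#' constant `env_time_constant`. Scaling the input by `g` scales the envelope
#' by `g^2`.
#'
#' @param subband numeric vector or matrix (columns are channels).
#' @param params a [cue_params()].
#' @param fs sample rate in Hz.
#' @return non-negative envelope, same shape as the input.
#' @export
energy_envelope <- function(subband, params = cue_params(), fs) {
  ema_smooth(subband^2, params$env_time_constant, fs)
}

#' Running interaural correlation at a probe lag
#'
#' Per-sample normalized cross-correlation between the left-ear signal and
#' the right-ear signal delayed by `lag` seconds, with exponential windows of
#' `corr_time_constant` for the numerator and both energy normalizers. By the
#' Cauchy-Schwarz inequality the trace lies in `[-1, 1]`; flooring the
#' normalizers at the silence guard returns 0 for digital silence.
#'
#' A positive probe lag matches a source on the listener's right (the left
#' ear signal lags the right by the interaural time difference).
#'
#' @param uL,uR single-channel waveforms of equal length.
#' @param lag probe lag in seconds, `|lag| < 2 ms`; realized as a shift by
#'   the nearest integer number of samples.
#' @param params a [cue_params()].
#' @param fs sample rate in Hz.
#' @return correlation trace in `[-1, 1]`, same length as the inputs.
#' @export
running_xcorr_at_lag <- function(uL, uR, lag, params = cue_params(), fs) {
  abort_if(length(uL) != length(uR), "uL and uR must have equal length")
  abort_if(abs(lag) >= 0.002, "|lag| must be below 2 ms")
  uRs <- shift_samples(uR, round(lag * fs))
  num <- ema_smooth(uL * uRs, params$corr_time_constant, fs)
  eL <- ema_smooth(uL^2, params$corr_time_constant, fs)
  eR <- ema_smooth(uRs^2, params$corr_time_constant, fs)
  floor_e <- env_floor_energy(params)
  num / sqrt(pmax(eL, floor_e) * pmax(eR, floor_e))
}

#' Interaural level difference in dB
#'
#' `10 log10((envL + floor) / (envR + floor))`; positive values mean the left
#' ear is louder. A common gain on both ears leaves the trace unchanged.
#'
#' @param envL,envR energy envelopes (equal shapes).
#' @param params a [cue_params()].
#' @return dB trace, same shape as the inputs.
#' @export
ild_db <- function(envL, envR, params = cue_params()) {
  abort_if(length(envL) != length(envR), "envelopes must have equal shape")
  floor_e <- env_floor_energy(params)
  10 * log10((envL + floor_e) / (envR + floor_e))
}

#' Extract the cue map for a bank of probe lags
#'
#' Assembles, for every frequency channel, the running interaural correlation
#' evaluated at the supplied probe lag (one per channel, or a single scalar
#' used for all channels -- interaural delays are modeled as
#' frequency-independent), the ILD trace, and both energy envelopes.
#'
#' @param subbands a [analyze_binaural()] result.
#' @param probe_lags probe lag(s) in seconds: scalar or one per channel.
#' @param params a [cue_params()].
#' @return object of class `cue_map`: list of matrices `corr_at_lag`,
#'   `ild_db`, `env_left`, `env_right` (`[n_samples x n_channels]`), plus
#'   `fs` and `center_freqs`.
#' @export
extract_cues <- function(subbands, probe_lags = 0, params = cue_params()) {
  stopifnot(inherits(subbands, "subbands"))
  K <- ncol(subbands$left)
  fs <- subbands$fs
  if (length(probe_lags) == 1L) probe_lags <- rep(probe_lags, K)
  abort_if(length(probe_lags) != K, "need one probe lag per channel")
  envL <- energy_envelope(subbands$left, params, fs)
  envR <- energy_envelope(subbands$right, params, fs)
  lag_samples <- round(probe_lags * fs)
  corr <- matrix(0, nrow(subbands$left), K)
  # channels sharing a quantized lag can reuse one shifted matrix
  for (s in unique(lag_samples)) {
    idx <- which(lag_samples == s)
    uR <- subbands$right[, idx, drop = FALSE]
    if (s != 0) uR <- apply(uR, 2, shift_samples, n = s)
    uL <- subbands$left[, idx, drop = FALSE]
    num <- ema_smooth(uL * uR, params$corr_time_constant, fs)
    eL <- ema_smooth(uL^2, params$corr_time_constant, fs)
    eR <- ema_smooth(uR^2, params$corr_time_constant, fs)
    floor_e <- env_floor_energy(params)
    corr[, idx] <- num / sqrt(pmax(eL, floor_e) * pmax(eR, floor_e))
  }
  structure(list(corr_at_lag = corr, ild_db = ild_db(envL, envR, params),
                 env_left = envL, env_right = envR, fs = fs,
                 center_freqs = subbands$center_freqs,
                 probe_lags = probe_lags),
            class = "cue_map")
}

#' Export a cue map to CSV files
#'
#' Writes one CSV per component (`corr`, `ild_db`, `env_l`, `env_r`) plus a
#' small metadata CSV with the sample rate and center frequencies.
#'
#' @param cues a [extract_cues()] result.
#' @param dir output directory (created if missing).
#' @param stride keep every `stride`-th sample (default 1).
#' @return the directory, invisibly.
#' @export
export_cue_map <- function(cues, dir, stride = 1L) {
  stopifnot(inherits(cues, "cue_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- seq(1L, nrow(cues$corr_at_lag), by = stride)
  comp <- list(corr = cues$corr_at_lag, ild_db = cues$ild_db,
               env_l = cues$env_left, env_r = cues$env_right)
  for (nm in names(comp)) {
    write.csv(comp[[nm]][idx, , drop = FALSE],
              file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  write.csv(data.frame(fs = cues$fs, channel = seq_along(cues$center_freqs),
                       center_freq_hz = cues$center_freqs),
            file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}
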