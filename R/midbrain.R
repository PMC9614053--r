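#' Woodworth interaural time difference
#'
#' The spherical-head path-length model: `tau = (r/c) * (theta + sin(theta))`
#' with `theta` in radians, signed by side and independent of frequency.
#' Restricted to the frontal hemifield.
#'
#' @param theta azimuth in degrees, `|theta| <= 90`; positive (right) gives a
#'   positive ITD (left ear lags).
#' @param head_radius head radius in meters (default 0.0875).
#' @param c_sound speed of sound in m/s (default 343).
#' @return ITD in seconds.
#' @examples
#' woodworth_itd(90) # about 655 microseconds
#' @export
woodworth_itd <- function(theta, head_radius = 0.0875, c_sound = 343) {
  abort_if(any(abs(theta) > 90), "|theta| must be <= 90 degrees")
  th <- abs(theta) * pi / 180
  sign(theta) * (head_radius / c_sound) * (th + sin(th))
}

#' Parameters of one set of spatially tuned neurons
#'
#' A set holds one model neuron per frequency channel, all preferring the
#' same azimuth `theta`. Each neuron is tuned to the interaural time
#' difference `best_itd` (frequency-independent, from [woodworth_itd()]) and
#' to a frequency-dependent interaural level difference `best_ild[k]`
#' (derived from an HRTF set by [derive_ild_table()]). ITD evidence
#' (half-wave rectified running interaural correlation at the neuron's best
#' lag) and ILD evidence (the normalized energy envelope of the ear
#' ipsilateral to `theta`, gated to the window `best_ild +/- ild_tolerance`)
#' are combined additively into a subthreshold drive, then passed through a
#' sigmoid to an instantaneous firing rate.
#'
#' @param theta preferred azimuth in degrees (positive = right).
#' @param best_itd preferred ITD in seconds (default: [woodworth_itd()]).
#' @param best_ild preferred ILD per channel, dB (vector, one per channel).
#' @param ild_tolerance half-width of the accepted ILD window, dB (default 5).
#' @param itd_weight,ild_weight mixing weights of the two cue components
#'   (defaults 1, 1).
#' @param sigmoid_midpoint,sigmoid_slope sigmoid parameters in drive units
#'   (see [calibrate_sigmoid()]).
#' @param rate_max maximum firing rate, spikes/s (default 500).
#' @return object of class `stn_params`.
#' @export
stn_params <- function(theta, best_itd = woodworth_itd(theta), best_ild,
                       ild_tolerance = 5, itd_weight = 1, ild_weight = 1,
                       sigmoid_midpoint = 1, sigmoid_slope = 0.25,
                       rate_max = 500) {
  abort_if(rate_max <= 0, "rate_max must be positive")
  abort_if(sigmoid_slope <= 0, "sigmoid_slope must be positive")
  abort_if(ild_tolerance <= 0, "ild_tolerance must be positive")
  structure(list(theta = theta, best_itd = best_itd,
                 best_ild = as.numeric(best_ild),
                 ild_tolerance = ild_tolerance, itd_weight = itd_weight,
                 ild_weight = ild_weight, sigmoid_midpoint = sigmoid_midpoint,
                 sigmoid_slope = sigmoid_slope, rate_max = rate_max),
            class = "stn_params")
}

#' Derive the preferred-ILD table from an HRTF set
#'
#' For every azimuth and frequency channel, a seeded white Gaussian noise is
#' spatialized through the HRTF and decomposed by the gammatone filterbank in
#' each ear; the table entry is the time-averaged interaural level difference
#' of that narrowband channel over the steady state (the first 50 ms are
#' discarded). Because both the spatialization and the filterbank are linear
#' and time-invariant, this equals the ILD of a narrowband noise placed at
#' that azimuth.
#'
#' @param hrtf an `hrtf_set`.
#' @param thetas azimuths in degrees.
#' @param spec a [filterbank_spec()] (its `fs` must match the HRTF set).
#' @param seed integer seed for the probe noise.
#' @param duration probe duration in seconds (default 0.3).
#' @return matrix `[length(thetas) x n_channels]` in dB, with `thetas` as
#'   rownames and channel center frequencies as colnames.
#' @export
derive_ild_table <- function(hrtf, thetas, spec = filterbank_spec(),
                             seed = 1L, duration = 0.3) {
  abort_if(hrtf$fs != spec$fs, "HRTF and filterbank sample rates differ")
  set.seed(seed)
  noise <- rnorm(round(duration * spec$fs))
  skip <- round(0.05 * spec$fs)
  tab <- matrix(NA_real_, length(thetas), spec$n_channels)
  for (i in seq_along(thetas)) {
    y <- spatialize(noise, thetas[i], hrtf)
    sb <- analyze_binaural(y, spec)
    eL <- colSums(sb$left[-seq_len(skip), , drop = FALSE]^2)
    eR <- colSums(sb$right[-seq_len(skip), , drop = FALSE]^2)
    tab[i, ] <- 10 * log10(eL / eR)
  }
  rownames(tab) <- as.character(thetas)
  colnames(tab) <- sprintf("%.1f", erb_center_frequencies(spec))
  tab
}

#' Subthreshold drive of one STN set
#'
#' `drive = itd_weight * max(corr, 0) + ild_weight * gate * env_norm`, where
#' `gate` is 1 when the running ILD lies within `ild_tolerance` of the
#' neuron's preferred ILD and 0 otherwise, and `env_norm` is the energy
#' envelope of the ear ipsilateral to `theta` (the mean of both ears at
#' `theta = 0`), normalized per channel by its maximum over the utterance.
#' Negative interaural correlation carries no excitatory evidence and is
#' rectified away.
#'
#' @param cues a [extract_cues()] result computed at `params$best_itd`.
#' @param params an [stn_params()].
#' @return drive matrix `[n_samples x n_channels]`, non-negative.
#' @export
stn_drive <- function(cues, params) {
  stopifnot(inherits(cues, "cue_map"), inherits(params, "stn_params"))
  K <- ncol(cues$corr_at_lag)
  abort_if(length(params$best_ild) != K,
           "best_ild must have one entry per channel")
  corr_evidence <- pmax(cues$corr_at_lag, 0)
  gate <- abs(sweep(cues$ild_db, 2L, params$best_ild, "-")) <=
    params$ild_tolerance
  env <- if (params$theta > 0) {
    cues$env_right
  } else if (params$theta < 0) {
    cues$env_left
  } else {
    (cues$env_left + cues$env_right) / 2
  }
  peak <- apply(env, 2L, max)
  peak[peak <= 0] <- 1
  env_norm <- sweep(env, 2L, peak, "/")
  params$itd_weight * corr_evidence + params$ild_weight * gate * env_norm
}

#' Sigmoidal rate activation
#'
#' `rate = rate_max / (1 + exp(-(drive - midpoint) / slope))`, elementwise,
#' identical for all frequency channels.
#'
#' @param drive drive matrix from [stn_drive()].
#' @param params an [stn_params()].
#' @return firing-rate matrix in spikes/s.
#' @export
activation <- function(drive, params) {
  params$rate_max / (1 + exp(-(drive - params$sigmoid_midpoint) /
                               params$sigmoid_slope))
}

#' Poisson spike generation
#'
#' Independent per-sample Bernoulli draws with probability `rate / fs`
#' (valid while `rate_max / fs < 1`); reproducible for a given seed.
#'
#' @param rate non-negative rate matrix, spikes/s.
#' @param fs sample rate in Hz.
#' @param seed integer seed.
#' @return object of class `spike_trains`: list with binary `spikes` matrix,
#'   `fs`, `theta` (`NA` unless set by the caller), `seed`.
#' @export
poisson_spikes <- function(rate, fs, seed = 1L) {
  abort_if(any(rate < 0), "rates must be non-negative")
  abort_if(max(rate) / fs >= 1,
           "rate/fs must stay below 1 for per-sample Bernoulli draws")
  set.seed(seed)
  p <- rate / fs
  spikes <- matrix(as.numeric(runif(length(p)) < p), nrow(rate), ncol(rate))
  structure(list(spikes = spikes, fs = fs, theta = NA_real_,
                 seed = as.integer(seed)),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains> theta = %s deg, %d samples x %d channels, %d spikes\n",
              format(x$theta), nrow(x$spikes), ncol(x$spikes), sum(x$spikes)))
  invisible(x)
}

# Deterministic part of one STN set's response; silence gating zeroes the
# rate wherever both ears carry digital silence (no input, no spikes).
stn_rate <- function(subbands, params, cue_params) {
  cues <- extract_cues(subbands, params$best_itd, cue_params)
  drive <- stn_drive(cues, params)
  rate <- activation(drive, params)
  floor_e <- env_floor_energy(cue_params)
  rate[cues$env_left <= floor_e & cues$env_right <= floor_e] <- 0
  rate
}

#' Build the default bank of STN sets
#'
#' One [stn_params()] per preferred azimuth, with best ITDs from
#' [woodworth_itd()], best ILDs from [derive_ild_table()], and sigmoid
#' parameters from [calibrate_sigmoid()] (shared by all sets).
#'
#' @param thetas preferred azimuths in degrees (default `0, +/-30, +/-60`,
#'   matching the five-source mixture geometry).
#' @param hrtf an `hrtf_set` (default: spherical model at `spec$fs`).
#' @param spec a [filterbank_spec()].
#' @param cue_params a [cue_params()].
#' @param ild_tolerance,itd_weight,ild_weight,rate_max forwarded to
#'   [stn_params()].
#' @param sigmoid sigmoid parameters as `c(midpoint, slope)`, or `NULL` to
#'   calibrate on a diotic white-noise probe.
#' @param seed integer seed for the ILD-table probe and calibration.
#' @return object of class `stn_bank`: list of `stn_params` plus the shared
#'   `spec`, `cue_params`, and `hrtf`.
#' @export
stn_bank <- function(thetas = c(0, -30, 30, -60, 60), hrtf = NULL,
                     spec = filterbank_spec(), cue_params = NULL,
                     ild_tolerance = 5, itd_weight = 1, ild_weight = 1,
                     rate_max = 500, sigmoid = NULL, seed = 1L) {
  if (is.null(cue_params)) cue_params <- default_cue_params()
  if (is.null(hrtf)) hrtf <- spherical_hrtf_set(azimuths = thetas, fs = spec$fs)
  ild_tab <- derive_ild_table(hrtf, thetas, spec, seed = derive_seed(seed, 1L))
  if (is.null(sigmoid)) {
    sigmoid <- calibrate_sigmoid(spec, cue_params, seed = derive_seed(seed, 2L))
  }
  sets <- lapply(seq_along(thetas), function(i) {
    stn_params(theta = thetas[i], best_ild = ild_tab[i, ],
               ild_tolerance = ild_tolerance, itd_weight = itd_weight,
               ild_weight = ild_weight, sigmoid_midpoint = sigmoid[1L],
               sigmoid_slope = sigmoid[2L], rate_max = rate_max)
  })
  names(sets) <- as.character(thetas)
  structure(list(sets = sets, thetas = thetas, spec = spec,
                 cue_params = cue_params, hrtf = hrtf,
                 ild_table = ild_tab, sigmoid = sigmoid),
            class = "stn_bank")
}

#' @export
print.stn_bank <- function(x, ...) {
  cat(sprintf("<stn_bank> %d STN sets at [%s] deg, %d channels, sigmoid (s0 = %.3f, k = %.3f)\n",
              length(x$sets), paste(x$thetas, collapse = ", "),
              x$spec$n_channels, x$sigmoid[1], x$sigmoid[2]))
  invisible(x)
}

#' Calibrate the sigmoid operating point
#'
#' The sigmoid midpoint is placed at half the maximum drive an on-target
#' (0 degree) neuron receives for a diotic white-noise probe, and the slope
#' at a quarter of the midpoint, so the probe spans the full dynamic range of
#' the rate function.
#'
#' @param spec a [filterbank_spec()].
#' @param cue_params a [cue_params()].
#' @param seed integer seed for the probe noise.
#' @param duration probe duration in seconds (default 0.5).
#' @return numeric `c(midpoint, slope)` in drive units.
#' @export
calibrate_sigmoid <- function(spec = filterbank_spec(),
                              cue_params = cue_params(), seed = 1L,
                              duration = 0.5) {
  set.seed(seed)
  probe <- rnorm(round(duration * spec$fs))
  probe <- probe / max(abs(probe)) * 0.5
  sb <- analyze_binaural(cbind(probe, probe), spec)
  params <- stn_params(theta = 0, best_itd = 0,
                       best_ild = rep(0, spec$n_channels))
  cues <- extract_cues(sb, 0, cue_params)
  drive <- stn_drive(cues, params)
  skip <- round(0.05 * spec$fs)
  s0 <- 0.5 * max(drive[-seq_len(skip), ])
  c(midpoint = s0, slope = s0 / 4)
}

#' Run the midbrain stage for every STN set
#'
#' For each preferred azimuth: extract cues at that set's best ITD, compute
#' the drive and rate, and draw Poisson spikes (one deterministic child seed
#' per set).
#'
#' @param subbands a [analyze_binaural()] result.
#' @param bank an [stn_bank()].
#' @param seed integer master seed for the spike generators.
#' @param return_rates logical; also return the deterministic rate matrices.
#' @return named list of `spike_trains` (one per azimuth). With
#'   `return_rates = TRUE`, a list with elements `spikes` and `rates`.
#' @export
run_midbrain <- function(subbands, bank, seed = 1L, return_rates = FALSE) {
  stopifnot(inherits(bank, "stn_bank"))
  rates <- lapply(bank$sets, function(p) {
    stn_rate(subbands, p, bank$cue_params)
  })
  spikes <- lapply(seq_along(rates), function(i) {
    st <- poisson_spikes(rates[[i]], subbands$fs, derive_seed(seed, 100L + i))
    st$theta <- bank$thetas[i]
    st
  })
  names(spikes) <- names(bank$sets)
  if (return_rates) list(spikes = spikes, rates = rates) else spikes
}

#' Export spike trains as an event list
#'
#' One row per spike with columns `time_s`, `channel_index`, `theta_deg`;
#' suitable for raster plots.
#'
#' @param spike_list list of `spike_trains` (or a single one).
#' @return a tibble.
#' @export
spike_events <- function(spike_list) {
  if (inherits(spike_list, "spike_trains")) spike_list <- list(spike_list)
  rows <- lapply(spike_list, function(st) {
    idx <- which(st$spikes == 1, arr.ind = TRUE)
    tibble::tibble(time_s = (idx[, 1L] - 1L) / st$fs,
                   channel_index = as.integer(idx[, 2L]),
                   theta_deg = st$theta)
  })
  do.call(rbind, rows)
}
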