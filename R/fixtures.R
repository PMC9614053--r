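#' Seeded white Gaussian noise probe
#'
#' @param duration seconds.
#' @param fs sample rate in Hz.
#' @param seed integer seed.
#' @param rms_target root-mean-square level (default 0.05).
#' @return mono numeric vector.
#' @export
white_noise <- function(duration, fs = 44100, seed = 1L, rms_target = 0.05) {
  abort_if(duration <= 0, "duration must be positive")
  set.seed(seed)
  x <- rnorm(round(duration * fs))
  x / rms(x) * rms_target
}

#' Speech-like synthetic signal
#'
#' A deterministic-given-seed stand-in for a recorded monosyllabic-word
#' sentence: a harmonic complex with a slowly drifting fundamental
#' (100-300 Hz), a formant-like spectral envelope confined to 0.2-8 kHz,
#' slow (2-8 Hz) amplitude modulation, and a grid of `n_segments` word-like
#' onsets. All generators called with the same `duration` share the onset
#' grid, emulating word-aligned competing sentences.
#'
#' @param duration seconds.
#' @param fs sample rate in Hz.
#' @param seed integer seed.
#' @param n_segments number of word-like segments (default 5).
#' @return mono numeric vector with RMS 0.05.
#' @export
synth_speechlike <- function(duration, fs = 44100, seed = 1L,
                             n_segments = 5L) {
  abort_if(duration <= 0, "duration must be positive")
  set.seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  # drifting fundamental: geometric mean ~170 Hz, +/- ~0.5 octave drift
  drift <- runif(1, 0.3, 1.2)
  f0 <- 170 * 2^(0.45 * sin(2 * pi * drift * t + runif(1, 0, 2 * pi)))
  phase0 <- 2 * pi * cumsum(f0) / fs
  # formant-like envelope, seeded formant positions
  formants <- c(runif(1, 350, 800), runif(1, 1000, 1800), runif(1, 2200, 3200))
  bw <- c(350, 500, 650)
  spec_env <- function(f) {
    amp <- exp(-((f - formants[1])^2) / (2 * bw[1]^2)) +
      0.5 * exp(-((f - formants[2])^2) / (2 * bw[2]^2)) +
      0.3 * exp(-((f - formants[3])^2) / (2 * bw[3]^2)) +
      0.05 * exp(-f / 2500)
    amp * (f >= 100 & f <= 8000)
  }
  x <- numeric(n)
  for (h in seq_len(45L)) {
    fh <- h * f0
    amp <- spec_env(fh)
    if (all(amp == 0)) break
    x <- x + amp * sin(h * phase0 + runif(1, 0, 2 * pi))
  }
  # syllabic amplitude modulation, 2-8 Hz
  fm <- runif(1, 2, 8)
  am <- 0.35 + 0.65 * (0.5 + 0.5 * sin(2 * pi * fm * t + runif(1, 0, 2 * pi)))
  # shared word-onset grid: n_segments raised-cosine gates with short gaps
  seg <- duration / n_segments
  gate <- numeric(n)
  ramp <- 0.020
  for (s in seq_len(n_segments)) {
    t0 <- (s - 1) * seg
    t1 <- s * seg - 0.04 * seg
    up <- pmin(pmax((t - t0) / ramp, 0), 1)
    down <- pmin(pmax((t1 - t) / ramp, 0), 1)
    gate <- pmax(gate, pmin(up, down))
  }
  x <- x * am * gate
  x / rms(x) * 0.05
}

#' Specification of a multi-talker spatial mixture
#'
#' The default geometry matches the five-source cocktail-party layout: a
#' target straight ahead and four maskers at `+/-30` and `+/-60` degrees,
#' each masker at a common reference level and the target level set by the
#' target-to-masker ratio (TMR, defined per masker on pre-spatialization
#' RMS). The digital reference maps 55 dB SPL to -30 dBFS RMS.
#'
#' @param target_azimuth degrees (default 0).
#' @param masker_azimuths degrees (default `c(-30, 30, -60, 60)`).
#' @param tmr_db target-to-masker ratio in dB (default 0).
#' @param masker_level_db_spl nominal masker level (default 55).
#' @param dbfs_at_reference digital RMS level (dBFS) assigned to the
#'   reference SPL (default -30).
#' @param seed integer seed used when sources are generated.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(target_azimuth = 0,
                         masker_azimuths = c(-30, 30, -60, 60),
                         tmr_db = 0, masker_level_db_spl = 55,
                         dbfs_at_reference = -30, seed = 1L) {
  abort_if(length(masker_azimuths) == 0, "need at least one masker azimuth")
  abort_if(any(masker_azimuths == target_azimuth),
           "masker azimuths must differ from the target azimuth")
  structure(list(target_azimuth = target_azimuth,
                 masker_azimuths = masker_azimuths, tmr_db = tmr_db,
                 masker_level_db_spl = masker_level_db_spl,
                 dbfs_at_reference = dbfs_at_reference,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Build a spatial mixture and its clean-target reference
#'
#' Each masker is scaled to the common reference RMS, the target to
#' `reference + tmr_db`, all sources are spatialized at their azimuths, and
#' the binaural signals summed. The spatialized target alone is returned as
#' the evaluation reference.
#'
#' @param spec a [mixture_spec()].
#' @param hrtf an `hrtf_set`.
#' @param sources list of mono waveforms of equal length: the target first,
#'   then one per masker azimuth. `NULL` (default) generates
#'   [synth_speechlike()] sources of `duration` seconds from `spec$seed`.
#' @param duration used only when `sources` is `NULL` (default 1.5 s).
#' @return list with `mixture` (`[n x 2]`), `target_ref` (`[n x 2]`), and
#'   `manifest` (tibble: source index, azimuth, pre-spatialization RMS,
#'   seed).
#' @export
make_mixture <- function(spec, hrtf, sources = NULL, duration = 1.5) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(hrtf, "hrtf_set"))
  azimuths <- c(spec$target_azimuth, spec$masker_azimuths)
  if (is.null(sources)) {
    sources <- lapply(seq_along(azimuths), function(i) {
      synth_speechlike(duration, fs = hrtf$fs,
                       seed = derive_seed(spec$seed, i))
    })
  }
  abort_if(length(sources) != length(azimuths),
           "need 1 + length(masker_azimuths) source signals")
  n <- unique(lengths(sources))
  abort_if(length(n) != 1L, "sources must have equal durations")
  ref_rms <- 10^(spec$dbfs_at_reference / 20)
  levels <- c(ref_rms * 10^(spec$tmr_db / 20),
              rep(ref_rms, length(spec$masker_azimuths)))
  scaled <- Map(function(x, lv) x / rms(x) * lv, sources, levels)
  spatialized <- Map(function(x, az) spatialize(x, az, hrtf), scaled, azimuths)
  mixture <- Reduce(`+`, spatialized)
  list(mixture = mixture, target_ref = spatialized[[1L]],
       manifest = tibble::tibble(source = seq_along(azimuths),
                                 azimuth_deg = azimuths,
                                 rms = levels, seed = spec$seed))
}
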