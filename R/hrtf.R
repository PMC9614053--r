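#' Spherical-head HRTF pair for one azimuth
#'
#' A synthetic head-related impulse-response pair built from first
#' principles: the interaural delay is split symmetrically between the ears
#' (`+/- woodworth_itd(theta)/2`), the contralateral (far) ear receives a
#' single-pole low-pass head-shadow filter whose cutoff decreases with
#' `|theta|`, and the ipsilateral ear a mild high shelf. At `theta = 0` both
#' ears are identical. This is a stand-in for a measured manikin set (see
#' [load_sofa()]): it reproduces the qualitative structure of real HRTFs
#' (frequency-independent ITD, ILD growing with azimuth and frequency) but
#' none of the pinna/torso detail.
#'
#' @param theta azimuth in degrees, `|theta| <= 90`; positive is the
#'   listener's right (the left ear then lags and is shadowed).
#' @param head_radius head radius in meters (default 0.0875).
#' @param fs sample rate in Hz.
#' @param c_sound speed of sound in m/s (default 343).
#' @param shadow_strength scales the shadow time constant (default 1); the
#'   default is chosen so channel-wise ILDs approximate measured manikin
#'   magnitudes (a few dB at 500 Hz-1 kHz for lateral sources, 15-25 dB at
#'   8 kHz for `|theta| = 90`).
#' @param shelf_db ipsilateral high-shelf gain at `|theta| = 90`, dB
#'   (default 6).
#' @return list with numeric vectors `left` and `right` (equal length).
#' @export
spherical_hrtf <- function(theta, head_radius = 0.0875, fs = 44100,
                           c_sound = 343, shadow_strength = 1,
                           shelf_db = 6) {
  abort_if(abs(theta) > 90, "|theta| must be <= 90 degrees")
  base_delay <- round(0.0015 * fs)
  n_taps <- 4L * base_delay
  itd <- woodworth_itd(theta, head_radius, c_sound)
  half <- itd * fs / 2
  d_left <- as.integer(round(base_delay + half))
  d_right <- as.integer(round(base_delay - half))
  s <- sin(abs(theta) * pi / 180)
  # magnitude responses; linear-phase FIRs keep the interaural delay equal
  # to the Woodworth split at every frequency
  tau_shadow <- shadow_strength * (head_radius / c_sound) * s
  f_cut <- if (tau_shadow > 0) 1 / (2 * pi * tau_shadow) else Inf
  mag_shadow <- function(f) 1 / sqrt(1 + (f / f_cut)^2)
  f_shelf <- 2000
  mag_shelf <- function(f) {
    10^((shelf_db * s / 20) * (f / f_shelf)^2 / (1 + (f / f_shelf)^2))
  }
  if (theta >= 0) {
    mag_left <- mag_shadow
    mag_right <- mag_shelf
  } else {
    mag_left <- mag_shelf
    mag_right <- mag_shadow
  }
  list(left = linear_phase_fir(mag_left, d_left, n_taps, fs),
       right = linear_phase_fir(mag_right, d_right, n_taps, fs))
}

# Linear-phase FIR with the given magnitude response, centered at integer
# delay `center` (frequency-sampling design, Hann-windowed).
linear_phase_fir <- function(mag, center, n_taps, fs) {
  nfft <- 1024L
  f <- fs * (0:(nfft / 2)) / nfft
  M <- mag(f)
  M_full <- c(M, rev(M[2:(nfft / 2)]))
  ir0 <- Re(fft(M_full, inverse = TRUE)) / nfft  # zero-phase, circular
  half <- min(center, n_taps - center - 1L, nfft / 2 - 1L)
  lags <- -half:half
  taps <- ir0[(lags %% nfft) + 1L]
  w <- 0.5 + 0.5 * cos(pi * lags / (half + 1L))
  h <- numeric(n_taps)
  h[center + lags + 1L] <- taps * w
  h
}

#' Build an HRTF set from the spherical-head model
#'
#' @param azimuths azimuths to precompute, degrees (default covers the demo
#'   grid `0, +/-30, +/-45, +/-60, +/-90`).
#' @param fs sample rate in Hz.
#' @param ... passed to [spherical_hrtf()].
#' @return object of class `hrtf_set`.
#' @export
spherical_hrtf_set <- function(azimuths = c(0, -30, 30, -45, 45, -60, 60, -90, 90),
                               fs = 44100, ...) {
  irs <- lapply(azimuths, spherical_hrtf, fs = fs, ...)
  names(irs) <- as.character(azimuths)
  structure(list(azimuths = azimuths, irs = irs, fs = fs,
                 source_kind = "spherical_model", args = list(...)),
            class = "hrtf_set")
}

#' @export
print.hrtf_set <- function(x, ...) {
  cat(sprintf("<hrtf_set> %s, %d azimuths [%s], fs = %.0f Hz\n",
              x$source_kind, length(x$azimuths),
              paste(sort(x$azimuths), collapse = ", "), x$fs))
  invisible(x)
}

hrtf_lookup <- function(hrtf, theta) {
  i <- which(abs(hrtf$azimuths - theta) < 1e-6)
  if (length(i) >= 1L) return(hrtf$irs[[i[1L]]])
  if (identical(hrtf$source_kind, "spherical_model")) {
    return(do.call(spherical_hrtf,
                   c(list(theta = theta, fs = hrtf$fs), hrtf$args)))
  }
  # measured set: fall back to the nearest measured direction
  j <- which.min(abs(hrtf$azimuths - theta))
  if (abs(hrtf$azimuths[j] - theta) > 10) {
    stop("azimuth ", theta,
         " degrees not covered by the HRTF set and not interpolable",
         call. = FALSE)
  }
  warning("azimuth ", theta, " not measured; using nearest (",
          hrtf$azimuths[j], ")", call. = FALSE)
  hrtf$irs[[j]]
}

#' Spatialize a mono source at an azimuth
#'
#' Convolves the source with the left- and right-ear impulse responses and
#' trims to the input length.
#'
#' @param mono numeric vector.
#' @param theta azimuth in degrees.
#' @param hrtf an `hrtf_set`.
#' @return stereo matrix `[length(mono) x 2]`.
#' @export
spatialize <- function(mono, theta, hrtf) {
  ir <- hrtf_lookup(hrtf, theta)
  cbind(conv_columns(ir$left, matrix(mono, ncol = 1L))[, 1L],
        conv_columns(ir$right, matrix(mono, ncol = 1L))[, 1L])
}

#' Load a measured HRTF set from a SOFA file
#'
#' Reads a `SimpleFreeFieldHRIR` SOFA set (the standard distribution format
#' for measured HRTFs, e.g. KEMAR), restricted to horizontal-plane
#' measurements with `|azimuth| <= 90`, and resamples the impulse responses
#' to the pipeline sample rate. SOFA files are HDF5 containers; they are read
#' through the `h5py` Python library (the `python` binary on the PATH must
#' provide it), keeping this optional loader free of compiled HDF5
#' dependencies in R.
#'
#' @param path SOFA file path.
#' @param fs target sample rate in Hz.
#' @param elevation_tol keep measurements with `|elevation|` below this many
#'   degrees (default 5).
#' @return object of class `hrtf_set` with `source_kind = "sofa_file"`.
#' @export
load_sofa <- function(path, fs = 44100, elevation_tol = 5) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  python <- Sys.which("python")
  abort_if(python == "", "SOFA loading requires a `python` binary with h5py")
  out_dir <- tempfile("sofa")
  dir.create(out_dir)
  script <- file.path(out_dir, "dump.py")
  writeLines(c(
    "import sys, csv, h5py, numpy as np",
    "path, out = sys.argv[1], sys.argv[2]",
    "f = h5py.File(path, 'r')",
    "ir = np.asarray(f['Data.IR']); pos = np.asarray(f['SourcePosition'])",
    "sr = float(np.ravel(f['Data.SamplingRate'])[0])",
    "if ir.ndim != 3 or ir.shape[1] != 2: raise SystemExit('not SimpleFreeFieldHRIR')",
    "np.savetxt(out + '/pos.csv', pos, delimiter=',')",
    "np.savetxt(out + '/ir_l.csv', ir[:, 0, :], delimiter=',')",
    "np.savetxt(out + '/ir_r.csv', ir[:, 1, :], delimiter=',')",
    "open(out + '/fs.txt', 'w').write(str(sr) + '\\n')"
  ), script)
  status <- system2(python, c(script, shQuote(path), shQuote(out_dir)),
                    stdout = FALSE, stderr = FALSE)
  abort_if(status != 0, paste0("not a readable SOFA (SimpleFreeFieldHRIR) file: ", path))
  pos <- as.matrix(read.csv(file.path(out_dir, "pos.csv"), header = FALSE))
  ir_l <- as.matrix(read.csv(file.path(out_dir, "ir_l.csv"), header = FALSE))
  ir_r <- as.matrix(read.csv(file.path(out_dir, "ir_r.csv"), header = FALSE))
  fs_in <- as.numeric(readLines(file.path(out_dir, "fs.txt")))
  # SOFA azimuth: counterclockwise 0-360 (90 = left); convert to signed
  # right-positive azimuth
  az <- ((-pos[, 1] + 180) %% 360) - 180
  keep <- abs(pos[, 2]) <= elevation_tol & abs(az) <= 90
  abort_if(!any(keep), "no horizontal-plane measurements in the SOFA file")
  az <- az[keep]
  ir_l <- ir_l[keep, , drop = FALSE]
  ir_r <- ir_r[keep, , drop = FALSE]
  ord <- order(az)
  irs <- lapply(ord, function(i) {
    l <- as.numeric(ir_l[i, ])
    r <- as.numeric(ir_r[i, ])
    if (fs_in != fs) {
      l <- resample_audio(l, fs_in, fs)
      r <- resample_audio(r, fs_in, fs)
    }
    list(left = l, right = r)
  })
  azimuths <- az[ord]
  names(irs) <- as.character(azimuths)
  structure(list(azimuths = azimuths, irs = irs, fs = fs,
                 source_kind = "sofa_file", args = list()),
            class = "hrtf_set")
}
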