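#' Alpha-function smoothing kernel
#'
#' `h(t) = t * exp(-t / tau_h)` sampled at `fs`, starting at `t = 0` (so
#' `h[1] = 0`) and truncated to `length` seconds. The kernel peaks at
#' `t = tau_h`.
#'
#' @param tau_h kernel time constant in seconds (default 0.020).
#' @param length kernel duration in seconds (default 0.100).
#' @param fs sample rate in Hz.
#' @return object of class `alpha_kernel`: list with `samples`, `tau_h`,
#'   `length`, `fs`.
#' @export
alpha_kernel <- function(tau_h = 0.020, length = 0.100, fs = 44100) {
  abort_if(tau_h <= 0 || length <= 0, "tau_h and length must be positive")
  n <- round(length * fs)
  t <- (seq_len(n) - 1L) / fs
  structure(list(samples = t * exp(-t / tau_h), tau_h = tau_h,
                 length = length, fs = fs),
            class = "alpha_kernel")
}

new_mask <- function(values, kind, theta = NA_real_, fs = NA_real_,
                     normalized = FALSE) {
  structure(list(values = values, kind = kind, theta = theta, fs = fs,
                 normalized = normalized),
            class = "tf_mask")
}

#' @export
print.tf_mask <- function(x, ...) {
  cat(sprintf("<tf_mask> %s, theta = %s deg, %d samples x %d channels%s\n",
              x$kind, format(x$theta), nrow(x$values), ncol(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Firing-rate mask from spike trains
#'
#' Convolves each channel's spike train with the smoothing kernel (causally,
#' truncated to the signal length), yielding a smoothed firing-rate-like
#' non-negative time-frequency mask.
#'
#' @param spikes a [poisson_spikes()] result.
#' @param kernel an [alpha_kernel()] at the same sample rate.
#' @return a `tf_mask` of kind `"frmask"`.
#' @export
compute_frmask <- function(spikes, kernel) {
  stopifnot(inherits(spikes, "spike_trains"), inherits(kernel, "alpha_kernel"))
  abort_if(spikes$fs != kernel$fs, "spike and kernel sample rates differ")
  vals <- conv_columns(kernel$samples, spikes$spikes)
  vals[vals < 0] <- 0  # guard FFT round-off
  new_mask(vals, "frmask", theta = spikes$theta, fs = spikes$fs)
}

#' Firing-rate mask directly from the deterministic rate
#'
#' Convolution of `rate / fs` with the kernel; this equals the expectation
#' of [compute_frmask()] over Poisson draws, so the spike path is an
#' unbiased sampling of this rate path.
#'
#' @param rate rate matrix in spikes/s.
#' @param kernel an [alpha_kernel()].
#' @param theta optional azimuth tag in degrees.
#' @return a `tf_mask` of kind `"frmask"`.
#' @export
rate_frmask <- function(rate, kernel, theta = NA_real_) {
  stopifnot(inherits(kernel, "alpha_kernel"))
  vals <- conv_columns(kernel$samples, rate / kernel$fs)
  vals[vals < 0] <- 0
  new_mask(vals, "frmask", theta = theta, fs = kernel$fs)
}

scale_mask_values <- function(values, scaling = c("global", "per_channel",
                                                  "running")) {
  scaling <- match.arg(scaling)
  if (scaling == "global") {
    m <- max(values)
    if (m > 0) values <- values / m
  } else if (scaling == "per_channel") {
    m <- apply(values, 2L, max)
    m[m <= 0] <- 1
    values <- sweep(values, 2L, m, "/")
  } else {
    m <- cummax(apply(values, 1L, max))
    m[m <= 0] <- 1
    values <- values / m
  }
  values
}

#' Lateral-inhibition sharpened mask
#'
#' `DiffMask = max(FRMask_0 - a * sum(FRMask_theta), 0)`, computed after
#' scaling the masks to `[0, 1]`. The default `"joint"` scaling divides all
#' masks by their common maximum (over spatial channels, time and frequency
#' jointly): the firing rates of all STN sets already share one scale (same
#' sigmoid and maximum rate), and preserving their relative amplitudes is
#' what lets the subtraction discriminate locations. `"per_mask"` instead
#' scales each spatial channel's mask by its own maximum, `"per_channel"`
#' each frequency channel separately, and `"running"` is a causal
#' running-maximum variant of `"per_mask"`. An all-zero mask is left
#' all-zero.
#'
#' @param frmask_center the on-target `tf_mask`.
#' @param frmasks_off list of off-target `tf_mask`s (same shapes).
#' @param a inhibition scaling factor (default 0.5), shared across all
#'   frequencies and spatial channels.
#' @param scaling mask normalization mode (default `"joint"`).
#' @return a `tf_mask` of kind `"diffmask"`, `normalized = TRUE`.
#' @export
compute_diffmask <- function(frmask_center, frmasks_off, a = 0.5,
                             scaling = c("joint", "per_mask", "per_channel",
                                         "running")) {
  stopifnot(inherits(frmask_center, "tf_mask"))
  scaling <- match.arg(scaling)
  dims <- dim(frmask_center$values)
  for (m in frmasks_off) {
    stopifnot(inherits(m, "tf_mask"))
    abort_if(!identical(dim(m$values), dims), "mask shapes differ")
  }
  if (scaling == "joint") {
    mx <- max(max(frmask_center$values),
              vapply(frmasks_off, function(m) max(m$values), numeric(1)))
    if (mx <= 0) mx <- 1
    center <- frmask_center$values / mx
    inhib <- 0
    for (m in frmasks_off) inhib <- inhib + m$values / mx
  } else {
    mode <- c(per_mask = "global", per_channel = "per_channel",
              running = "running")[[scaling]]
    center <- scale_mask_values(frmask_center$values, mode)
    inhib <- 0
    for (m in frmasks_off) inhib <- inhib + scale_mask_values(m$values, mode)
  }
  vals <- pmax(center - a * inhib, 0)
  new_mask(vals, "diffmask", theta = frmask_center$theta,
           fs = frmask_center$fs, normalized = TRUE)
}

#' Apply a time-frequency mask to binaural subbands
#'
#' Point-multiplies the mask with each ear's subbands and sums the channels
#' without weighting, returning a binaural waveform that retains the natural
#' interaural cues of the mixture (the same per-channel gain is applied to
#' both ears).
#'
#' @param mask a `tf_mask`.
#' @param subbands a [analyze_binaural()] result of the same shape.
#' @return stereo matrix `[n_samples x 2]`.
#' @export
apply_mask <- function(mask, subbands) {
  stopifnot(inherits(mask, "tf_mask"), inherits(subbands, "subbands"))
  abort_if(!identical(dim(mask$values), dim(subbands$left)),
           "mask and subband shapes differ")
  cbind(rowSums(mask$values * subbands$left),
        rowSums(mask$values * subbands$right))
}

#' End-to-end segregation of a binaural mixture
#'
#' Runs the full pipeline: gammatone analysis of both ears, spatially tuned
#' neurons and Poisson spiking for every azimuth in the bank, kernel
#' smoothing into FRMasks, optional lateral-inhibition sharpening into a
#' DiffMask, and mask application / resynthesis.
#'
#' @param stereo_in stereo matrix `[n_samples x 2]` at the bank's sample
#'   rate.
#' @param bank an [stn_bank()]; its 0-degree set is the reconstruction
#'   target.
#' @param mask `"diffmask"` (default) or `"frmask"`.
#' @param kernel an [alpha_kernel()] (default parameters at the bank's fs).
#' @param a DiffMask scaling factor (default 0.5).
#' @param scaling mask normalization mode (see [compute_diffmask()]).
#' @param off_thetas azimuths of the off-target sets used for inhibition
#'   (default: every non-zero azimuth in the bank).
#' @param seed integer seed for the spike generators.
#' @param use_rate logical; bypass the Poisson stage and smooth the
#'   deterministic rates instead (default `FALSE`).
#' @param compensate_latency logical; advance the mask by `tau_h` to undo
#'   the kernel's group delay (default `FALSE`).
#' @param details logical; also return the masks and spike trains.
#' @return stereo matrix `[n_samples x 2]`; with `details = TRUE`, a list
#'   with `audio`, `masks` (both kinds), and `spikes`.
#' @export
segregate <- function(stereo_in, bank, mask = c("diffmask", "frmask"),
                      kernel = NULL, a = 0.5,
                      scaling = c("joint", "per_mask", "per_channel",
                                  "running"),
                      off_thetas = NULL, seed = 1L, use_rate = FALSE,
                      compensate_latency = FALSE, details = FALSE) {
  mask <- match.arg(mask)
  scaling <- match.arg(scaling)
  stopifnot(inherits(bank, "stn_bank"))
  abort_if(!is.matrix(stereo_in) || ncol(stereo_in) != 2L,
           "stereo_in must be an [n x 2] matrix")
  abort_if(!any(bank$thetas == 0), "the bank must contain a 0-degree set")
  if (is.null(kernel)) kernel <- alpha_kernel(fs = bank$spec$fs)
  abort_if(kernel$fs != bank$spec$fs, "kernel and bank sample rates differ")
  sb <- analyze_binaural(stereo_in, bank$spec)
  mb <- run_midbrain(sb, bank, seed = seed, return_rates = TRUE)
  frmasks <- if (use_rate) {
    lapply(seq_along(mb$rates), function(i) {
      rate_frmask(mb$rates[[i]], kernel, theta = bank$thetas[i])
    })
  } else {
    lapply(mb$spikes, compute_frmask, kernel = kernel)
  }
  names(frmasks) <- names(bank$sets)
  center <- frmasks[[which(bank$thetas == 0)]]
  if (is.null(off_thetas)) off_thetas <- bank$thetas[bank$thetas != 0]
  offs <- frmasks[as.character(off_thetas)]
  selected <- if (mask == "diffmask") {
    compute_diffmask(center, offs, a = a, scaling = scaling)
  } else {
    norm_center <- center
    norm_center$values <- scale_mask_values(center$values, "global")
    norm_center$normalized <- TRUE
    norm_center
  }
  if (compensate_latency) {
    shift <- round(kernel$tau_h * kernel$fs)
    selected$values <- apply(selected$values, 2L, shift_samples, n = -shift)
  }
  audio <- apply_mask(selected, sb)
  if (!details) return(audio)
  diff_mask <- if (mask == "diffmask") selected else
    compute_diffmask(center, offs, a = a, scaling = scaling)
  list(audio = audio, mask = selected, frmasks = frmasks,
       diffmask = diff_mask, spikes = if (use_rate) NULL else mb$spikes,
       rates = mb$rates, subbands = sb)
}

#' Export a mask to CSV
#'
#' Writes the mask values plus a metadata CSV (`fs`, `kind`, `theta`,
#' center frequencies).
#'
#' @param mask a `tf_mask`.
#' @param dir output directory.
#' @param center_freqs optional center-frequency vector for the metadata.
#' @param stride keep every `stride`-th sample (default 1).
#' @return the directory, invisibly.
#' @export
export_mask <- function(mask, dir, center_freqs = NULL, stride = 1L) {
  stopifnot(inherits(mask, "tf_mask"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- seq(1L, nrow(mask$values), by = stride)
  write.csv(mask$values[idx, , drop = FALSE],
            file.path(dir, "mask.csv"), row.names = FALSE)
  meta <- data.frame(fs = mask$fs, kind = mask$kind, theta = mask$theta)
  write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  if (!is.null(center_freqs)) {
    write.csv(data.frame(channel = seq_along(center_freqs),
                         center_freq_hz = center_freqs),
              file.path(dir, "center_freqs.csv"), row.names = FALSE)
  }
  invisible(dir)
}
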