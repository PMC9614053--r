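#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline in one nested list that can be
#' round-tripped through YAML. Two presets are provided: `"full"` is the
#' default wideband analysis (64 channels, 200 Hz-20 kHz, fs 44.1 kHz);
#' `"speech"` restricts the bank to the speech band (64 channels,
#' 200 Hz-8 kHz, fs 20 kHz), the range used for the per-channel spatial
#' tuning illustrations, and is the cheaper choice for objective evaluation.
#'
#' @param preset `"full"` (default) or `"speech"`.
#' @param ... named overrides of individual fields, e.g.
#'   `filterbank = list(n_channels = 32)` merges into the preset.
#' @return object of class `seg_config` (a nested list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$filterbank$n_channels
#' @export
pipeline_config <- function(preset = c("full", "speech"), ...) {
  preset <- match.arg(preset)
  base <- list(
    filterbank = list(n_channels = 64L, f_min_hz = 200, f_max_hz = 20000,
                      q = 9.26449, b_min_hz = 24.7, fs_hz = 44100),
    cues = list(corr_time_constant_s = 0.005, env_time_constant_s = 0.005,
                env_floor_db = -100, log_envelope = TRUE),
    stn = list(thetas_deg = c(0, -30, 30, -60, 60), ild_tolerance_db = 5,
               itd_weight = 1, ild_weight = 1, rate_max_hz = 500,
               sigmoid_midpoint = NULL, sigmoid_slope = NULL,
               head_radius_m = 0.0875, c_sound_m_s = 343),
    kernel = list(tau_h_s = 0.020, length_s = 0.100),
    diffmask = list(a = 0.5, scaling = "joint", off_thetas_deg = NULL,
                    compensate_latency = FALSE),
    hrtf = list(kind = "spherical_model", sofa_path = NULL),
    fixtures = list(tmr_db = 0, masker_azimuths_deg = c(-30, 30, -60, 60),
                    masker_level_db_spl = 55, dbfs_at_reference = -30,
                    duration_s = 1.5),
    seed = 1L
  )
  if (preset == "speech") {
    base$filterbank$f_max_hz <- 8000
    base$filterbank$fs_hz <- 20000
  }
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  structure(base, class = "seg_config")
}

#' @export
print.seg_config <- function(x, ...) {
  cat(sprintf(
    "<seg_config> %d channels %.0f-%.0f Hz @ %.0f Hz; STNs at [%s]; kernel tau_h = %.0f ms; a = %.2f\n",
    x$filterbank$n_channels, x$filterbank$f_min_hz, x$filterbank$f_max_hz,
    x$filterbank$fs_hz, paste(x$stn$thetas_deg, collapse = ", "),
    1000 * x$kernel$tau_h_s, x$diffmask$a))
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `seg_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

#' @rdname read_config
#' @param config a `seg_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build pipeline objects from a configuration
#'
#' `config_filterbank_spec()`, `config_cue_params()`, `config_kernel()`, and
#' `config_hrtf()` construct the corresponding stage objects;
#' `build_bank()` assembles the full [stn_bank()] (deriving the ILD table
#' and, unless fixed in the config, calibrating the sigmoid).
#'
#' @param config a [pipeline_config()].
#' @return the corresponding stage object.
#' @export
config_filterbank_spec <- function(config) {
  fb <- config$filterbank
  filterbank_spec(n_channels = fb$n_channels, f_min = fb$f_min_hz,
                  f_max = fb$f_max_hz, Q = fb$q, b_min = fb$b_min_hz,
                  fs = fb$fs_hz)
}

#' @rdname config_filterbank_spec
#' @export
config_cue_params <- function(config) {
  cu <- config$cues
  cue_params(corr_time_constant = cu$corr_time_constant_s,
             env_time_constant = cu$env_time_constant_s,
             env_floor = cu$env_floor_db,
             log_envelope = cu$log_envelope)
}

#' @rdname config_filterbank_spec
#' @export
config_kernel <- function(config) {
  alpha_kernel(tau_h = config$kernel$tau_h_s,
               length = config$kernel$length_s,
               fs = config$filterbank$fs_hz)
}

#' @rdname config_filterbank_spec
#' @export
config_hrtf <- function(config) {
  if (identical(config$hrtf$kind, "sofa_file")) {
    abort_if(is.null(config$hrtf$sofa_path),
             "hrtf kind is sofa_file but sofa_path is not set")
    load_sofa(config$hrtf$sofa_path, fs = config$filterbank$fs_hz)
  } else {
    spherical_hrtf_set(
      azimuths = sort(unique(c(config$stn$thetas_deg, 0, -30, 30, -45, 45,
                               -60, 60, -90, 90))),
      fs = config$filterbank$fs_hz,
      head_radius = config$stn$head_radius_m,
      c_sound = config$stn$c_sound_m_s)
  }
}

#' @rdname config_filterbank_spec
#' @param hrtf optional pre-built `hrtf_set` (defaults to [config_hrtf()]).
#' @param seed integer seed for ILD-table derivation and calibration
#'   (defaults to `config$seed`).
#' @export
build_bank <- function(config, hrtf = NULL, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(hrtf)) hrtf <- config_hrtf(config)
  sigmoid <- NULL
  if (!is.null(config$stn$sigmoid_midpoint)) {
    sigmoid <- c(config$stn$sigmoid_midpoint, config$stn$sigmoid_slope)
  }
  stn_bank(thetas = config$stn$thetas_deg, hrtf = hrtf,
           spec = config_filterbank_spec(config),
           cue_params = config_cue_params(config),
           ild_tolerance = config$stn$ild_tolerance_db,
           itd_weight = config$stn$itd_weight,
           ild_weight = config$stn$ild_weight,
           rate_max = config$stn$rate_max_hz,
           sigmoid = sigmoid, seed = seed)
}
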