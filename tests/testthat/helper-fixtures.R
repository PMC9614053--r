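# Shared fixtures, built once per test run. Tests use the speech-band
# preset (64 channels, 200 Hz-8 kHz, fs 20 kHz) where full bandwidth is not
# the point: it exercises identical code paths at a quarter of the cost.

.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

speech_spec <- function() {
  cached_fixture("speech_spec",
                 config_filterbank_spec(pipeline_config("speech")))
}

speech_hrtf <- function() {
  cached_fixture("speech_hrtf", spherical_hrtf_set(fs = speech_spec()$fs))
}

# five-set bank (0, +/-30, +/-60): the default processing configuration
speech_bank5 <- function() {
  cached_fixture("speech_bank5",
                 stn_bank(hrtf = speech_hrtf(), spec = speech_spec(),
                          seed = 1L))
}

# nine-set bank (adds +/-45, +/-90): the tuning-curve demo configuration
speech_bank9 <- function() {
  cached_fixture("speech_bank9",
                 stn_bank(thetas = c(0, -30, 30, -45, 45, -60, 60, -90, 90),
                          hrtf = speech_hrtf(), spec = speech_spec(),
                          seed = 1L))
}

# deterministic-rate tuning curves on the full probe grid, reused by
# several property tests
speech_tuning9 <- function() {
  cached_fixture("speech_tuning9",
                 tuning_curves(speech_bank9(), duration = 0.3, mode = "rate",
                               seed = 3L))
}

rms_of <- function(x) sqrt(mean(x^2))
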