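test_that("every STN set peaks at its own azimuth on the probe grid", {
  tc <- speech_tuning9()
  for (th in unique(tc$stn_theta)) {
    sub <- tc[tc$stn_theta == th, ]
    expect_identical(sub$stim_azimuth[which.max(sub$response)], th)
  }
  expect_true(all(tc$response >= 0))
})

test_that("spatial leakage is present but mirror-symmetric", {
  tc <- speech_tuning9()
  r0 <- tc[tc$stn_theta == 0, ]
  expect_gt(r0$response[r0$stim_azimuth == 90], 0)
  expect_gt(r0$response[r0$stim_azimuth == -90], 0)
  # left-right mirror within 2 percent on deterministic rates
  for (th in c(30, 45, 60, 90)) {
    for (phi in unique(tc$stim_azimuth)) {
      a <- tc$response[tc$stn_theta == th & tc$stim_azimuth == phi]
      b <- tc$response[tc$stn_theta == -th & tc$stim_azimuth == -phi]
      expect_lt(abs(a - b) / b, 0.02)
    }
  }
})

test_that("silence elicits well under 1 percent of the noise-probe response", {
  bank <- speech_bank9()
  zero <- analyze_binaural(matrix(0, 3000, 2), bank$spec)
  mb <- run_midbrain(zero, bank, seed = 1, return_rates = TRUE)
  silent_total <- sum(vapply(mb$rates, sum, numeric(1)))
  wgn_total <- sum(speech_tuning9()$response)
  expect_lt(silent_total, 0.01 * wgn_total)
})

test_that("spike-mode tuning agrees with rate mode at the peaks", {
  bank <- speech_bank5()
  tc <- tuning_curves(bank, stim_azimuths = c(0, -60, 60), duration = 0.25,
                      mode = "spikes", seed = 13)
  for (th in c(0, -60, 60)) {
    sub <- tc[tc$stn_theta == th, ]
    expect_identical(sub$stim_azimuth[which.max(sub$response)], th)
  }
})

test_that("DiffMask sharpens the 0-degree set and more off-masks suppress more", {
  dt <- cached_fixture("diffmask_tuning",
                       diffmask_tuning(speech_bank5(),
                                       stim_azimuths = c(0, -90, 90),
                                       duration = 0.3, seed = 3))
  total <- function(stage, az) {
    sum(dt$response[dt$stage == stage & dt$stim_azimuth == az])
  }
  for (az in c(-90, 90)) {
    # relative side response shrinks after the DiffMask operation
    expect_lt(total("full", az) / total("full", 0),
              total("before", az) / total("before", 0))
    # and the full off-target set suppresses at least as much as either
    # two-mask subset
    expect_lte(total("full", az), total("pm30", az) + 1e-9)
    expect_lte(total("full", az), total("pm60", az) + 1e-9)
  }
  # per channel: subtraction plus rectification can never increase
  for (az in c(-90, 90)) {
    before <- dt$response[dt$stage == "before" & dt$stim_azimuth == az]
    after <- dt$response[dt$stage == "full" & dt$stim_azimuth == az]
    expect_true(all(after <= before + 1e-9))
  }
})

test_that("a = 0 leaves the tuning curves unchanged up to normalization", {
  dt0 <- diffmask_tuning(speech_bank5(), stim_azimuths = c(0, 90),
                         duration = 0.2, a = 0, seed = 3)
  # normalization is per utterance, so compare within each stimulus
  for (az in c(0, 90)) {
    before <- dt0$response[dt0$stage == "before" & dt0$stim_azimuth == az]
    full <- dt0$response[dt0$stage == "full" & dt0$stim_azimuth == az]
    ratio <- full[before > 0] / before[before > 0]
    expect_lt(diff(range(ratio)), 1e-6)
  }
})

test_that("the parameter sweep flags its argmax and is reproducible", {
  bank <- speech_bank5()
  sw1 <- parameter_sweep(bank, tau_h_grid = 0.020, a_grid = 0.5,
                         n_mixtures = 1L, duration = 0.8, seed = 5)
  expect_identical(nrow(sw1), 1L)
  expect_true(sw1$is_best[1])
  expect_true(sw1$mean_stoi >= 0 && sw1$mean_stoi <= 1)
  sw2 <- parameter_sweep(bank, tau_h_grid = c(0.010, 0.020),
                         a_grid = c(0.25, 0.5), n_mixtures = 1L,
                         duration = 0.8, seed = 5)
  expect_identical(sum(sw2$is_best), 1L)
  expect_true(all(is.finite(sw2$mean_stoi)))
  expect_gt(diff(range(sw2$mean_stoi)), 0)  # surface is not constant
  sw2b <- parameter_sweep(bank, tau_h_grid = c(0.010, 0.020),
                          a_grid = c(0.25, 0.5), n_mixtures = 1L,
                          duration = 0.8, seed = 5)
  expect_identical(sw2$mean_stoi, sw2b$mean_stoi)
  expect_error(parameter_sweep(bank, tau_h_grid = numeric(0)), "non-empty")
})

test_that("autoplot methods return ggplot objects", {
  tc <- speech_tuning9()
  expect_s3_class(ggplot2::autoplot(tc), "ggplot")
  dt <- cached_fixture("diffmask_tuning",
                       diffmask_tuning(speech_bank5(),
                                       stim_azimuths = c(0, -90, 90),
                                       duration = 0.3, seed = 3))
  expect_s3_class(ggplot2::autoplot(dt), "ggplot")
})
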