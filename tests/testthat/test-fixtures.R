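test_that("spherical HRTF is symmetric, delay-true, and shadowed", {
  fs <- 20000
  h0 <- spherical_hrtf(0, fs = fs)
  expect_identical(h0$left, h0$right)

  h90 <- spherical_hrtf(90, fs = fs)
  cc <- stats::ccf(h90$left, h90$right, lag.max = 40, plot = FALSE)
  measured <- cc$lag[which.max(cc$acf)]
  expect_lte(abs(measured - woodworth_itd(90) * fs), 1)

  hm <- spherical_hrtf(-37, fs = fs)
  hp <- spherical_hrtf(37, fs = fs)
  expect_equal(hm$left, hp$right, tolerance = 1e-12)
  expect_equal(hm$right, hp$left, tolerance = 1e-12)
  expect_error(spherical_hrtf(100, fs = fs), "90")
})

test_that("spatialized noise shows head-shadow ILD growing with frequency", {
  spec <- speech_spec()
  hrtf <- speech_hrtf()
  tab <- derive_ild_table(hrtf, 60, spec, seed = 31)
  cf <- erb_center_frequencies(spec)
  expect_gt(abs(tab[1, which.min(abs(cf - 8000))]),
            abs(tab[1, which.min(abs(cf - 500))]))
})

test_that("spatialize preserves length, mirrors, and passes theta = 0 through", {
  hrtf <- speech_hrtf()
  x <- white_noise(0.2, fs = hrtf$fs, seed = 8)
  y0 <- spatialize(x, 0, hrtf)
  expect_identical(dim(y0), c(length(x), 2L))
  expect_equal(y0[, 1], y0[, 2], tolerance = 1e-12)
  # theta = 0 filter is a pure delay: correlation with the delayed input is 1
  d <- round(0.0015 * hrtf$fs)
  expect_equal(y0[-(1:d), 1], x[1:(length(x) - d)], tolerance = 1e-9)

  yp <- spatialize(x, 45, hrtf)
  ym <- spatialize(x, -45, hrtf)
  expect_equal(ym, yp[, 2:1], tolerance = 1e-12)
})

test_that("speech-like generator is seeded, novel across seeds, and slow-modulated", {
  fs <- 16000
  a <- synth_speechlike(1.0, fs = fs, seed = 3)
  expect_identical(a, synth_speechlike(1.0, fs = fs, seed = 3))
  for (pair in list(c(1, 2), c(4, 9), c(10, 17), c(21, 22), c(30, 40))) {
    x <- synth_speechlike(1.0, fs = fs, seed = pair[1])
    y <- synth_speechlike(1.0, fs = fs, seed = pair[2])
    cc <- stats::ccf(x, y, lag.max = 400, plot = FALSE)
    expect_lt(max(abs(cc$acf)), 0.5)
  }
  # modulation spectrum of the envelope peaks between 2 and 8 Hz
  env <- abs(a)
  env <- stats::filter(env, rep(1 / 400, 400), sides = 2)
  env <- env[!is.na(env)]
  env <- env - mean(env)
  sp <- Mod(fft(env))[seq_len(length(env) %/% 2)]
  freq <- (seq_along(sp) - 1) * fs / length(env)
  peak_f <- freq[freq > 0.5][which.max(sp[freq > 0.5])]
  expect_gte(peak_f, 2 - 0.5)
  expect_lte(peak_f, 8 + 0.5)
})

test_that("mixtures implement TMR on pre-spatialization RMS and sum exactly", {
  hrtf <- speech_hrtf()
  fs <- hrtf$fs
  spec <- mixture_spec(tmr_db = 0, seed = 5)
  sources <- lapply(1:5, function(i) synth_speechlike(0.5, fs = fs, seed = i))
  mix <- make_mixture(spec, hrtf, sources = sources)
  expect_equal(mix$manifest$azimuth_deg, c(0, -30, 30, -60, 60))
  # tmr = 0: target RMS equals each masker RMS before spatialization
  expect_true(all(abs(mix$manifest$rms - mix$manifest$rms[1]) < 1e-12))
  # additivity: mixture equals the sum of spatialized scaled components
  resum <- Reduce(`+`, Map(function(x, lv, az) {
    spatialize(x / rms_of(x) * lv, az, hrtf)
  }, sources, mix$manifest$rms, mix$manifest$azimuth_deg))
  expect_lt(max(abs(mix$mixture - resum)), 1e-9)
  # +6 dB TMR doubles the target level only
  mix6 <- make_mixture(mixture_spec(tmr_db = 6.0206, seed = 5), hrtf,
                       sources = sources)
  expect_equal(mix6$manifest$rms[1] / mix$manifest$rms[1], 2,
               tolerance = 1e-4)
  expect_equal(mix6$manifest$rms[-1], mix$manifest$rms[-1])
  expect_error(make_mixture(spec, hrtf, sources = sources[1:3]), "source")
  expect_error(mixture_spec(masker_azimuths = numeric(0)), "masker")
  expect_error(mixture_spec(masker_azimuths = c(0, 30)), "differ")
})

test_that("mixture generation is bit-reproducible under a fixed seed", {
  hrtf <- speech_hrtf()
  m1 <- make_mixture(mixture_spec(seed = 77), hrtf, duration = 0.4)
  m2 <- make_mixture(mixture_spec(seed = 77), hrtf, duration = 0.4)
  expect_identical(m1$mixture, m2$mixture)
  expect_identical(m1$target_ref, m2$target_ref)
})

test_that("SOFA round trip recovers horizontal-plane impulse responses", {
  python <- Sys.which("python")
  expect_true(nzchar(python))  # guaranteed by the runtime image
  path <- withr::local_tempfile(fileext = ".sofa")
  n_az <- 5L
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import h5py, numpy as np, sys",
    "az = np.array([0.0, 330.0, 30.0, 270.0, 90.0])",
    "pos = np.stack([az, np.zeros(5), np.full(5, 1.4)], 1)",
    "rng = np.random.default_rng(1)",
    "ir = rng.standard_normal((5, 2, 64))",
    "with h5py.File(sys.argv[1], 'w') as f:",
    "    f['Data.IR'] = ir",
    "    f['SourcePosition'] = pos",
    "    f['Data.SamplingRate'] = np.array([20000.0])",
    "np.savetxt(sys.argv[1] + '.ir0.csv', ir[1, 0, :])"
  ), script)
  status <- system2(python, c(script, path))
  expect_identical(status, 0L)
  hrtf <- load_sofa(path, fs = 20000)
  expect_s3_class(hrtf, "hrtf_set")
  # SOFA azimuth 330 (counterclockwise) is +30 right-positive
  expect_setequal(hrtf$azimuths, c(-90, -30, 0, 30, 90))
  ir0 <- as.numeric(read.csv(paste0(path, ".ir0.csv"), header = FALSE)[[1]])
  expect_equal(hrtf$irs[["30"]]$left, ir0, tolerance = 1e-6)
  expect_error(load_sofa(withr::local_tempfile(lines = "not hdf5")),
               "SOFA")
})
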