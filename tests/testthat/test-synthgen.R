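test_that("gen_colored_noise has the requested spectral slope", {
  # oracle: smoothed-periodogram log-log slope over 1-100 Hz, averaged seeds
  slopes0 <- vapply(1:20, function(s)
    psd_slope(gen_colored_noise(2^17, 600, 0, seed = s), 600), 0)
  slopes2 <- vapply(1:20, function(s)
    psd_slope(gen_colored_noise(2^17, 600, 2, seed = s), 600), 0)
  expect_gt(mean(slopes0), -0.1)
  expect_lt(mean(slopes0), 0.1)
  expect_gt(mean(slopes2), -2.1)
  expect_lt(mean(slopes2), -1.9)
})

test_that("gen_colored_noise is seeded-deterministic, normalised, validated", {
  a <- gen_colored_noise(4096, 600, 1.5, seed = 7)
  b <- gen_colored_noise(4096, 600, 1.5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, gen_colored_noise(4096, 600, 1.5, seed = 8)))
  expect_equal(mean(a), 0, tolerance = 1e-12)
  expect_equal(sd(a), 1, tolerance = 1e-12)
  # odd lengths exercise the other Hermitian branch
  expect_equal(sd(gen_colored_noise(4097, 600, 1, seed = 1)), 1)
  expect_error(gen_colored_noise(1, 600, 1, seed = 1), "n_samples")
  expect_error(gen_colored_noise(100, 600, -1, seed = 1), "beta")
})

test_that("generate_record: empty-room channels are uncorrelated without line", {
  # Monte Carlo over 10 seeds at n = 2^16
  r <- vapply(1:10, function(s) {
    cfg <- generator_config("empty_room", n_channels = 2,
                            duration = 2^16 / 600, fs = 600, line = FALSE,
                            seed = s)
    rec <- generate_record(cfg)
    cor(rec$data[1, ], rec$data[2, ])
  }, 0)
  expect_lt(max(abs(r)), 0.05)
})

test_that("generate_record: full coupling without noise duplicates channels", {
  cfg <- generator_config("human", n_channels = 2, duration = 5, fs = 600,
                          coupling = 1, sensor_noise_sd = 0, seed = 3)
  rec <- generate_record(cfg)
  expect_identical(rec$data[1, ], rec$data[2, ])
})

test_that("generate_record: line noise dominates the empty-room PSD at f0", {
  cfg <- generator_config("empty_room", n_channels = 2, duration = 60,
                          fs = 600,
                          line = line_noise_model(50, 1, amplitudes = 0.3),
                          seed = 5)
  rec <- generate_record(cfg)
  for (ch in 1:2) {
    sp <- stats::spec.pgram(stats::ts(rec$data[ch, ], frequency = 600),
                            plot = FALSE, taper = 0)
    sel <- sp$freq >= 1 & sp$freq <= 150
    peak <- sp$freq[sel][which.max(sp$spec[sel])]
    expect_lt(abs(peak - 50), 0.1)
  }
})

test_that("generate_record is bit-identical under identical config + seed", {
  cfg <- generator_config("human", duration = 3, fs = 600, seed = 42)
  expect_identical(generate_record(cfg)$data, generate_record(cfg)$data)
  cfg2 <- generator_config("empty_room", duration = 3, fs = 600, seed = 42)
  expect_identical(generate_record(cfg2)$data, generate_record(cfg2)$data)
})

test_that("generated background variance is controlled", {
  # uncoupled human channel: configured variance = background (1) + noise^2;
  # empty-room channel: sensor_noise_sd^2. (A coupled channel's sample
  # variance carries the spurious covariance of long-memory series and is
  # not variance-controlled sample-by-sample; see the methods vignette.)
  v_hum <- vapply(1:10, function(s) {
    cfg <- generator_config("human", n_channels = 1, duration = 2^16 / 600,
                            fs = 600, coupling = 0, sensor_noise_sd = 0.2,
                            seed = s)
    var(generate_record(cfg)$data[1, ])
  }, 0)
  expect_lt(abs(mean(v_hum) - 1.04) / 1.04, 0.05)
  v_emp <- vapply(1:10, function(s) {
    cfg <- generator_config("empty_room", n_channels = 1,
                            duration = 2^16 / 600, fs = 600, line = FALSE,
                            seed = s)
    var(generate_record(cfg)$data[1, ])
  }, 0)
  expect_lt(abs(mean(v_emp) - 1) / 1, 0.05)
})

test_that("zero-lag cross-correlation is monotone in coupling", {
  couplings <- c(0, 0.25, 0.5, 0.75, 1)
  r <- vapply(couplings, function(cp) {
    cfg <- generator_config("human", n_channels = 2, duration = 60, fs = 600,
                            coupling = cp, seed = 9)
    rec <- generate_record(cfg)
    cor(rec$data[1, ], rec$data[2, ])
  }, 0)
  expect_true(all(diff(r) >= 0))
})

test_that("add_line_noise matches its definition and leaves input unchanged", {
  n <- 1200; fs <- 600
  zero <- ts_record(matrix(0, 1, n), fs)
  # zero amplitudes: exact identity
  lm0 <- line_noise_model(50, 2, amplitudes = 0, phase_drift_std = 0)
  expect_identical(add_line_noise(zero, lm0, seed = 1)$data, zero$data)
  # pure cosine with the drawn initial phase, drift = 0
  lm1 <- line_noise_model(50, 1, amplitudes = 1, phase_drift_std = 0)
  out <- add_line_noise(zero, lm1, seed = 4)
  phi0 <- plscan:::with_seed(plscan:::derive_seed(4, 1), runif(1, 0, 2 * pi))
  tt <- (0:(n - 1)) / fs
  expect_equal(out$data[1, ], cos(2 * pi * 50 * tt + phi0), tolerance = 1e-12)
  # shared waveform: identical across channels even with drift
  zero2 <- ts_record(matrix(0, 2, n), fs)
  lm2 <- line_noise_model(50, 2, amplitudes = c(1, 0.5),
                          phase_drift_std = 1e-3, shared = TRUE)
  out2 <- add_line_noise(zero2, lm2, seed = 2)
  expect_identical(out2$data[1, ], out2$data[2, ])
  # aliasing guard
  lm_bad <- line_noise_model(50, 6, amplitudes = 1)
  expect_error(add_line_noise(zero, lm_bad, seed = 1), "Nyquist")
  expect_error(generator_config("empty_room", fs = 200, duration = 2,
                                line = line_noise_model(50, 3)), "liasing")
})

test_that("record CSV round trip preserves data, fs and labels", {
  cfg <- generator_config("empty_room", n_channels = 3, duration = 1,
                          fs = 250, line = FALSE, seed = 1)
  rec <- generate_record(cfg)
  path <- tempfile(fileext = ".csv")
  write_record_csv(rec, path)
  back <- read_record_csv(path)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$labels, rec$labels)
  unlink(c(path, paste0(path, ".json")))
})

test_that("ts_record validates its invariants", {
  expect_error(ts_record(matrix(c(1, NA), 1, 2), 100), "non-finite")
  expect_error(ts_record(matrix(1, 1, 1), 100), "n_samples")
  expect_error(ts_record(matrix(1, 2, 10), 0), "fs")
  expect_error(ts_record(matrix(1, 2, 10), 100, labels = c("a", "a")), "unique")
})
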