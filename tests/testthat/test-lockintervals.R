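test_that("phase_difference wraps into (-pi, pi]", {
  expect_equal(phase_difference(0.1, 0.2), -0.1)
  expect_equal(phase_difference(3.0, -3.0), 6.0 - 2 * pi)
  x <- runif(100, -pi, pi)
  expect_equal(phase_difference(x, x), rep(0, 100))
  expect_error(phase_difference(1:3 / 10, 1:4 / 10), "length")
  # wrapping convention: pi maps to pi, -pi maps to pi
  expect_identical(wrap_phase(pi), pi)
  expect_identical(wrap_phase(-pi), pi)
})

test_that("smooth_circular equals the brute-force phasor mean", {
  # constant and identity cases
  expect_equal(smooth_circular(rep(0.7, 50), 5), rep(0.7, 50))
  x <- runif(64, -pi, pi)
  expect_equal(smooth_circular(x, 1), x)
  expect_error(smooth_circular(x, 4), "odd")
  # alternating +pi/2 / -pi/2 and random input vs direct computation
  alt <- rep(c(pi / 2, -pi / 2), length.out = 101)
  for (input in list(alt, x)) {
    for (w in c(3L, 7L)) {
      got <- smooth_circular(input, w)
      h <- (w - 1L) %/% 2L
      want <- vapply(seq_along(input), function(t) {
        idx <- max(1, t - h):min(length(input), t + h)
        Arg(mean(exp(1i * input[idx])))
      }, 0)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # alternating +-pi/2 under window 3: each window holds two phasors of the
  # neighbours' sign and one of the centre's, so the +-pi/2 pattern survives
  # mirrored: Arg((2 e^{+i pi/2} + e^{-i pi/2})/3) = +pi/2 exactly
  sm <- smooth_circular(alt, 3)
  inner <- 2:100
  expect_equal(sm[inner], -alt[inner], tolerance = 1e-12)
})

test_that("extract_intervals handles the canonical examples", {
  fs <- 600
  # all-zero dphi: one censored full-length interval
  iv <- extract_intervals(rep(0, 600), fs = fs)
  expect_equal(iv$durations, 1.0)
  expect_true(iv$censored)
  # alternating 0, pi: interior runs of one sample
  alt <- rep(c(0, pi), length.out = 200)
  iv2 <- extract_intervals(alt, fs = fs)
  expect_true(all(iv2$durations == 1 / fs))
  expect_equal(length(iv2$durations), 100)
  # all-invalid input: empty set, not an error
  iv3 <- extract_intervals(rep(0, 100), valid = rep(FALSE, 100), fs = fs)
  expect_length(iv3$durations, 0)
  expect_equal(iv3$n_samples_valid, 0L)
})

test_that("extract_intervals matches the brute-force oracle on random input", {
  fs <- 250
  crit <- lock_criterion(smoothing_window = 0L)
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(20:500, 1)
    dphi <- runif(n, -pi, pi)
    valid <- runif(n) > 0.15
    got <- extract_intervals(dphi, valid, fs, crit)
    want <- oracle_intervals(dphi, valid, fs)
    expect_identical(got$durations, want$durations)
    expect_identical(got$censored, want$censored)
  }
})

test_that("locked-sample conservation and threshold monotonicity hold", {
  fs <- 100
  set.seed(7)
  dphi <- smooth_circular(runif(5000, -pi, pi), 9)
  valid <- runif(5000) > 0.05
  crit <- lock_criterion(smoothing_window = 0L)
  iv <- extract_intervals(dphi, valid, fs, crit)
  locked <- abs(dphi) < crit$threshold & valid
  expect_equal(sum(iv$durations) * fs, sum(locked))
  # larger threshold never decreases total locked time
  totals <- vapply(c(0.2, 0.5, 1, 2, 3), function(th) {
    sum(extract_intervals(dphi, valid, fs,
                          lock_criterion(threshold = th,
                                         smoothing_window = 0L))$durations)
  }, 0)
  expect_true(all(diff(totals) >= 0))
})

test_that("min_duration and include_censored filter as documented", {
  fs <- 10
  dphi <- c(0, 0, pi, 0, pi, 0, 0, 0, pi, 0)
  # runs: [1,2] censored-left, [4] interior, [6,7,8] interior, [10] censored-right
  iv <- extract_intervals(dphi, fs = fs)
  expect_equal(iv$durations * fs, c(2, 1, 3, 1))
  expect_equal(iv$censored, c(TRUE, FALSE, FALSE, TRUE))
  iv_min <- extract_intervals(dphi, fs = fs,
                              crit = lock_criterion(smoothing_window = 0L,
                                                    min_duration = 2L))
  expect_equal(iv_min$durations * fs, c(2, 3))
  iv_nc <- extract_intervals(dphi, fs = fs,
                             crit = lock_criterion(smoothing_window = 0L,
                                                   include_censored = FALSE))
  expect_equal(iv_nc$durations * fs, c(1, 3))  # boundary runs dropped
  # validity boundaries censor too
  valid <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  iv_v <- extract_intervals(rep(0, 10), valid, fs)
  expect_equal(iv_v$durations * fs, c(4, 5))
  expect_equal(iv_v$censored, c(TRUE, TRUE))
})

test_that("two identical channels lock for the whole valid span in every band", {
  cfg <- generator_config("human", n_channels = 2, duration = 30, fs = 600,
                          coupling = 1, sensor_noise_sd = 0, seed = 5)
  rec <- generate_record(cfg)
  stack <- wavelet_phase(rec)
  sets <- phase_lock_intervals(stack, lock_criterion())
  for (s in sets) {
    expect_length(s$durations, 1)
    expect_true(s$censored)
    expect_equal(s$durations * rec$fs, s$n_samples_valid)
  }
})

test_that("pool_intervals concatenates and validates grouping", {
  b <- band_spec("a", 1, 2)
  s1 <- interval_set(c(1, 2, 3), c(FALSE, FALSE, TRUE), band = b,
                     n_samples_valid = 100L)
  s2 <- interval_set(c(4, 5, 6, 7), rep(FALSE, 4), band = b,
                     n_samples_valid = 200L)
  expect_identical(pool_intervals(list(s1))$durations, s1$durations)
  pooled <- pool_intervals(list(s1, s2))
  expect_length(pooled$durations, 7)
  expect_equal(pooled$n_samples_valid, 300L)
  # pooled mean equals the weighted mean of the inputs
  expect_equal(mean(pooled$durations),
               (3 * mean(s1$durations) + 4 * mean(s2$durations)) / 7)
  s3 <- interval_set(1, FALSE, band = band_spec("b", 2, 4))
  expect_error(pool_intervals(list(s1, s3)), "mixed bands")
})

test_that("log-binned distribution normalises and recovers a known slope", {
  # degenerate: all durations equal -> one occupied bin, density integrates to 1
  d0 <- log_binned_distribution(interval_set(rep(0.5, 20), rep(FALSE, 20)))
  expect_equal(sum(d0$density > 0), 1)
  expect_equal(sum(d0$density * diff(d0$edges)), 1, tolerance = 1e-9)
  # any input integrates to 1
  set.seed(1)
  x <- interval_set(rexp(500) + 0.01, rep(FALSE, 500))
  d1 <- log_binned_distribution(x)
  expect_equal(sum(d1$density * diff(d1$edges)), 1, tolerance = 1e-9)
  # 10^4 samples from a known power law: log-log slope within 0.15 of -alpha
  set.seed(2)
  pl <- r_power_law(1e4, alpha = 2.0, xmin = 0.01)
  d2 <- log_binned_distribution(interval_set(pl, rep(FALSE, 1e4)),
                                bins_per_decade = 10)
  centre <- sqrt(d2$edges[-1] * d2$edges[-length(d2$edges)])
  use <- d2$counts >= 10
  fit <- stats::lm(log(d2$density[use]) ~ log(centre[use]))
  expect_lt(abs(stats::coef(fit)[[2]] - (-2.0)), 0.15)
  # empty input: flagged, not an error
  expect_true(log_binned_distribution(interval_set(numeric(0), logical(0)))$empty)
  # mean-normalised durations attached
  expect_equal(mean(d1$normalized), 1, tolerance = 1e-12)
})
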