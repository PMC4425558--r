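# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the interval oracle is a sample-by-sample linear
# scan, the samplers are inverse-CDF draws, and PSD slopes come from
# stats::spec.pgram.

# brute-force phase-lock interval extraction: linear scan over samples
oracle_intervals <- function(dphi, valid, fs, threshold = pi / 4,
                             min_duration = 1L, include_censored = TRUE) {
  n <- length(dphi)
  locked <- (abs(dphi) < threshold) & valid
  durations <- numeric(0)
  censored <- logical(0)
  run_start <- NA_integer_
  for (t in seq_len(n + 1L)) {
    inside <- t <= n && locked[t]
    if (inside && is.na(run_start)) run_start <- t
    if (!inside && !is.na(run_start)) {
      run_end <- t - 1L
      cens <- (run_start == 1L) || (run_end == n) ||
        (!valid[run_start - 1L]) || (!valid[run_end + 1L])
      len <- run_end - run_start + 1L
      if (len >= min_duration && (include_censored || !cens)) {
        durations <- c(durations, len / fs)
        censored <- c(censored, cens)
      }
      run_start <- NA_integer_
    }
  }
  list(durations = durations, censored = censored)
}

# inverse-CDF sampler for the continuous power law p(x) ~ x^-alpha, x >= xmin
r_power_law <- function(n, alpha, xmin) {
  u <- runif(n)
  xmin * (1 - u)^(-1 / (alpha - 1))
}

# shifted exponential: x = xmin + Exp(rate)
r_shifted_exp <- function(n, rate, xmin) {
  xmin + stats::rexp(n, rate)
}

# least-squares log-log PSD slope over [f_lo, f_hi], smoothed periodogram
psd_slope <- function(x, fs, f_lo = 1, f_hi = 100) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 31,
                          plot = FALSE, detrend = TRUE, taper = 0.1)
  sel <- sp$freq >= f_lo & sp$freq <= f_hi
  stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[[2]]
}

# circular (Fisher-Lee) correlation between two phase sequences
circ_corr <- function(a, b) {
  ma <- atan2(mean(sin(a)), mean(cos(a)))
  mb <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - ma); sb <- sin(b - mb)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

# a pure-tone record fixture
tone_record <- function(freq, fs = 600, dur = 20, amp = 1, n_channels = 1,
                        phase = 0) {
  tt <- (seq_len(round(dur * fs)) - 1) / fs
  x <- amp * cos(2 * pi * freq * tt + phase)
  ts_record(matrix(rep(x, n_channels), nrow = n_channels, byrow = TRUE),
            fs = fs)
}

middle <- function(n, frac = 0.8) {
  drop <- floor(n * (1 - frac) / 2)
  (drop + 1L):(n - drop)
}
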