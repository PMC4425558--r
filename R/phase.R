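#' Per-band instantaneous phase stack
#'
#' Container produced by the two phase backends: arrays of wrapped
#' instantaneous phase (radians, in `(-pi, pi]`) and non-negative
#' instantaneous amplitude, of shape `n_bands x n_channels x n_samples`,
#' plus a per-band edge-validity mask. Samples within three centre periods
#' of either record end are flagged unreliable (filter/wavelet edge
#' effects) and are excluded from interval extraction, as are samples whose
#' amplitude is numerically degenerate (below `1e-12` of the channel's
#' band-amplitude RMS).
#'
#' @name phase_stack
#' @keywords internal
NULL

new_phase_stack <- function(phases, amplitudes, ladder, method, fs) {
  structure(
    list(phases = phases, amplitudes = amplitudes, ladder = ladder,
         method = method, fs = fs,
         edge_valid = edge_valid_mask(ladder, dim(phases)[3], fs)),
    class = "phase_stack"
  )
}

#' @export
print.phase_stack <- function(x, ...) {
  d <- dim(x$phases)
  cat(sprintf("<phase_stack> method=%s: %d band(s) x %d channel(s) x %d samples @ %g Hz\n",
              x$method, d[1], d[2], d[3], x$fs))
  invisible(x)
}

band_center <- function(band) sqrt(band$f_lo * band$f_hi)

# TRUE where a sample is outside the edge-discard zone (3 centre periods)
edge_valid_mask <- function(ladder, n, fs) {
  m <- matrix(TRUE, nrow = length(ladder), ncol = n)
  for (b in seq_along(ladder)) {
    discard <- min(ceiling(3 * fs / band_center(ladder[[b]])), floor(n / 2))
    if (discard > 0) {
      m[b, seq_len(discard)] <- FALSE
      m[b, (n - discard + 1L):n] <- FALSE
    }
  }
  m
}

# analytic signal via FFT: negative frequencies zeroed, positive doubled
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Band-pass + Hilbert (analytic signal) phase backend
#'
#' The "simplified" estimator: each band of the ladder is isolated by a
#' zero-phase Butterworth band-pass ([bandpass_filter()]) and the analytic
#' signal is formed by zeroing negative frequencies in the Fourier domain.
#' Phase is the argument of the analytic signal, amplitude its modulus.
#'
#' @param record a [ts_record].
#' @param ladder a `band_ladder` (default [default_ladder()] clipped to the
#'   record's Nyquist frequency).
#' @return a [phase_stack] with `method = "hilbert"`.
#' @export
hilbert_phase <- function(record, ladder = default_ladder(record$fs)) {
  stopifnot(inherits(record, "ts_record"), inherits(ladder, "band_ladder"))
  nb <- length(ladder); nc <- n_channels(record); n <- n_samples(record)
  phases <- array(0, dim = c(nb, nc, n))
  amps <- array(0, dim = c(nb, nc, n))
  for (b in seq_len(nb)) {
    filtered <- bandpass_filter(record, ladder[[b]])
    for (ch in seq_len(nc)) {
      z <- analytic_signal(filtered$data[ch, ])
      phases[b, ch, ] <- Arg(z)
      amps[b, ch, ] <- Mod(z)
    }
  }
  new_phase_stack(phases, amps, ladder, "hilbert", record$fs)
}

#' Analytic continuous-wavelet phase backend
#'
#' The original-style estimator: for each band, the record is convolved (in
#' the Fourier domain) with an analytic Morlet-type wavelet at the band's
#' centre scale -- a Gaussian frequency window centred on the geometric mean
#' of the band edges, with half-power width matched to the band width, and
#' zero response at negative frequencies. The complex coefficient sequence
#' supplies phase (argument) and amplitude (modulus). One scale per octave
#' band keeps the stack rectangular.
#'
#' @inheritParams hilbert_phase
#' @param cycles wavelet width as the Morlet cycle count: the Gaussian
#'   frequency window has `sigma_f = fc / cycles`. The default 6 is the
#'   standard analytic Morlet and keeps adjacent octave bands well
#'   separated; `cycles = NULL` instead matches the half-power width to the
#'   band's octave width (`sigma_f = (f_hi - f_lo) / (2 sqrt(log 2))`, about
#'   2.35 cycles), which is broader and leaks appreciably into neighbouring
#'   bands.
#' @return a [phase_stack] with `method = "wavelet"`.
#' @export
wavelet_phase <- function(record, ladder = default_ladder(record$fs),
                          cycles = 6) {
  stopifnot(inherits(record, "ts_record"), inherits(ladder, "band_ladder"))
  fs <- record$fs; n <- n_samples(record)
  for (band in ladder) {
    if (3 * fs / band_center(band) > n / 2)
      stop_arg("band %s: centre scale too long for a %d-sample record",
               band$name, n)
  }
  nb <- length(ladder); nc <- n_channels(record)
  phases <- array(0, dim = c(nb, nc, n))
  amps <- array(0, dim = c(nb, nc, n))
  f <- c(0, seq_len(n - 1)) * fs / n
  for (b in seq_len(nb)) {
    band <- ladder[[b]]
    fc <- band_center(band)
    sigma_f <- if (is.null(cycles)) {
      (band$f_hi - band$f_lo) / (2 * sqrt(log(2)))
    } else {
      fc / cycles
    }
    w <- numeric(n)
    pos <- f > 0 & f <= fs / 2       # analytic: positive frequencies only
    w[pos] <- 2 * exp(-(f[pos] - fc)^2 / (2 * sigma_f^2))
    for (ch in seq_len(nc)) {
      z <- fft(fft(record$data[ch, ]) * w, inverse = TRUE) / n
      phases[b, ch, ] <- Arg(z)
      amps[b, ch, ] <- Mod(z)
    }
  }
  new_phase_stack(phases, amps, ladder, "wavelet", record$fs)
}

#' Dispatch on phase-extraction backend
#'
#' @inheritParams hilbert_phase
#' @param method `"wavelet"` or `"hilbert"`.
#' @param ... passed on to the backend (e.g. `cycles` for
#'   [wavelet_phase()]).
#' @return a [phase_stack].
#' @export
extract_phase <- function(record, method = c("wavelet", "hilbert"),
                          ladder = default_ladder(record$fs), ...) {
  method <- match.arg(method)
  switch(method,
         wavelet = wavelet_phase(record, ladder, ...),
         hilbert = hilbert_phase(record, ladder))
}

# per-(band, channel) degeneracy threshold: 1e-12 x RMS amplitude
amplitude_floor <- function(stack, b, ch) {
  1e-12 * sqrt(mean(stack$amplitudes[b, ch, ]^2))
}

# validity mask for one channel in one band: edge zone and degenerate
# amplitudes removed
valid_mask <- function(stack, b, ch) {
  stack$edge_valid[b, ] & (stack$amplitudes[b, ch, ] > amplitude_floor(stack, b, ch))
}
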