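#' Notch (band-stop) filter specification
#'
#' A cascade of narrow second-order IIR notches at `k * f0`,
#' `k = 1..n_harmonics`, applied forward-backward (zero phase). The default
#' `n_harmonics = NULL` notches every harmonic below `0.9 * fs/2` at
#' application time.
#'
#' @param f0 fundamental frequency to remove (Hz).
#' @param n_harmonics number of harmonics to notch, or `NULL` for all below
#'   `0.9 * Nyquist`.
#' @param quality dimensionless Q factor of each notch (centre frequency /
#'   -3 dB bandwidth); default 30 (1.7 Hz wide at 50 Hz).
#' @return an object of class `notch_spec`.
#' @export
notch_spec <- function(f0, n_harmonics = NULL, quality = 30) {
  if (!is.numeric(f0) || f0 <= 0) stop_arg("`f0` must be positive (Hz)")
  if (!is.null(n_harmonics) && (!is_count(n_harmonics) || n_harmonics < 1))
    stop_arg("`n_harmonics` must be a positive integer or NULL")
  if (!is.numeric(quality) || quality <= 0) stop_arg("`quality` must be > 0")
  structure(list(f0 = f0,
                 n_harmonics = if (!is.null(n_harmonics)) as.integer(n_harmonics),
                 quality = quality),
            class = "notch_spec")
}

#' Frequency-band specification
#'
#' @param name band label (e.g. `"alpha"` or `"8-17.5Hz"`).
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(name, f_lo, f_hi) {
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_hi <= f_lo)
    stop_arg("need 0 < f_lo < f_hi, got [%g, %g]", f_lo, f_hi)
  structure(list(name = as.character(name), f_lo = f_lo, f_hi = f_hi),
            class = "band_spec")
}

#' The default octave band ladder
#'
#' Dyadic bands from the delta band up through a high-frequency control band:
#' 1-2, 2-4, 4-8, 8-17.5, 17.5-35, 35-70, 70-140 Hz, clipped to the Nyquist
#' frequency (bands entirely above `0.95 * fs/2` are dropped; a partially
#' clipped band keeps its name).
#'
#' @param fs sampling rate in Hz used for Nyquist clipping; `Inf` keeps all
#'   bands unclipped.
#' @return a `band_ladder`: list of [band_spec]s ordered by `f_lo`.
#' @export
default_ladder <- function(fs = Inf) {
  edges <- list(c(1, 2), c(2, 4), c(4, 8), c(8, 17.5), c(17.5, 35),
                c(35, 70), c(70, 140))
  bands <- list()
  for (e in edges) {
    f_lo <- e[1]; f_hi <- e[2]
    if (f_lo >= 0.95 * fs / 2) next
    f_hi <- min(f_hi, 0.95 * fs / 2)
    bands[[length(bands) + 1L]] <-
      band_spec(sprintf("%g-%gHz", e[1], e[2]), f_lo, f_hi)
  }
  band_ladder(bands)
}

#' @rdname default_ladder
#' @param bands list of [band_spec]s.
#' @export
band_ladder <- function(bands) {
  if (!length(bands)) stop_arg("ladder must contain at least one band")
  lo <- vapply(bands, `[[`, 0, "f_lo")
  if (is.unsorted(lo, strictly = TRUE))
    stop_arg("bands must be strictly ordered by f_lo")
  structure(bands, class = "band_ladder")
}

# ---- IIR design ------------------------------------------------------------

# RBJ cookbook second-order notch at f0 with quality Q, as one SOS row
design_notch_sos <- function(f0, fs, quality) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * quality)
  c2 <- -2 * cos(w0)
  a0 <- 1 + alpha
  matrix(c(1 / a0, c2 / a0, 1 / a0, 1, c2 / a0, (1 - alpha) / a0), nrow = 1)
}

# Butterworth band-pass as second-order sections: analog low-pass prototype,
# LP->BP transform with pre-warped edges, bilinear transform, conjugate-pair
# pooling. `order` is the prototype order (must be even); the band-pass has
# 2*order poles and `order` sections.
design_butter_bandpass_sos <- function(f_lo, f_hi, fs, order = 4L) {
  if (order %% 2L != 0L) stop_arg("`order` must be even")
  if (f_lo <= 0 || f_hi <= f_lo || f_hi >= fs / 2)
    stop_arg("band [%g, %g] Hz invalid for fs = %g Hz", f_lo, f_hi, fs)
  n <- as.integer(order)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # LHP prototype poles
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * f_lo / fs)
  w2 <- fs2 * tan(pi * f_hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  ps <- p * bw / 2
  pbp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  # bilinear transform; n zeros at s=0 -> z=+1, n at s=Inf -> z=-1
  pd <- (fs2 + pbp) / (fs2 - pbp)
  # gain after bilinear: k_bp * prod(fs2 - z_s) / prod(fs2 - p_s), zeros at s=0
  gain <- (bw * fs2)^n * Re(1 / prod(fs2 - pbp))
  up <- pd[Im(pd) > 0]
  if (length(up) != n) {
    # numerically real poles possible for narrow bands: pair by conjugates
    ord <- order(Re(pd), Im(pd))
    up <- pd[ord][seq(1, 2 * n, by = 2)]
  }
  sos <- matrix(0, nrow = n, ncol = 6)
  g <- abs(gain)^(1 / n)
  sgn <- sign(gain)
  for (s in seq_len(n)) {
    pp <- up[s]
    gs <- if (s == 1L) g * sgn else g
    sos[s, ] <- c(gs * c(1, 0, -1), 1, -2 * Re(pp), Mod(pp)^2)
  }
  sos
}

# complex frequency response of an SOS cascade at frequencies f (Hz)
sos_freq_response <- function(sos, f, fs) {
  z <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    h <- h * num / den
  }
  h
}

# forward-backward SOS filtering with odd-reflection padding of `padlen`
# samples at each end (settling length); zero initial conditions.
sos_filtfilt <- function(x, sos, padlen) {
  n <- length(x)
  padlen <- max(1L, min(as.integer(padlen), n - 1L))
  ext <- c(2 * x[1] - x[(padlen + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- sosfilt_cpp(sos, ext)
  y <- rev(sosfilt_cpp(sos, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

# ---- user-facing filters ---------------------------------------------------

#' Remove line noise with zero-phase notch filtering
#'
#' Each channel is filtered forward-backward through a cascade of
#' second-order IIR notches at `k * f0` for every requested harmonic, giving
#' zero phase distortion and (squared) stop-band attenuation at the line
#' frequencies. Reflect-padding of one settling length suppresses edge
#' transients.
#'
#' @param record a [ts_record].
#' @param spec a [notch_spec]. Every notch centre must lie strictly below
#'   the Nyquist frequency; a centre at or above Nyquist is an error, not a
#'   silent skip.
#' @return the filtered [ts_record]; `meta$preprocessing` gains an entry.
#' @export
notch_filter <- function(record, spec) {
  stopifnot(inherits(record, "ts_record"), inherits(spec, "notch_spec"))
  fs <- record$fs
  nh <- spec$n_harmonics
  if (is.null(nh)) nh <- max(1L, floor(0.9 * (fs / 2) / spec$f0))
  centers <- spec$f0 * seq_len(nh)
  if (any(centers >= fs / 2))
    stop_arg("notch centre %g Hz is at/above Nyquist (%g Hz)",
             centers[which(centers >= fs / 2)[1]], fs / 2)
  sos <- do.call(rbind, lapply(centers, design_notch_sos, fs = fs,
                               quality = spec$quality))
  padlen <- ceiling(3 * fs * spec$quality / spec$f0)
  out <- record$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- sos_filtfilt(out[ch, ], sos, padlen)
  }
  rec <- ts_record(out, fs, record$labels, record$meta)
  record_note(rec, "notch_filter",
              list(f0 = spec$f0, harmonics = nh, quality = spec$quality))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth band-pass (effective order 8 after forward-backward
#' application), with half-power points at the band edges per pass.
#' Reflect-padding of one settling length (`3 * fs / f_lo` samples)
#' suppresses edge transients.
#'
#' @param record a [ts_record].
#' @param band a [band_spec]; `f_hi` must lie below Nyquist.
#' @param order prototype filter order (even; default 4).
#' @return the filtered [ts_record].
#' @export
bandpass_filter <- function(record, band, order = 4L) {
  stopifnot(inherits(record, "ts_record"), inherits(band, "band_spec"))
  fs <- record$fs
  if (band$f_hi >= fs / 2)
    stop_arg("band [%g, %g] Hz exceeds Nyquist (%g Hz)",
             band$f_lo, band$f_hi, fs / 2)
  sos <- design_butter_bandpass_sos(band$f_lo, band$f_hi, fs, order)
  padlen <- ceiling(3 * fs / band$f_lo)
  out <- record$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- sos_filtfilt(out[ch, ], sos, padlen)
  }
  rec <- ts_record(out, fs, record$labels, record$meta)
  record_note(rec, "bandpass_filter",
              list(band = band$name, f_lo = band$f_lo, f_hi = band$f_hi,
                   order = order))
}
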