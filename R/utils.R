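#' Wrap phase angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 6))
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All package-internal randomness goes through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed derivation: reproducible independent of how
# many channels/harmonics are drawn before a given one. Kept < 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 104729 + 1) %% 2147483629
  }
  as.integer(s)
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x)

# inverse FFT returning a real signal from a full complex spectrum
ifft_real <- function(spec) Re(fft(spec, inverse = TRUE)) / length(spec)
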