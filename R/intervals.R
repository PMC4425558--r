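#' Wrapped pairwise phase difference
#'
#' @param phi_a,phi_b numeric phase sequences of equal length (radians).
#' @return `wrap_phase(phi_a - phi_b)`, in `(-pi, pi]`.
#' @examples
#' phase_difference(3.0, -3.0)  # wraps to ~ -0.283
#' @export
phase_difference <- function(phi_a, phi_b) {
  if (length(phi_a) != length(phi_b))
    stop_arg("phase sequences differ in length (%d vs %d)",
             length(phi_a), length(phi_b))
  wrap_phase(phi_a - phi_b)
}

#' Sliding-window circular smoothing of a phase-difference sequence
#'
#' Each sample is replaced by the argument of the centred moving mean of the
#' unit phasors `exp(1i * dphi)` -- the time-resolved quasi-instantaneous
#' coherence direction. At the sequence ends the window is truncated to the
#' available samples.
#'
#' @param dphi numeric phase sequence (radians).
#' @param window odd window length in samples; `1` is the identity.
#' @return smoothed sequence, wrapped to `(-pi, pi]`.
#' @export
smooth_circular <- function(dphi, window) {
  if (!is_count(window) || window < 1) stop_arg("`window` must be >= 1")
  if (window %% 2 == 0) stop_arg("`window` must be odd, got %d", window)
  if (window == 1) return(wrap_phase(dphi))
  n <- length(dphi)
  h <- (window - 1L) / 2L
  cre <- cumsum(c(0, cos(dphi)))
  cim <- cumsum(c(0, sin(dphi)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  atan2(cim[hi + 1L] - cim[lo], cre[hi + 1L] - cre[lo])
}

#' Phase-lock extraction criterion
#'
#' @param threshold lock threshold in radians, `0 < threshold < pi`
#'   (default `pi/4`): samples with `|dphi| < threshold` count as locked.
#' @param smoothing_window sliding-window length (odd sample count) for
#'   [smooth_circular()] applied to the phase difference before
#'   thresholding; `0` disables smoothing; `"auto"` selects the backend
#'   convention (off for the wavelet backend, one centre period rounded to
#'   odd for the hilbert backend).
#' @param min_duration minimum interval length in samples (>= 1); shorter
#'   runs are dropped.
#' @param include_censored keep intervals that touch a record/validity
#'   boundary? Default `TRUE`: the longest intervals under study are exactly
#'   the ones most likely to be boundary-truncated.
#' @return an object of class `lock_criterion`.
#' @export
lock_criterion <- function(threshold = pi / 4, smoothing_window = "auto",
                           min_duration = 1L, include_censored = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= pi)
    stop_arg("`threshold` must lie in (0, pi)")
  if (!identical(smoothing_window, "auto")) {
    if (!is_count(smoothing_window) || smoothing_window < 0)
      stop_arg("`smoothing_window` must be \"auto\" or an integer >= 0")
    if (smoothing_window > 1 && smoothing_window %% 2 == 0)
      stop_arg("`smoothing_window` must be odd")
    smoothing_window <- as.integer(smoothing_window)
  }
  if (!is_count(min_duration) || min_duration < 1)
    stop_arg("`min_duration` must be >= 1 sample")
  structure(
    list(threshold = threshold, smoothing_window = smoothing_window,
         min_duration = as.integer(min_duration),
         include_censored = isTRUE(include_censored)),
    class = "lock_criterion"
  )
}

# resolve "auto" smoothing for a given backend and band centre frequency
resolve_smoothing <- function(crit, method, fc, fs) {
  if (!identical(crit$smoothing_window, "auto")) return(crit$smoothing_window)
  if (method == "wavelet") return(0L)
  w <- max(1L, round(fs / fc))
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(w)
}

#' Set of phase-lock interval durations
#'
#' @param durations positive durations in seconds.
#' @param censored logical vector parallel to `durations`: interval touched
#'   a record or validity boundary (true duration only bounded below).
#' @param pair length-2 character vector of channel labels (or `NA`).
#' @param band a [band_spec] or `NULL`.
#' @param n_samples_valid number of valid samples scanned.
#' @return an object of class `interval_set`.
#' @export
interval_set <- function(durations, censored, pair = c(NA, NA), band = NULL,
                         n_samples_valid = NA_integer_) {
  stopifnot(length(durations) == length(censored))
  structure(
    list(durations = as.numeric(durations), censored = as.logical(censored),
         pair = pair, band = band,
         n_samples_valid = as.integer(n_samples_valid)),
    class = "interval_set"
  )
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d interval(s)%s%s; %d censored; mean %.4g s\n",
              length(x$durations),
              if (!is.null(x$band)) paste0(", band ", x$band$name) else "",
              if (!all(is.na(x$pair))) paste0(", pair ", paste(x$pair, collapse = "~")) else "",
              sum(x$censored),
              if (length(x$durations)) mean(x$durations) else NA))
  invisible(x)
}

#' Extract phase-lock intervals from a phase-difference sequence
#'
#' A sample is locked when `|dphi| < threshold` (after optional circular
#' smoothing) and valid. Intervals are maximal runs of locked samples;
#' duration = run length / `fs`. A run is censored when it abuts the start
#' or end of the record or an invalid sample -- its true duration is only
#' bounded below. Runs shorter than `min_duration` samples are dropped;
#' censored runs are kept iff `crit$include_censored`.
#'
#' @param dphi numeric phase-difference sequence (radians).
#' @param valid logical vector of the same length; `FALSE` samples can never
#'   be locked. All-invalid input yields an empty interval set, not an
#'   error.
#' @param fs sampling rate (Hz).
#' @param crit a [lock_criterion]; `smoothing_window = "auto"` is not
#'   resolvable here and means no smoothing unless a number is given.
#' @return an [interval_set].
#' @export
extract_intervals <- function(dphi, valid = NULL, fs,
                              crit = lock_criterion(smoothing_window = 0L)) {
  n <- length(dphi)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n)
    stop_arg("`dphi` and `valid` differ in length (%d vs %d)", n, length(valid))
  stopifnot(inherits(crit, "lock_criterion"))
  w <- if (identical(crit$smoothing_window, "auto")) 0L else crit$smoothing_window
  if (w > 1L) dphi <- smooth_circular(dphi, w)
  locked <- (abs(dphi) < crit$threshold) & valid
  if (!any(locked)) {
    return(interval_set(numeric(0), logical(0),
                        n_samples_valid = sum(valid)))
  }
  r <- rle(as.vector(locked))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]; lens <- r$lengths[keep]
  censored <- (starts == 1L) | (ends == n) |
    !valid[pmax(starts - 1L, 1L)] | !valid[pmin(ends + 1L, n)]
  sel <- lens >= crit$min_duration
  if (!crit$include_censored) sel <- sel & !censored
  interval_set(lens[sel] / fs, censored[sel],
               n_samples_valid = sum(valid))
}

#' Pool interval sets
#'
#' Concatenates durations and censoring flags across sets, typically over
#' all channel pairs within one band. Under `by = "band"` all sets must
#' share the same band (mixed bands are an error); under `by = "pair"` the
#' same channel pair.
#'
#' @param sets list of [interval_set]s.
#' @param by grouping key the sets are required to share: `"band"`,
#'   `"pair"`, or `"none"`.
#' @return one pooled [interval_set].
#' @export
pool_intervals <- function(sets, by = c("band", "pair", "none")) {
  by <- match.arg(by)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "interval_set")))
  if (by == "band") {
    keys <- vapply(sets, function(s) if (is.null(s$band)) NA_character_ else s$band$name, "")
    if (length(unique(keys)) > 1L)
      stop_arg("cannot pool mixed bands: %s", paste(unique(keys), collapse = ", "))
  }
  if (by == "pair") {
    keys <- vapply(sets, function(s) paste(s$pair, collapse = "~"), "")
    if (length(unique(keys)) > 1L)
      stop_arg("cannot pool mixed pairs: %s", paste(unique(keys), collapse = ", "))
  }
  nv <- vapply(sets, `[[`, 0L, "n_samples_valid")
  interval_set(
    durations = unlist(lapply(sets, `[[`, "durations"), use.names = FALSE),
    censored = unlist(lapply(sets, `[[`, "censored"), use.names = FALSE),
    pair = if (by == "pair") sets[[1]]$pair else c(NA, NA),
    band = if (by == "band") sets[[1]]$band,
    n_samples_valid = if (all(is.na(nv))) NA_integer_ else sum(nv, na.rm = TRUE)
  )
}

#' Pairwise phase-lock intervals from a phase stack
#'
#' Computes, for every band and every unordered channel pair, the wrapped
#' phase difference, applies the criterion (with `"auto"` smoothing resolved
#' per band/backend) and extracts intervals. With more than `max_pairs`
#' implied pairs a seeded random subset of `max_pairs` pairs is analysed.
#'
#' @param stack a [phase_stack].
#' @param crit a [lock_criterion].
#' @param pairs optional integer matrix (2 columns) of channel index pairs;
#'   default all unordered pairs.
#' @param max_pairs pair-count cap before random subsetting (default 496).
#' @param pair_seed seed for the pair subset draw.
#' @return list of [interval_set]s, one per band x pair, with attributes
#'   `band_index` and `pair_index` for regrouping.
#' @export
phase_lock_intervals <- function(stack, crit = lock_criterion(),
                                 pairs = NULL, max_pairs = 496L,
                                 pair_seed = 1L) {
  stopifnot(inherits(stack, "phase_stack"), inherits(crit, "lock_criterion"))
  nb <- dim(stack$phases)[1]; nc <- dim(stack$phases)[2]
  if (is.null(pairs)) {
    if (nc < 2) stop_arg("need at least 2 channels for pairwise locking")
    pairs <- t(utils::combn(nc, 2))
    if (nrow(pairs) > max_pairs) {
      idx <- with_seed(pair_seed, sample.int(nrow(pairs), max_pairs))
      pairs <- pairs[sort(idx), , drop = FALSE]
    }
  }
  out <- vector("list", nb * nrow(pairs))
  band_idx <- integer(length(out)); pair_idx <- integer(length(out))
  k <- 0L
  for (b in seq_len(nb)) {
    band <- stack$ladder[[b]]
    w <- resolve_smoothing(crit, stack$method, band_center(band), stack$fs)
    crit_b <- crit; crit_b$smoothing_window <- w
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      dphi <- phase_difference(stack$phases[b, i, ], stack$phases[b, j, ])
      valid <- valid_mask(stack, b, i) & valid_mask(stack, b, j)
      iv <- extract_intervals(dphi, valid, stack$fs, crit_b)
      iv$pair <- paste0("ch", c(i, j))
      iv$band <- band
      k <- k + 1L
      out[[k]] <- iv
      band_idx[k] <- b; pair_idx[k] <- p
    }
  }
  attr(out, "band_index") <- band_idx
  attr(out, "pair_index") <- pair_idx
  attr(out, "pairs") <- pairs
  out
}

#' Log-binned duration distribution
#'
#' Geometric (log-spaced) histogram of interval durations as a probability
#' density: `density = count / (N * bin_width)`, so that
#' `sum(density * diff(edges)) == 1`. Mean-normalised durations
#' (`t / mean(t)`) are attached for cross-band scale collapse.
#'
#' @param set an [interval_set] (or bare numeric durations).
#' @param bins_per_decade geometric bins per factor of 10 (default 10).
#' @return an object of class `log_binned_distribution` with fields
#'   `edges`, `density`, `counts`, `n`, `mean_duration`, `normalized`.
#'   An empty set yields an empty distribution flagged `empty = TRUE`.
#' @export
log_binned_distribution <- function(set, bins_per_decade = 10L) {
  x <- if (inherits(set, "interval_set")) set$durations else as.numeric(set)
  if (!is_count(bins_per_decade) || bins_per_decade < 1)
    stop_arg("`bins_per_decade` must be >= 1")
  if (!length(x)) {
    return(structure(list(edges = numeric(0), density = numeric(0),
                          counts = integer(0), n = 0L,
                          mean_duration = NA_real_, normalized = numeric(0),
                          empty = TRUE),
                     class = "log_binned_distribution"))
  }
  stopifnot(all(x > 0))
  lo <- min(x); hi <- max(x)
  if (lo == hi) {  # degenerate: one bin centred on the value
    half <- 0.5 / bins_per_decade
    edges <- 10^(log10(lo) + c(-half, half))
  } else {
    nbins <- max(1L, ceiling(log10(hi / lo) * bins_per_decade))
    edges <- 10^seq(log10(lo), log10(hi), length.out = nbins + 1L)
    edges[1L] <- lo             # guard rounding: no sample may fall outside
    edges[length(edges)] <- hi
  }
  counts <- tabulate(cut(x, edges, include.lowest = TRUE, labels = FALSE),
                     nbins = length(edges) - 1L)
  density <- counts / (length(x) * diff(edges))
  structure(list(edges = edges, density = density, counts = counts,
                 n = length(x), mean_duration = mean(x),
                 normalized = x / mean(x), empty = FALSE),
            class = "log_binned_distribution")
}

#' @export
print.log_binned_distribution <- function(x, ...) {
  if (isTRUE(x$empty)) cat("<log_binned_distribution> (empty)\n")
  else cat(sprintf("<log_binned_distribution> n=%d, %d bins over [%.4g, %.4g] s, mean %.4g s\n",
                   x$n, length(x$density), min(x$edges), max(x$edges),
                   x$mean_duration))
  invisible(x)
}

#' Interval sets as a data table
#'
#' Flattens a list of [interval_set]s (as produced by
#' [phase_lock_intervals()]) into one table with columns `band`, `pair`,
#' `duration_s`, `censored` -- the TSV result layout.
#'
#' @param sets list of [interval_set]s.
#' @return a `data.table`.
#' @export
intervals_table <- function(sets) {
  rows <- lapply(sets, function(s) {
    if (!length(s$durations)) return(NULL)
    data.table::data.table(
      band = if (is.null(s$band)) NA_character_ else s$band$name,
      pair = paste(s$pair, collapse = "~"),
      duration_s = s$durations,
      censored = s$censored
    )
  })
  data.table::rbindlist(rows)
}
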