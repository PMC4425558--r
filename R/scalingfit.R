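#' Maximum-likelihood power-law tail fit
#'
#' Fits the continuous power law `p(x) = (alpha - 1)/xmin * (x/xmin)^-alpha`
#' to the tail `x >= xmin` by the closed-form MLE
#' `alpha = 1 + n / sum(log(x/xmin))`. With `xmin = "auto"` the cutoff is
#' chosen, in the Clauset-Shalizi-Newman manner, as the candidate value (an
#' observed data point) minimising the Kolmogorov-Smirnov distance between
#' the empirical tail and the fitted model; ties go to the smaller cutoff.
#'
#' @param durations positive numeric sample (seconds, or any single unit).
#' @param xmin lower cutoff in the same units, or `"auto"`.
#' @param xmin_min hard floor on the cutoff (e.g. `3 / fs` to skip
#'   sampling-discretised durations); candidates below it are not
#'   considered. Default 0.
#' @param max_candidates cap on the number of distinct candidate cutoffs
#'   scanned under `"auto"` (quantile-thinned above this; default 100).
#' @return an object of class `power_law_fit` with fields `alpha`, `xmin`,
#'   `n_tail`, `ks`, and (for `"auto"`) attribute `candidates`, a data frame
#'   of scanned cutoffs with their KS distances.
#' @export
fit_power_law <- function(durations, xmin = "auto", xmin_min = 0,
                          max_candidates = 100L) {
  x <- as.numeric(durations)
  x <- x[is.finite(x) & x > 0]
  if (identical(xmin, "auto")) {
    cand <- sort(unique(x[x >= xmin_min]))
    # need >= 10 tail points per candidate
    cand <- cand[vapply(cand, function(c0) sum(x >= c0), 0) >= 10]
    if (!length(cand))
      stop_arg("AUTO xmin needs >= 10 tail samples above xmin_min")
    if (length(cand) > max_candidates) {
      idx <- unique(round(seq(1, length(cand), length.out = max_candidates)))
      cand <- cand[idx]
    }
    fits <- lapply(cand, function(c0) power_law_mle(x, c0))
    ks <- vapply(fits, `[[`, 0, "ks")
    best <- which.min(ks)
    fit <- fits[[best]]
    attr(fit, "candidates") <- data.frame(xmin = cand, ks = ks)
    fit
  } else {
    if (!is.numeric(xmin) || length(xmin) != 1L || xmin <= 0)
      stop_arg("`xmin` must be a positive scalar or \"auto\"")
    # a single sample above xmin suffices for the closed-form MLE; a tail
    # that sits entirely AT xmin falls through to the divergence error
    if (sum(x >= xmin) < 1)
      stop_arg("no samples at or above xmin")
    power_law_mle(x, xmin)
  }
}

power_law_mle <- function(x, xmin) {
  tail <- x[x >= xmin]
  n <- length(tail)
  s <- sum(log(tail / xmin))
  if (s <= 0)
    stop_arg("all tail samples equal xmin: power-law MLE diverges")
  alpha <- 1 + n / s
  xs <- sort(tail)
  f_fit <- 1 - (xs / xmin)^(1 - alpha)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  ks <- max(pmax(abs(emp_hi - f_fit), abs(emp_lo - f_fit)))
  structure(list(alpha = alpha, xmin = xmin, n_tail = n, ks = ks),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha=%.4f, xmin=%.4g, n_tail=%d, KS=%.4f\n",
              x$alpha, x$xmin, x$n_tail, x$ks))
  invisible(x)
}

#' Maximum-likelihood shifted-exponential tail fit
#'
#' Fits `p(x) = rate * exp(-rate * (x - xmin))` to the tail `x >= xmin`;
#' the MLE is `rate = 1 / (mean(tail) - xmin)`. This is the null
#' alternative against which power-law scaling is judged.
#'
#' @inheritParams fit_power_law
#' @param xmin lower cutoff (positive scalar).
#' @return list with fields `rate`, `xmin`, `n_tail`, `degenerate` (TRUE
#'   when the tail has zero variance around xmin and the rate diverges).
#' @export
fit_exponential <- function(durations, xmin) {
  x <- as.numeric(durations)
  x <- x[is.finite(x)]
  if (!is.numeric(xmin) || length(xmin) != 1L)
    stop_arg("`xmin` must be a scalar")
  if (sum(x > xmin) < 2)
    stop_arg("need >= 2 samples above xmin")
  tail <- x[x >= xmin]
  m <- mean(tail) - xmin
  if (m <= 0) {
    return(list(rate = Inf, xmin = xmin, n_tail = length(tail),
                degenerate = TRUE))
  }
  list(rate = 1 / m, xmin = xmin, n_tail = length(tail), degenerate = FALSE)
}

#' Power law versus exponential tail comparison
#'
#' Both models are fit by maximum likelihood on the common tail
#' `x >= xmin`; the pointwise log-likelihood differences
#' `d_i = log p_PL(x_i) - log p_EXP(x_i)` are summed and normalised
#' Vuong-style, `llr = sum(d) / (sd(d) * sqrt(n))`. The verdict is
#' `power_law` when `llr >= 2`, `exponential` when `llr <= -2`, else
#' `indeterminate`; any tail smaller than `min_tail` is `indeterminate`
#' regardless (too little evidence either way).
#'
#' @inheritParams fit_power_law
#' @param xmin common lower cutoff (positive scalar) or `"auto"` (selected
#'   by the power-law KS scan, floored at `xmin_min`).
#' @param min_tail minimum tail size for a determinate verdict (default 50).
#' @return an object of class `scaling_verdict`: fields `fit`
#'   ([fit_power_law] result or `NULL`), `rate`, `llr`, `verdict`,
#'   `min_tail_met`, `n_tail`.
#' @export
compare_models <- function(durations, xmin = "auto", xmin_min = 0,
                           min_tail = 50L) {
  x <- as.numeric(durations)
  x <- x[is.finite(x) & x > 0]
  res <- list(fit = NULL, rate = NA_real_, llr = NA_real_,
              verdict = "indeterminate", min_tail_met = FALSE,
              n_tail = 0L, band = NULL)
  class(res) <- "scaling_verdict"
  enough <- function(c0) sum(x > c0) >= 2 && sum(x >= c0) >= 10
  if (identical(xmin, "auto")) {
    if (!enough(xmin_min)) return(res)
    fit <- tryCatch(fit_power_law(x, "auto", xmin_min = xmin_min),
                    error = function(e) NULL)
  } else {
    if (!(sum(x > xmin) >= 2)) return(res)
    fit <- tryCatch(fit_power_law(x, xmin), error = function(e) NULL)
  }
  if (is.null(fit)) return(res)
  res$fit <- fit
  tail <- x[x >= fit$xmin]
  n <- length(tail)
  res$n_tail <- n
  exp_fit <- fit_exponential(x, fit$xmin)
  res$rate <- exp_fit$rate
  if (exp_fit$degenerate) return(res)
  ll_pl <- log(fit$alpha - 1) - log(fit$xmin) -
    fit$alpha * log(tail / fit$xmin)
  ll_ex <- log(exp_fit$rate) - exp_fit$rate * (tail - fit$xmin)
  d <- ll_pl - ll_ex
  sdd <- sd(d)
  if (!is.finite(sdd) || sdd == 0) return(res)
  res$llr <- sum(d) / (sdd * sqrt(n))
  res$min_tail_met <- n >= min_tail
  if (res$min_tail_met) {
    res$verdict <- if (res$llr >= 2) "power_law"
                   else if (res$llr <= -2) "exponential"
                   else "indeterminate"
  }
  res
}

#' @export
print.scaling_verdict <- function(x, ...) {
  cat(sprintf("<scaling_verdict>%s %s (llr=%.2f, n_tail=%d%s)\n",
              if (!is.null(x$band)) paste0(" [", x$band$name, "]") else "",
              x$verdict,
              if (is.na(x$llr)) NA else x$llr, x$n_tail,
              if (!is.null(x$fit)) sprintf(", alpha=%.3f, xmin=%.4g",
                                           x$fit$alpha, x$fit$xmin) else ""))
  invisible(x)
}
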