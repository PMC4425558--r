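#' Run one analysis condition end to end
#'
#' One cell of the method-by-condition grid: obtain the record (generate
#' from a [generator_config] or use one supplied), optionally notch-filter,
#' extract per-band phase with the chosen backend, extract pairwise lock
#' intervals, pool per band, and fit the scaling models. Fully deterministic
#' given the seeds carried in the configuration.
#'
#' @param input a [ts_record] or a [generator_config].
#' @param method phase backend, `"wavelet"` or `"hilbert"`.
#' @param notch a [notch_spec] applied before phase extraction, or `NULL`
#'   for none.
#' @param criterion a [lock_criterion].
#' @param ladder a `band_ladder`; default [default_ladder()] at the record's
#'   sampling rate.
#' @param min_tail minimum pooled tail size for a determinate verdict.
#' @param bins_per_decade log-binning resolution of the reported
#'   distributions.
#' @param xmin_tail_quantile lower bound of the scanned power-law cutoffs,
#'   as a floor of `3 / fs` (sampling discreteness guard); kept as a
#'   parameter for sensitivity analysis.
#' @param name condition label carried into reports.
#' @return an object of class `condition_result`: list with `name`,
#'   `bands` (per-band list of `band`, `intervals` summary,
#'   `distribution`, `verdict`, `total_locked_s`, `n_intervals`), and
#'   `provenance`.
#' @export
run_condition <- function(input, method = c("wavelet", "hilbert"),
                          notch = NULL, criterion = lock_criterion(),
                          ladder = NULL, min_tail = 50L,
                          bins_per_decade = 10L, xmin_tail_quantile = NULL,
                          name = NULL) {
  method <- match.arg(method)
  t0 <- proc.time()[["elapsed"]]
  if (inherits(input, "generator_config")) {
    record <- generate_record(input)
    input_desc <- list(type = "generated", config = unclass_deep(input))
  } else if (inherits(input, "ts_record")) {
    record <- input
    input_desc <- list(type = "record", meta = record$meta)
  } else {
    stop_arg("`input` must be a ts_record or generator_config")
  }
  log_stage("input", sprintf("%d ch x %d samples @ %g Hz",
                             n_channels(record), n_samples(record), record$fs), t0)
  if (!is.null(notch)) {
    t1 <- proc.time()[["elapsed"]]
    record <- notch_filter(record, notch)
    log_stage("notch", sprintf("f0=%g Hz Q=%g", notch$f0, notch$quality), t1)
  }
  if (is.null(ladder)) ladder <- default_ladder(record$fs)
  t1 <- proc.time()[["elapsed"]]
  stack <- extract_phase(record, method, ladder)
  log_stage("phase", method, t1)
  t1 <- proc.time()[["elapsed"]]
  sets <- phase_lock_intervals(stack, criterion)
  band_idx <- attr(sets, "band_index")
  log_stage("intervals", sprintf("%d band x pair sets", length(sets)), t1)
  xmin_min <- 3 / record$fs
  bands <- vector("list", length(ladder))
  for (b in seq_along(ladder)) {
    pooled <- pool_intervals(sets[band_idx == b], by = "band")
    verdict <- compare_models(pooled$durations, xmin = "auto",
                              xmin_min = xmin_min, min_tail = min_tail)
    verdict$band <- ladder[[b]]
    bands[[b]] <- list(
      band = ladder[[b]],
      distribution = log_binned_distribution(pooled, bins_per_decade),
      verdict = verdict,
      total_locked_s = sum(pooled$durations),
      n_intervals = length(pooled$durations),
      n_censored = sum(pooled$censored)
    )
  }
  names(bands) <- vapply(ladder, `[[`, "", "name")
  structure(
    list(name = name %||% method, method = method, bands = bands,
         provenance = list(
           input = input_desc,
           method = method,
           notch = if (!is.null(notch)) unclass(notch),
           criterion = unclass(criterion),
           ladder = lapply(ladder, unclass),
           min_tail = min_tail, bins_per_decade = bins_per_decade,
           xmin_min = xmin_min,
           package_version = as.character(utils::packageVersion("plscan"))
         )),
    class = "condition_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

# structured per-stage log lines to stderr; off unless
# options(plscan.verbose = TRUE) (the CLI turns it on)
log_stage <- function(stage, detail, t0) {
  if (!isTRUE(getOption("plscan.verbose", FALSE))) return(invisible())
  dt <- proc.time()[["elapsed"]] - t0
  message(sprintf("[plscan] stage=%s %s (%.2fs)", stage, detail, dt))
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> '%s' (%s backend)\n", x$name, x$method))
  print(summary_table(list(x)))
  invisible(x)
}

#' Run a grid of analysis conditions
#'
#' Evaluates several conditions (e.g. the six-cell comparison
#' \{wavelet, hilbert\} x \{human, empty room + line, empty room notched\})
#' and collects per-band verdicts. A failing cell is recorded as failed;
#' the grid always completes.
#'
#' @param conditions named list; each element is a list of arguments for
#'   [run_condition()].
#' @return an object of class `grid_result` with `cells` (condition results
#'   or error messages) and `provenance`.
#' @export
run_grid <- function(conditions) {
  stopifnot(length(conditions) >= 1)
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    names(conditions) <- paste0("cell", seq_along(conditions))
  cells <- lapply(names(conditions), function(nm) {
    args <- conditions[[nm]]
    args$name <- args$name %||% nm
    tryCatch(do.call(run_condition, args),
             error = function(e) structure(
               list(name = nm, error = conditionMessage(e)),
               class = "condition_failure"))
  })
  names(cells) <- names(conditions)
  structure(
    list(cells = cells,
         provenance = list(
           n_conditions = length(conditions),
           package_version = as.character(utils::packageVersion("plscan")))),
    class = "grid_result"
  )
}

#' The default six-cell condition grid
#'
#' The analog of the published comparison: rows \{synthetic human, synthetic
#' empty room with mains line noise, the same empty-room record notch
#' filtered\} by columns \{wavelet backend, hilbert backend\}. The human
#' cells use the synthetic human preset because no real recordings ship
#' with the package; report headers say so.
#'
#' @param seed master seed; per-regime seeds are derived deterministically.
#' @param duration,fs,n_channels record geometry (defaults 300 s, 600 Hz, 4).
#' @param line_f0 mains fundamental for the empty-room rows (50 or 60 Hz).
#' @return named list of condition argument lists for [run_grid()].
#' @export
default_grid_conditions <- function(seed = 1L, duration = 300, fs = 600,
                                    n_channels = 4L, line_f0 = 50) {
  human <- generator_config("human", n_channels = n_channels,
                            duration = duration, fs = fs,
                            seed = derive_seed(seed, 1L))
  empty <- generator_config("empty_room", n_channels = n_channels,
                            duration = duration, fs = fs,
                            line = default_line_model(f0 = line_f0),
                            seed = derive_seed(seed, 2L))
  notch <- notch_spec(line_f0)
  list(
    human_wavelet       = list(input = human, method = "wavelet"),
    human_hilbert       = list(input = human, method = "hilbert"),
    empty_line_wavelet  = list(input = empty, method = "wavelet"),
    empty_line_hilbert  = list(input = empty, method = "hilbert"),
    empty_notch_wavelet = list(input = empty, method = "wavelet", notch = notch),
    empty_notch_hilbert = list(input = empty, method = "hilbert", notch = notch)
  )
}

#' Summarise grid or condition results as a table
#'
#' @param results a `grid_result`, a `condition_result`, or a list of
#'   condition results.
#' @return a `data.table` with one row per condition x band: columns
#'   `condition`, `band`, `n_intervals`, `total_locked_s`, `alpha`, `xmin`,
#'   `ks`, `llr`, `verdict`.
#' @export
summary_table <- function(results) {
  if (inherits(results, "grid_result")) results <- results$cells
  if (inherits(results, "condition_result")) results <- list(results)
  rows <- list()
  for (cell in results) {
    if (inherits(cell, "condition_failure")) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        condition = cell$name, band = NA_character_, n_intervals = NA_integer_,
        total_locked_s = NA_real_, alpha = NA_real_, xmin = NA_real_,
        ks = NA_real_, llr = NA_real_, verdict = paste("FAILED:", cell$error))
      next
    }
    for (bres in cell$bands) {
      v <- bres$verdict
      rows[[length(rows) + 1L]] <- data.table::data.table(
        condition = cell$name, band = bres$band$name,
        n_intervals = bres$n_intervals,
        total_locked_s = bres$total_locked_s,
        alpha = if (!is.null(v$fit)) v$fit$alpha else NA_real_,
        xmin = if (!is.null(v$fit)) v$fit$xmin else NA_real_,
        ks = if (!is.null(v$fit)) v$fit$ks else NA_real_,
        llr = v$llr, verdict = v$verdict)
    }
  }
  data.table::rbindlist(rows)
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d cell(s)\n", length(x$cells)))
  print(summary_table(x))
  invisible(x)
}

#' Serialise results to JSON / TSV
#'
#' `grid_json()` returns a deterministic JSON string (no timestamps) with
#' per-band fits and the full provenance needed to re-run bit-identically;
#' `write_grid_results()` writes `results.json`, a `summary.tsv` table and
#' per-cell distribution TSVs (`band, bin_lo_s, bin_hi_s, density`) into a
#' directory.
#'
#' @param grid a `grid_result`.
#' @return `grid_json()`: a JSON string; `write_grid_results()`: the output
#'   directory, invisibly.
#' @export
grid_json <- function(grid) {
  stopifnot(inherits(grid, "grid_result"))
  cells <- lapply(grid$cells, function(cell) {
    if (inherits(cell, "condition_failure"))
      return(list(failed = TRUE, error = cell$error))
    list(
      method = cell$method,
      note = "synthetic data: no real recordings are analysed",
      bands = lapply(cell$bands, function(bres) {
        v <- bres$verdict
        list(band = list(name = bres$band$name, f_lo = bres$band$f_lo,
                         f_hi = bres$band$f_hi),
             n_intervals = bres$n_intervals,
             n_censored = bres$n_censored,
             total_locked_s = bres$total_locked_s,
             alpha = if (!is.null(v$fit)) v$fit$alpha else NA,
             xmin = if (!is.null(v$fit)) v$fit$xmin else NA,
             ks = if (!is.null(v$fit)) v$fit$ks else NA,
             llr = v$llr,
             n_tail = v$n_tail,
             verdict = v$verdict)
      }),
      provenance = cell$provenance
    )
  })
  jsonlite::toJSON(list(cells = cells, provenance = grid$provenance),
                   auto_unbox = TRUE, digits = 10, null = "null",
                   na = "null", pretty = TRUE)
}

#' @rdname grid_json
#' @param outdir output directory (created if missing).
#' @export
write_grid_results <- function(grid, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeLines(grid_json(grid), file.path(outdir, "results.json"))
  data.table::fwrite(summary_table(grid), file.path(outdir, "summary.tsv"),
                     sep = "\t")
  for (nm in names(grid$cells)) {
    cell <- grid$cells[[nm]]
    if (inherits(cell, "condition_failure")) next
    rows <- data.table::rbindlist(lapply(cell$bands, function(bres) {
      d <- bres$distribution
      if (isTRUE(d$empty)) return(NULL)
      data.table::data.table(
        band = bres$band$name,
        bin_lo_s = utils::head(d$edges, -1),
        bin_hi_s = utils::tail(d$edges, -1),
        density = d$density)
    }))
    data.table::fwrite(rows, file.path(outdir, paste0(nm, "_distribution.tsv")),
                       sep = "\t")
  }
  invisible(outdir)
}
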