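#' Multichannel time-series record
#'
#' The universal signal container: a channels x samples real matrix plus the
#' sampling rate, channel labels and a free-form provenance list. All
#' generator, preprocessing and phase-extraction functions consume and
#' produce `ts_record` objects.
#'
#' @param data numeric matrix, `n_channels x n_samples`; all values finite.
#' @param fs sampling rate in Hz (strictly positive scalar).
#' @param labels character vector of unique channel names; defaults to
#'   `"ch1", "ch2", ...`.
#' @param meta named list of provenance (generator parameters, preprocessing
#'   history). Preprocessing functions append to `meta$preprocessing`.
#' @return an object of class `ts_record`.
#' @examples
#' rec <- ts_record(matrix(rnorm(200), nrow = 2), fs = 100)
#' rec
#' @export
ts_record <- function(data, fs, labels = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_arg("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 2L)
    stop_arg("need n_channels >= 1 and n_samples >= 2, got %d x %d",
             nrow(data), ncol(data))
  if (!all(is.finite(data))) stop_arg("`data` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_arg("`fs` must be a positive scalar (Hz)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data) || anyDuplicated(labels))
    stop_arg("`labels` must supply one unique name per channel")
  structure(
    list(data = unname(data), fs = as.numeric(fs), labels = labels,
         meta = meta),
    class = "ts_record"
  )
}

#' @export
print.ts_record <- function(x, ...) {
  cat(sprintf("<ts_record> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$fs, duration(x)))
  cat(" labels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (n_channels(x) > 8) "...", "\n")
  if (length(x$meta$preprocessing))
    cat(" preprocessing:",
        paste(vapply(x$meta$preprocessing, `[[`, "", "step"),
              collapse = " -> "), "\n")
  invisible(x)
}

#' @rdname ts_record
#' @param x a `ts_record`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname ts_record
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname ts_record
#' @export
duration <- function(x) ncol(x$data) / x$fs

# append one preprocessing history entry
record_note <- function(rec, step, params) {
  rec$meta$preprocessing <- c(rec$meta$preprocessing,
                              list(c(list(step = step), params)))
  rec
}

#' Read and write records as CSV with a JSON sidecar
#'
#' The plain-text container: a CSV file with one column per channel (header
#' row = channel labels) and a JSON sidecar `<path>.json` holding the
#' sampling rate, labels and metadata. Suited to small fixtures and to
#' exchanging records with other tools.
#'
#' @param record a [ts_record].
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_record_csv` returns `path` invisibly; `read_record_csv`
#'   returns a [ts_record].
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "ts_record"))
  dt <- data.table::as.data.table(t(record$data))
  data.table::setnames(dt, record$labels)
  data.table::fwrite(dt, path)
  side <- list(fs = record$fs, labels = record$labels, meta = record$meta)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop_arg("sidecar %s not found (fs is required)", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  dt <- data.table::fread(path)
  ts_record(t(as.matrix(dt)), fs = side$fs, labels = names(dt),
            meta = if (is.null(side$meta)) list() else as.list(side$meta))
}
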