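# CSV readers/writers shared across modules.

#' Read a two-column time-series CSV into a temperature trace
#'
#' Expects a `time` column and one value column (any name). The `minutes`
#' dialect takes `time` as minutes from recording start; the `clock` dialect
#' takes `"HH:MM"` clock stamps, uses the first stamp as the clock anchor,
#' and unwraps across midnight.
#'
#' @param path CSV file path.
#' @param dialect `"minutes"` or `"clock"`.
#' @param ... metadata passed to [temperature_trace()] (e.g. `subject_id`).
#' @return A [temperature_trace()] (uniform-grid check applied).
#' @export
read_timeseries_csv <- function(path, dialect = c("minutes", "clock"), ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(d) || ncol(d) < 2L)
    stop("expected a 'time' column plus one value column")
  value <- d[[setdiff(names(d), "time")[1L]]]
  if (dialect == "clock") {
    clk <- parse_clock(d$time)
    time <- clk - clk[1L]
    wrap <- cumsum(c(0, diff(time) < 0)) * 1440
    time <- time + wrap
    extra <- list(...)
    if (is.null(extra$clock_offset)) extra$clock_offset <- clk[1L]
    args <- c(list(time = time, temp = value), extra)
  } else {
    time <- as.numeric(d$time)
    args <- list(time = time, temp = value, ...)
  }
  bad <- which(diff(time) <= 0)
  if (length(bad))
    stop(sprintf("time not strictly increasing at row %d", bad[1L] + 1L))
  do.call(temperature_trace, args)
}

#' Write a temperature trace to CSV
#'
#' Two columns, `time` (minutes from start) and `temp`; reading the file
#' back with [read_timeseries_csv()] reproduces the trace.
#'
#' @param trace a [temperature_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  utils::write.csv(data.frame(time = trace$time, temp = trace$temp),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a bout table to CSV
#'
#' @param bouts a `torpor_bouts` table from [detect_bouts()].
#' @param path output CSV path.
#' @param subject subject label column.
#' @return `path`, invisibly.
#' @export
write_bouts_csv <- function(bouts, path, subject = "subject") {
  d <- cbind(subject = subject, as.data.frame(bouts))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write per-subject torpor summaries to CSV
#'
#' @param summaries a `torpor_summary` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_torpor_summary_csv <- function(summaries, path) {
  if (inherits(summaries, "torpor_summary")) summaries <- list(summaries)
  d <- do.call(rbind, lapply(summaries, as.data.frame))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write generator ground truth as a JSON sidecar
#'
#' Plain-text, human-readable key/value sidecar for a generated dataset.
#'
#' @param truth the `truth` element returned by a generator.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
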