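#' Epoch-level accelerometer series
#'
#' An `epoch_series` holds the raw objective signal for one participant: a
#' regularly sampled sequence of nonnegative acceleration magnitudes
#' (milli-gravities, the vector-magnitude average over each epoch) together
#' with a per-epoch wear flag and the calendar start time. Analysis days run
#' noon-to-noon so that a single main sleep period is never split across a
#' day boundary.
#'
#' @param values Numeric vector of nonnegative epoch magnitudes (milli-g).
#' @param start POSIXct start timestamp of the first epoch (UTC recommended).
#' @param epoch_s Epoch length in seconds; must divide 3600.
#' @param wear Logical vector of the same length as `values`; `TRUE` where the
#'   device was worn. Defaults to all worn.
#'
#' @return An object of class `epoch_series`: a list with elements `values`,
#'   `wear`, `start` and `epoch_s`.
#' @examples
#' es <- epoch_series(rep(10, 1440), start = as.POSIXct("2015-06-01 12:00:00",
#'                    tz = "UTC"), epoch_s = 60)
#' n_days(es)
#' @export
epoch_series <- function(values, start, epoch_s = 60, wear = NULL) {
  if (is.null(wear)) wear <- rep(TRUE, length(values))
  if (!inherits(start, "POSIXct")) {
    start <- as.POSIXct(start, tz = "UTC")
  }
  if (length(values) != length(wear)) {
    stop("`values` and `wear` must have the same length", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("epoch magnitudes must be nonnegative and non-missing", call. = FALSE)
  }
  if (length(epoch_s) != 1L || epoch_s <= 0 || 3600 %% epoch_s != 0) {
    stop("`epoch_s` must be a positive divisor of 3600", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), wear = as.logical(wear),
         start = start, epoch_s = as.integer(epoch_s)),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> %d epochs of %ds from %s (%.2f days, %.1f%% worn)\n",
    length(x$values), x$epoch_s, format(x$start, "%Y-%m-%d %H:%M %Z"),
    length(x$values) * x$epoch_s / 86400, 100 * mean(x$wear)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)

#' Number of whole recording days in a series
#'
#' @param series An [epoch_series()].
#' @return Number of complete 24-h days covered by the series (integer when
#'   the series covers whole days).
#' @export
n_days <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  length(series$values) * series$epoch_s / 86400
}

epochs_per_day <- function(series) 86400L %/% series$epoch_s

#' Convert an epoch series to a data frame
#'
#' @param x An [epoch_series()].
#' @param row.names,optional,... Passed on for S3 consistency (unused).
#' @return A data.frame with columns `timestamp` (POSIXct), `magnitude`
#'   (milli-g) and `wear` (logical).
#' @export
as.data.frame.epoch_series <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    timestamp = x$start + (seq_along(x$values) - 1L) * x$epoch_s,
    magnitude = x$values,
    wear = x$wear
  )
}

#' Read / write an epoch series as CSV
#'
#' The on-disk format is one row per epoch with ISO-8601 timestamp, magnitude
#' in milli-g and a wear flag, matching [as.data.frame.epoch_series()].
#'
#' @param series An [epoch_series()].
#' @param path File path.
#' @return `write_epoch_series()` returns `path` invisibly;
#'   `read_epoch_series()` returns an [epoch_series()].
#' @export
write_epoch_series <- function(series, path) {
  df <- as.data.frame(series)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_series
#' @export
read_epoch_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  epoch_s <- if (nrow(df) > 1L) as.numeric(difftime(ts[2L], ts[1L], units = "secs")) else 60
  epoch_series(df$magnitude, start = ts[1L], epoch_s = epoch_s,
               wear = as.logical(df$wear))
}
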