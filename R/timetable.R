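#' Timestamped multivariate series
#'
#' A `timetable` is the package's universal data currency: a `data.frame`
#' whose first column, `date`, holds strictly increasing `POSIXct`
#' timestamps and whose remaining columns are numeric series aligned to
#' those timestamps, with `NA` as the missing marker. Timestamps are stored
#' timezone-naive (POSIXct in UTC); the local-time label the data were
#' recorded in is carried as the `tz_label` attribute and never used for
#' conversion.
#'
#' @param date `POSIXct` (or coercible) vector of timestamps.
#' @param ... named numeric vectors, one per variable, each of `length(date)`.
#' @param tz_label character label describing the clock the timestamps refer
#'   to (e.g. `"UTC+2"`); metadata only.
#' @param meta free-form provenance notes (any object).
#' @return A `timetable` object (subclass of `data.frame`).
#' @examples
#' tt <- timetable(as.POSIXct("2017-01-01 00:00", tz = "UTC") + 3600 * 0:2,
#'                 bc = c(1.2, NA, 0.8))
#' @export
timetable <- function(date, ..., tz_label = "UTC+2", meta = NULL) {
  date <- as.POSIXct(date, tz = "UTC")
  cols <- list(...)
  if (length(cols) == 1L && is.null(names(cols)) && is.data.frame(cols[[1L]]))
    cols <- as.list(cols[[1L]])
  out <- data.frame(date = date)
  for (nm in names(cols)) {
    v <- cols[[nm]]
    stopifnot(length(v) == length(date))
    out[[nm]] <- as.numeric(v)
  }
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  validate_timetable(out)
  attr(out, "tz_label") <- tz_label
  attr(out, "meta") <- meta
  class(out) <- c("timetable", "data.frame")
  out
}

validate_timetable <- function(x) {
  if (!"date" %in% names(x)) stop("timetable must have a 'date' column")
  d <- x$date
  if (anyNA(d)) stop("timetable timestamps must not be missing")
  if (is.unsorted(d, strictly = TRUE)) {
    dup <- d[duplicated(d)]
    if (length(dup))
      stop("duplicate timestamps: ",
           paste(format(unique(dup), tz = "UTC"), collapse = ", "))
    stop("timestamps must be strictly increasing")
  }
  invisible(x)
}

#' @export
print.timetable <- function(x, ...) {
  cat(sprintf("<timetable> %d rows x %d variables [%s]\n",
              nrow(x), ncol(x) - 1L, attr(x, "tz_label") %||% "?"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variable names of a timetable (excluding the timestamp column)
#' @param table a `timetable`.
#' @return character vector of variable names.
#' @export
tt_vars <- function(table) setdiff(names(table), "date")

#' Read a timetable from delimited text
#'
#' Reads a CSV (or other delimited) file with a header row and a timestamp
#' column into a [timetable]. Rows are re-sorted by time; cells matching any
#' of `missing_markers`, and cells that do not parse as numbers, become
#' missing.
#'
#' @param path file path.
#' @param time_col name of the timestamp column (default `"date"`).
#' @param missing_markers character values read as missing, in addition to
#'   empty cells.
#' @param sep field separator.
#' @param tz_label carried into the result; see [timetable].
#' @return A [timetable].
#' @export
read_timetable <- function(path, time_col = "date",
                           missing_markers = c("", "NA", "NaN"),
                           sep = ",", tz_label = "UTC+2") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "\"",
                           comment.char = "")
  if (!time_col %in% names(raw))
    stop("timestamp column '", time_col, "' not found in ", path)
  ts <- as.POSIXct(raw[[time_col]], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M",
                                  "%Y-%m-%d"))
  if (anyNA(ts))
    stop("unparseable timestamps in ", path, " at rows: ",
         paste(utils::head(which(is.na(ts)), 5L), collapse = ", "))
  if (anyDuplicated(ts))
    stop("duplicate timestamps in ", path, ": ",
         paste(format(unique(ts[duplicated(ts)]), tz = "UTC"), collapse = ", "))
  vars <- setdiff(names(raw), time_col)
  cols <- lapply(raw[vars], function(v) {
    v[v %in% missing_markers] <- NA_character_
    suppressWarnings(as.numeric(v))
  })
  names(cols) <- vars
  do.call(timetable, c(list(date = ts), cols, list(tz_label = tz_label)))
}

#' Write a timetable to CSV
#'
#' Timestamps are written as ISO-8601 (`YYYY-MM-DDTHH:MM:SS`), missing
#' values as empty cells. `read_timetable(write_timetable(x))` reproduces
#' `x` up to floating-point formatting (17 significant digits are written,
#' so round-trip error is below 1e-9 relative).
#'
#' @param table a [timetable].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timetable <- function(table, path) {
  validate_timetable(table)
  out <- as.data.frame(table)
  out$date <- format(out$date, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (nm in tt_vars(table))
    out[[nm]] <- ifelse(is.na(out[[nm]]), "",
                        formatC(out[[nm]], digits = 17, format = "g"))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
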