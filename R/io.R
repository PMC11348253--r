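# Readers and writers for event series and detection results.

#' Read an event series from a text file
#'
#' Two layouts are supported: \code{"timestamps"} — one non-negative integer
#' per row (an optional \code{timestamp} header is skipped) — and
#' \code{"binary"} — CSV rows \code{t,x} with \code{x} in \{0, 1\}; events
#' are the rows with \code{x = 1}. Timestamps are sorted and deduplicated;
#' the series length is the largest time seen.
#'
#' @param path file path.
#' @param format \code{"timestamps"} or \code{"binary"}.
#' @return an \code{\link{event_series}}.
#' @export
read_events <- function(path, format = c("timestamps", "binary")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  if (format == "timestamps") {
    if (grepl("[A-Za-z]", lines[1])) lines <- lines[-1]
    if (length(lines) == 0) stop("no timestamps in ", path)
    vals <- suppressWarnings(as.numeric(lines))
    bad <- which(!is.finite(vals) | vals < 0 | vals != round(vals))
    if (length(bad) > 0) {
      stop("invalid timestamp at line ", bad[1], ": '", lines[bad[1]], "'")
    }
    event_series(vals)
  } else {
    if (grepl("[A-Za-z]", lines[1])) lines <- lines[-1]
    parts <- strsplit(lines, ",", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop("binary format needs two comma-separated columns t,x")
    }
    t <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
    x <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
    bad <- which(!is.finite(t) | t < 0 | t != round(t) | !(x %in% c(0, 1)))
    if (length(bad) > 0) {
      stop("invalid binary row at line ", bad[1], ": '", lines[bad[1]], "'")
    }
    ts <- t[x == 1]
    if (length(ts) == 0) stop("no events (x = 1) in ", path)
    event_series(ts, n_t = max(t))
  }
}

#' Write an event series to a text file
#'
#' @param x an \code{\link{event_series}}.
#' @param path file path.
#' @param format \code{"timestamps"} (single \code{timestamp} column) or
#'   \code{"binary"} (\code{t,x} rows covering \code{0..n_t}).
#' @return \code{path}, invisibly.
#' @export
write_events <- function(x, path, format = c("timestamps", "binary")) {
  stopifnot(inherits(x, "event_series"))
  format <- match.arg(format)
  if (format == "timestamps") {
    writeLines(c("timestamp", format(x$timestamps, scientific = FALSE,
                                     trim = TRUE)), path)
  } else {
    v <- as_binary(x)
    writeLines(c("t,x", paste(seq_along(v) - 1L, v, sep = ",")), path)
  }
  invisible(path)
}

#' Write a fitted periodicity model to JSON
#'
#' @param fit a \code{\link{gmpda}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_result <- function(fit, path) {
  stopifnot(inherits(fit, "gmpda"))
  doc <- list(
    periods = as.integer(fit$periods),
    sigmas = as.numeric(fit$sigmas),
    loss = if (is.finite(fit$loss)) fit$loss else NULL,
    model = fit$model,
    candidates = as.integer(fit$candidates),
    z_hat = fit$z_hat,
    config = unclass(fit$config),
    package_version = as.character(utils::packageVersion("gmpda")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
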