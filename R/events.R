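#' Event time series
#'
#' Container for a uni-variate binary event-onset series, stored as the set
#' of event timestamps \code{S = \{s_i\}} (non-negative integers, sorted,
#' unique) together with the series length \code{n_t}. The equivalent binary
#' representation \code{X_t} of length \code{n_t} has \code{x_t = 1} exactly
#' at the timestamps.
#'
#' @param timestamps integer vector of event times (any order; duplicates are
#'   collapsed).
#' @param n_t series length. Defaults to \code{max(timestamps)}.
#' @return An object of class \code{"event_series"}: a list with elements
#'   \code{timestamps} and \code{n_t}.
#' @examples
#' event_series(c(12, 23, 34, 45, 56, 67))
#' @export
event_series <- function(timestamps, n_t = NULL) {
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) > 0) {
    if (any(!is.finite(timestamps))) {
      stop("timestamps must be finite")
    }
    if (any(timestamps < 0)) {
      stop("timestamps must be non-negative")
    }
    timestamps <- sort(unique(round(timestamps)))
  }
  if (is.null(n_t)) {
    if (length(timestamps) == 0) {
      stop("n_t must be given for an empty series")
    }
    n_t <- max(timestamps)
  }
  n_t <- round(as.numeric(n_t))
  if (!is.finite(n_t) || n_t < 1) stop("n_t must be a positive integer")
  if (length(timestamps) > 0 && max(timestamps) > n_t) {
    stop("timestamps must lie in [0, n_t]")
  }
  structure(list(timestamps = timestamps, n_t = n_t),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  n <- length(x$timestamps)
  cat(sprintf("Event series: %d events on [0, %d]\n", n, x$n_t))
  if (n > 0) {
    shown <- utils::head(x$timestamps, 10)
    cat("  s:", paste(shown, collapse = " "),
        if (n > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$timestamps)

#' Convert an event series to its binary 0/1 representation
#'
#' @param x an \code{\link{event_series}}.
#' @return integer vector of length \code{n_t + 1}; position \code{t + 1}
#'   holds \code{x_t} (timestamps are 0-based sample indices).
#' @export
as_binary <- function(x) {
  stopifnot(inherits(x, "event_series"))
  v <- integer(x$n_t + 1)
  v[x$timestamps + 1] <- 1L
  v
}

#' Naive single-period estimator
#'
#' The mean of consecutive inter-event intervals, i.e. the "average interval"
#' between adjacent timestamps. Valid only for a single stationary
#' periodicity without noise; for \code{S = \{12, 23, 34, 45, 56, 67\}} it
#' returns the prime period 11.
#'
#' @param x an \code{\link{event_series}} with at least two events.
#' @return the estimated period (numeric scalar).
#' @examples
#' naive_period(event_series(c(12, 23, 34, 45, 56, 67)))
#' @export
naive_period <- function(x) {
  stopifnot(inherits(x, "event_series"))
  if (length(x$timestamps) < 2) {
    stop("naive_period needs at least two events")
  }
  mean(diff(x$timestamps))
}
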