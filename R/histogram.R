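#' All-order forward inter-event interval histogram D(mu)
#'
#' Counts, for every lag \code{mu} in \code{1..max_lag}, the ordered pairs
#' \code{i < j} with \code{s_j - s_i = mu} — i.e. intervals of every order
#' \code{m}, not only between adjacent events. Peaks at a period and its
#' integer multiples are the raw signal the detector works on.
#'
#' @param events an \code{\link{event_series}}.
#' @param max_lag largest lag counted; capped at \code{n_t - 1}.
#' @return An object of class \code{"interval_histogram"}: list with
#'   \code{counts} (numeric vector indexed by lag \code{1..max_lag}),
#'   \code{max_lag}, \code{n_t}, \code{n_events}.
#' @examples
#' h <- interval_counts(event_series(c(12, 23, 34, 45, 56, 67)), 60)
#' h$counts[c(11, 22, 33)]
#' @export
interval_counts <- function(events, max_lag) {
  stopifnot(inherits(events, "event_series"))
  max_lag <- min(as.integer(max_lag), events$n_t - 1L)
  if (max_lag < 1) stop("max_lag must be >= 1")
  s <- events$timestamps
  n <- length(s)
  counts <- numeric(max_lag)
  if (n < 2) {
    warning("fewer than 2 events: empty histogram")
  } else {
    # order-m differences until all exceed max_lag
    for (m in seq_len(n - 1)) {
      d <- s[(m + 1):n] - s[1:(n - m)]
      d <- d[d <= max_lag & d >= 1]
      if (length(d) == 0) {
        if (min(s[(m + 1):n] - s[1:(n - m)]) > max_lag) break
        next
      }
      tab <- tabulate(d, nbins = max_lag)
      counts <- counts + tab
    }
  }
  structure(list(counts = counts, max_lag = max_lag,
                 n_t = events$n_t, n_events = n),
            class = "interval_histogram")
}

#' @export
print.interval_histogram <- function(x, ...) {
  cat(sprintf("Interval histogram: %d events, lags 1..%d, %d intervals\n",
              x$n_events, x$max_lag, sum(x$counts)))
  invisible(x)
}

#' Expected interaction-interval curve under uniform noise
#'
#' For events uniformly distributed on \code{[1, n_t]} the expected number of
#' forward pairwise differences equal to \code{mu} decays linearly:
#' \code{z * (1 - mu / n_t)}. This single curve approximates all interaction
#' intervals — between distinct periodicities, between periodic and noise
#' events, and among noise events.
#'
#' @param z level constant (for pure uniform noise of \code{n} events,
#'   \code{z = (2 n^2 - (n^2 + n)) / (2 n_t)}).
#' @param n_t series length.
#' @param lags integer lags at which to evaluate.
#' @return numeric vector, clipped at 0.
#' @export
expected_interaction <- function(z, n_t, lags) {
  stopifnot(z >= 0, n_t >= 1)
  pmax(z * (1 - lags / n_t), 0)
}

#' Estimate the interaction-curve level from sub-periodic lags
#'
#' Lags below the smallest admissible period can contain only noise and
#' interaction intervals, so the level \code{z} of the linear interaction
#' curve is estimated by pointwise inversion on that window:
#' the mean of \code{D(mu) / (1 - mu / n_t)} over
#' \code{mu = 1..noise_range}.
#'
#' @param hist an \code{\link{interval_counts}} histogram.
#' @param noise_range width of the sub-periodic window (must be below
#'   \code{l_min}).
#' @param l_min smallest period that will be searched.
#' @return An object of class \code{"noise_estimate"}: list with
#'   \code{z_hat}, \code{n_t}, \code{fit_window}.
#' @export
estimate_z <- function(hist, noise_range, l_min) {
  stopifnot(inherits(hist, "interval_histogram"))
  noise_range <- as.integer(noise_range)
  if (noise_range < 1 || noise_range >= l_min) {
    stop("need 1 <= noise_range < l_min")
  }
  win <- seq_len(min(noise_range, hist$max_lag))
  d <- hist$counts[win]
  z_hat <- if (all(d == 0)) 0 else mean(d / (1 - win / hist$n_t))
  structure(list(z_hat = z_hat, n_t = hist$n_t, fit_window = win),
            class = "noise_estimate")
}

#' Subtract the estimated interaction curve from a histogram
#'
#' @param hist an \code{\link{interval_counts}} histogram.
#' @param noise a \code{\link{estimate_z}} result (or any list with
#'   \code{z_hat}).
#' @return numeric vector \code{max(D(mu) - z_hat (1 - mu / n_t), 0)} over
#'   lags \code{1..max_lag}.
#' @export
denoise <- function(hist, noise) {
  stopifnot(inherits(hist, "interval_histogram"))
  lags <- seq_len(hist$max_lag)
  pmax(hist$counts - expected_interaction(noise$z_hat, hist$n_t, lags), 0)
}
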