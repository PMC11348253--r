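# Comparison detectors: spectral (FFT on the series, its ACF, or the
# interval histogram) and E-periodicity (modulus folding).

.baseline_result <- function(method, periods, scores) {
  structure(list(method = method, periods = as.integer(periods),
                 scores = scores),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("%s: periods %s\n", x$method,
              paste(x$periods, collapse = ", ")))
  invisible(x)
}

# top-k periodogram peaks of a real sequence, restricted to periods in
# [l_min, l_max]; iterative maximum with +/- 1 bin exclusion
.spectral_peaks <- function(x, k, l_min, l_max, method) {
  n <- length(x)
  x <- x - mean(x)
  if (all(x == 0)) stop("no spectral peak in range: constant sequence")
  pw <- Mod(stats::fft(x))^2
  j <- seq_len(floor(n / 2))         # frequency bins j/n, period n/j
  jlo <- max(1, ceiling(n / l_max))
  jhi <- floor(n / l_min)
  if (jlo > jhi || jhi < 1) stop("no frequency bin maps into the period range")
  j <- j[j >= jlo & j <= jhi]
  pow <- pw[j + 1]
  if (all(pow <= 0)) stop("no spectral peak in the period range")
  sel_j <- integer(0); sel_p <- numeric(0)
  avail <- rep(TRUE, length(j))
  while (length(sel_j) < k && any(avail & pow > 0)) {
    # an exact event comb has (near-)equal power at all harmonics, so among
    # near-tied maxima take the lowest frequency: the fundamental, whose
    # inverse is the prime period rather than a sub-multiple
    mx <- max(pow[avail])
    i <- which(avail & pow >= 0.9 * mx)[1]
    sel_j <- c(sel_j, j[i]); sel_p <- c(sel_p, pow[i])
    avail[abs(j - j[i]) <= 1] <- FALSE   # exclude the peak and +/- 1 bin
  }
  if (length(sel_j) < k) {
    # pad with the next-highest remaining bins
    warning("fewer isolated peaks than requested: padding with next bins")
    rest <- setdiff(order(-pow), match(sel_j, j))
    need <- k - length(sel_j)
    sel_j <- c(sel_j, j[utils::head(rest, need)])
    sel_p <- c(sel_p, pow[utils::head(rest, need)])
  }
  .baseline_result(method, round(n / sel_j), sel_p)
}

#' Periodogram baseline on the binary series
#'
#' Mean-removed binary series, raw periodogram, top-k peaks among
#' frequencies whose period lies in \code{[l_min, l_max]} (peaks exclude
#' their +/- 1 neighbouring bins); periods are the rounded inverse
#' frequencies.
#'
#' @param series an \code{\link{event_series}}.
#' @param k number of periods to return (the number of true periodicities,
#'   in benchmarks).
#' @param l_min,l_max period search range.
#' @return a \code{baseline_result} with \code{periods} and \code{scores}.
#' @export
fft_periods <- function(series, k = 1, l_min = 10, l_max = 350) {
  stopifnot(inherits(series, "event_series"), k >= 1)
  if (series$n_t < 2 * l_min) stop("insufficient data for spectral analysis")
  .spectral_peaks(as_binary(series), k, l_min, l_max, "fft")
}

#' Periodogram of the autocorrelation function
#'
#' Computes the full-length linear autocorrelation of the binary series
#' (via FFT) and takes the periodogram of that sequence; integer multiples
#' of a period share ACF peaks, which the spectrum folds back onto the
#' fundamental. Using all lags keeps the frequency resolution of the raw
#' periodogram, so long periods remain resolvable.
#'
#' @inheritParams fft_periods
#' @export
acf_fft_periods <- function(series, k = 1, l_min = 10, l_max = 350) {
  stopifnot(inherits(series, "event_series"), k >= 1)
  if (series$n_t < 2 * l_min) stop("insufficient data for spectral analysis")
  x <- as_binary(series)
  x <- x - mean(x)
  n <- length(x)
  # linear autocovariance by zero-padded FFT (Wiener-Khinchin)
  pad <- c(x, numeric(n))
  a <- Re(stats::fft(Mod(stats::fft(pad))^2, inverse = TRUE))[1:n] / (2 * n)
  .spectral_peaks(a, k, l_min, l_max, "acf_fft")
}

#' Periodogram of the inter-event interval histogram
#'
#' Applies the periodogram to \code{D(1..max_lag)}, the all-order forward
#' interval histogram, whose peaks at a period and its multiples form a
#' comb.
#'
#' @param hist an \code{\link{interval_counts}} histogram.
#' @inheritParams fft_periods
#' @export
hist_fft_periods <- function(hist, k = 1, l_min = 10, l_max = 350) {
  stopifnot(inherits(hist, "interval_histogram"), k >= 1)
  .spectral_peaks(hist$counts, k, l_min, l_max, "hist_fft")
}

#' E-periodicity baseline (modulus folding)
#'
#' For every integer candidate period p the discrepancy score is the number
#' of event pairs whose interval equals an integer multiple of p within
#' +/- 1, normalized by the number of whole periods in the observed span.
#' The top-k periods are returned, suppressing integer multiples (within
#' +/- 1) of already-selected periods.
#'
#' @inheritParams fft_periods
#' @export
e_periodicity_periods <- function(series, k = 1, l_min = 10, l_max = 350) {
  stopifnot(inherits(series, "event_series"), k >= 1)
  s <- series$timestamps
  if (length(s) < 2) stop("need at least two events")
  span <- max(s) - min(s)
  if (span < l_min) stop("series span below the period range")
  h <- interval_counts(series, max_lag = span)
  d <- c(h$counts, 0)  # sentinel for mp + 1 == span + 1
  ps <- seq.int(l_min, min(l_max, span))
  scores <- vapply(ps, function(p) {
    m <- seq_len(span %/% p)
    ctr <- m * p
    hits <- d[ctr] + ifelse(ctr > 1, d[pmax(ctr - 1, 1)], 0) + d[ctr + 1]
    sum(hits) / max(1, span %/% p)
  }, numeric(1))
  sel <- integer(0); sel_s <- numeric(0)
  avail <- rep(TRUE, length(ps))
  while (length(sel) < k && any(avail)) {
    i <- which(avail)[which.max(scores[avail])]
    p <- ps[i]
    sel <- c(sel, p); sel_s <- c(sel_s, scores[i])
    r <- ps %% p
    avail[r <= 1 | r >= p - 1] <- FALSE  # p and its near-multiples
    avail[i] <- FALSE
  }
  .baseline_result("e_periodicity", sel, sel_s)
}
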