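# S3 methods for fitted "gmpda" objects.

#' @export
print.gmpda <- function(x, ...) {
  cat(sprintf("Gaussian mixture periodicity fit (%s model)\n", x$model))
  if (length(x$periods) == 0) {
    cat("  No periodicity detected.\n")
  } else {
    cat("  periods:", paste(x$periods, collapse = ", "), "\n")
    cat("  sigmas: ", paste(signif(x$sigmas, 4), collapse = ", "), "\n")
    cat(sprintf("  loss:    %.4f\n", x$loss))
  }
  invisible(x)
}

#' @export
summary.gmpda <- function(object, ...) {
  out <- list(model = object$model,
              n_events = length(object$events$timestamps),
              n_t = object$events$n_t,
              periods = object$periods, sigmas = object$sigmas,
              loss = object$loss, z_hat = object$z_hat,
              candidates = object$candidates,
              config = object$config)
  class(out) <- "summary.gmpda"
  out
}

#' @export
print.summary.gmpda <- function(x, ...) {
  cat(sprintf("Gaussian mixture periodicity fit (%s model)\n", x$model))
  cat(sprintf("  %d events on [0, %d]\n", x$n_events, x$n_t))
  cat(sprintf("  interaction level z_hat = %.3f\n", x$z_hat))
  cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  if (length(x$periods) == 0) {
    cat("  No periodicity detected.\n")
  } else {
    tab <- data.frame(period = x$periods, sigma = signif(x$sigmas, 4))
    print(tab, row.names = FALSE)
    cat(sprintf("  loss: %.4f  (0 = perfect shape match, 2 = disjoint)\n",
                x$loss))
  }
  invisible(x)
}

#' @export
coef.gmpda <- function(object, ...) {
  cbind(period = object$periods, sigma = object$sigmas)
}

#' Expected interval-count curve of a fitted model
#'
#' @param object a fitted \code{\link{gmpda}} object with at least one
#'   detected period.
#' @param lags lags at which to evaluate; defaults to the fitted window.
#' @param ... unused.
#' @return numeric vector of expected counts.
#' @export
predict.gmpda <- function(object, lags = NULL, ...) {
  if (length(object$periods) == 0) stop("no periodicity was detected")
  if (is.null(lags)) lags <- seq_along(object$cleaned)
  mixture_curve(lags, object$model, object$periods, object$sigmas,
                object$events$n_t)
}

#' @export
residuals.gmpda <- function(object, ...) {
  if (length(object$periods) == 0 || is.null(object$cleaned)) {
    stop("no fitted curve available")
  }
  w <- seq.int(object$config$l_min, length(object$cleaned))
  obs <- object$cleaned[w]
  exp_ <- predict(object, w)
  obs / sum(obs) - exp_ / sum(exp_)
}

#' Simulate event series from a fitted periodicity model
#'
#' Draws new series from the generative scheme at the fitted periods and
#' sigmas, with the observed noise proportion.
#'
#' @param object a fitted \code{\link{gmpda}} object.
#' @param nsim number of series.
#' @param seed integer seed.
#' @param events_per_period events per periodicity; default matches the
#'   observed event count per fitted period.
#' @param ... unused.
#' @return list of \code{\link{event_series}} (an \code{event_series} when
#'   \code{nsim = 1}).
#' @export
simulate.gmpda <- function(object, nsim = 1, seed = 1L,
                           events_per_period = NULL, ...) {
  if (length(object$periods) == 0) stop("no periodicity was detected")
  if (is.null(events_per_period)) {
    events_per_period <- max(2, round(object$events$n_t /
                                        min(object$periods)))
  }
  out <- lapply(seq_len(nsim), function(i) {
    simulate_events(generative_spec(
      model = object$model, periods = object$periods,
      sigmas = object$sigmas, beta = 0,
      events_per_period = events_per_period,
      seed = as.integer(seed) + i - 1L))
  })
  if (nsim == 1) out[[1]] else out
}

#' Plot a fitted periodicity model over the interval histogram
#'
#' Shows the cleaned interval histogram together with the fitted mixture
#' curve (rescaled to the histogram mass) and marks the detected periods.
#'
#' @param x a fitted \code{\link{gmpda}} object.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.gmpda <- function(x, ...) {
  if (is.null(x$cleaned)) stop("nothing to plot: empty fit")
  lags <- seq_along(x$cleaned)
  graphics::plot(lags, x$cleaned, type = "h", col = "grey60",
                 xlab = "lag", ylab = "interval count (noise-subtracted)",
                 main = sprintf("%s mixture fit", x$model), ...)
  if (length(x$periods) > 0) {
    g <- predict(x, lags)
    if (sum(g) > 0) {
      graphics::lines(lags, g * sum(x$cleaned) / sum(g), col = "firebrick",
                      lwd = 2)
    }
    graphics::abline(v = x$periods, col = "steelblue", lty = 2)
  }
  invisible(x)
}
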