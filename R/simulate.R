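#' Generative specification for periodic event series
#'
#' Parameters of the generative scheme \code{S = f(mu, sigma, beta, alpha, M)}
#' producing event timestamps from \code{P} overlapping periodicities plus
#' uniform false-positive noise.
#'
#' Two model schemes are supported. Under the \emph{clock} model events are
#' placed at \code{alpha_p + i * mu_p + eps}, \code{eps ~ N(0, sigma_p^2)}:
#' the jitter of an event does not propagate, as in pacemaker-driven systems.
#' Under the \emph{random walk} model each event is offset from the previous
#' one by \code{mu_p + eps}: jitter accumulates, so the variance of the
#' m-step interval grows linearly in \code{m} (Markov, pacemaker-free
#' systems).
#'
#' @param model \code{"clock"} or \code{"random_walk"}.
#' @param periods numeric vector of true periods \code{mu_p > 0}, one per
#'   periodicity.
#' @param sigmas numeric vector of interval standard deviations
#'   \code{sigma_p >= 0} (recycled to the length of \code{periods}).
#' @param alphas integer start offsets \code{alpha_p >= 0} (recycled;
#'   default 0).
#' @param beta false-positive rate: \code{round(beta * n_periodic)} noise
#'   events are drawn uniformly on \code{[0, n_t]}. \code{beta = 2} means a
#'   signal-to-noise ratio of 1:2.
#' @param events_per_period number of events generated per periodicity.
#' @param seed integer seed making the simulation reproducible.
#' @return An object of class \code{"generative_spec"}.
#' @seealso \code{\link{simulate_events}}, \code{\link{build_test_grid}}
#' @export
generative_spec <- function(model = c("clock", "random_walk"),
                            periods,
                            sigmas = 0,
                            alphas = 0,
                            beta = 0,
                            events_per_period = 100,
                            seed = 1L) {
  model <- match.arg(model)
  periods <- as.numeric(periods)
  p <- length(periods)
  if (p < 1) stop("at least one period is required")
  sigmas <- rep_len(as.numeric(sigmas), p)
  alphas <- rep_len(as.numeric(alphas), p)
  bad <- function(v) any(!is.finite(v))
  if (bad(periods) || bad(sigmas) || bad(alphas) ||
      !is.finite(beta) || !is.finite(events_per_period)) {
    stop("invalid spec: non-finite parameter")
  }
  if (any(periods <= 0) || any(sigmas < 0) || any(alphas < 0) || beta < 0) {
    stop("invalid spec: negative parameter")
  }
  if (events_per_period < 1) stop("events_per_period must be >= 1")
  structure(list(model = model, periods = periods, sigmas = sigmas,
                 alphas = alphas, beta = beta,
                 events_per_period = as.integer(events_per_period),
                 seed = as.integer(seed)),
            class = "generative_spec")
}

#' @export
print.generative_spec <- function(x, ...) {
  cat(sprintf("Generative spec [%s]: mu = (%s), sigma = (%s), beta = %g, n = %d\n",
              x$model, paste(signif(x$periods, 4), collapse = ", "),
              paste(signif(x$sigmas, 4), collapse = ", "),
              x$beta, x$events_per_period))
  invisible(x)
}

# periodic timestamps for one periodicity, before rounding
.periodic_draw <- function(model, mu, sigma, alpha, n) {
  i <- seq_len(n)
  if (sigma == 0) {
    return(alpha + i * mu)
  }
  eps <- stats::rnorm(n, 0, sigma)
  if (model == "clock") {
    alpha + i * mu + eps
  } else {
    # random walk: i.i.d. N(mu, sigma^2) increments accumulated from alpha
    alpha + cumsum(mu + eps)
  }
}

#' Simulate an event series from a generative specification
#'
#' Draws \code{events_per_period} events for every periodicity according to
#' the model scheme, sets the series length \code{n_t} to the largest
#' periodic timestamp, then unions in \code{round(beta * n_periodic)} noise
#' timestamps drawn uniformly on \code{[0, n_t]}. Timestamps are rounded to
#' integers; duplicates (including noise landing on periodic events) are
#' collapsed.
#'
#' @param spec a \code{\link{generative_spec}}.
#' @return an \code{\link{event_series}}.
#' @examples
#' simulate_events(generative_spec("clock", periods = 50, sigmas = 0,
#'                                 events_per_period = 5))$timestamps
#' @export
simulate_events <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  periodic <- unlist(lapply(seq_along(spec$periods), function(p) {
    .periodic_draw(spec$model, spec$periods[p], spec$sigmas[p],
                   spec$alphas[p], spec$events_per_period)
  }))
  periodic <- round(periodic)
  periodic <- periodic[periodic >= 0]
  if (length(periodic) == 0 || max(periodic) < 1) {
    stop("degenerate series: all events collapse at or below zero")
  }
  n_t <- max(periodic)
  n_noise <- round(spec$beta * length(periodic))
  noise <- if (n_noise > 0) round(stats::runif(n_noise, 0, n_t)) else numeric(0)
  ts <- sort(unique(c(periodic, noise)))
  if (length(ts) < 2) {
    stop("degenerate series: fewer than two distinct timestamps")
  }
  event_series(ts, n_t = n_t)
}
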