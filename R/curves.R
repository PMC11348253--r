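#' Parametric expected interval-count curve of a Gaussian mixture model
#'
#' Evaluates, at integer lags, the expected all-order interval histogram
#' implied by periods \code{mu} and interval standard deviations
#' \code{sigma} under one of the two generative schemes. Per period the
#' curve is a comb of Gaussian components at multiples \code{m * mu}, each
#' weighted by the expected number of order-m intervals
#' \code{c_m = n_t / mu - (m - 1)} (floored at 0). Component variance is
#' \code{sigma^2} for the clock model and \code{m * sigma^2} for the random
#' walk model, whose m-step variance grows linearly.
#'
#' Components are evaluated while \code{m * mu} lies within four component
#' standard deviations of the largest requested lag; farther components
#' contribute negligibly.
#'
#' @param lags integer lags at which to evaluate.
#' @param model \code{"clock"} or \code{"random_walk"}.
#' @param mu,sigma numeric vectors (one entry per periodicity). A zero
#'   sigma is replaced by 0.5 (sub-sample resolution) with a warning.
#' @param n_t series length, which sets the component weights.
#' @return numeric vector of expected counts, same length as \code{lags}.
#' @examples
#' # peak height at the period: c_1 * dnorm(0) = 4 / sqrt(2 * pi)
#' mixture_curve(100, "clock", mu = 100, sigma = 1, n_t = 400)
#' @export
mixture_curve <- function(lags, model = c("clock", "random_walk"),
                          mu, sigma, n_t) {
  model <- match.arg(model)
  stopifnot(length(mu) == length(sigma), all(mu > 0), n_t >= 1)
  if (any(sigma == 0)) {
    warning("sigma = 0 replaced by 0.5 (sub-sample resolution)")
    sigma[sigma == 0] <- 0.5
  }
  top <- max(lags)
  out <- numeric(length(lags))
  for (p in seq_along(mu)) {
    m_hi <- if (model == "clock") {
      (top + 4 * sigma[p]) / mu[p]
    } else {
      # largest m with m * mu - 4 * sigma * sqrt(m) <= top
      ((4 * sigma[p] + sqrt(16 * sigma[p]^2 + 4 * mu[p] * top)) /
         (2 * mu[p]))^2
    }
    m <- seq_len(max(1, floor(m_hi) + 1L))
    w <- pmax(n_t / mu[p] - (m - 1), 0)
    keep <- w > 0
    m <- m[keep]; w <- w[keep]
    if (length(m) == 0) next
    sd_m <- if (model == "clock") rep(sigma[p], length(m)) else
      sigma[p] * sqrt(m)
    keep <- m * mu[p] <= top + 4 * sd_m
    m <- m[keep]; w <- w[keep]; sd_m <- sd_m[keep]
    for (k in seq_along(m)) {
      out <- out + w[k] * stats::dnorm(lags, m[k] * mu[p], sd_m[k])
    }
  }
  out
}

#' L1 loss between a cleaned histogram and a mixture curve
#'
#' Both arguments are normalized to unit sum over the window before the
#' absolute differences are summed, making the loss scale-free on
#' \code{[0, 2]}: 0 for identical shapes, 2 for disjoint support. Lower is
#' better.
#'
#' @param observed cleaned (noise-subtracted) histogram on the loss window.
#' @param expected mixture curve on the same window (see
#'   \code{\link{mixture_curve}}).
#' @return numeric loss in \code{[0, 2]}; \code{NA} with a warning when the
#'   observed histogram is all zero (no usable intervals).
#' @export
gmpda_loss <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  so <- sum(observed)
  se <- sum(expected)
  if (so <= 0) {
    warning("all-zero histogram: loss undefined")
    return(NA_real_)
  }
  if (se <= 0) return(2)
  sum(abs(observed / so - expected / se))
}
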