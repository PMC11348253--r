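#' Detector configuration
#'
#' Tuning parameters of the periodicity detector. Defaults are the
#' simulation-benchmark settings; \code{sleep_bout_config()} gives the preset used
#' for sleep-bout data (leg-movement recordings).
#'
#' @param model generative scheme fitted to the interval histogram:
#'   \code{"random_walk"} (variance of the m-step interval grows linearly
#'   in m) or \code{"clock"} (constant variance).
#' @param l_min,l_max smallest / largest period searched (samples).
#' @param loss_length largest lag entering the histogram and the loss.
#' @param max_periods maximal number of periodicities reported.
#' @param max_candidates maximal number of candidate periods retained.
#' @param max_iterations sweeps of the candidate search, each subtracting
#'   the best-explained comb before re-scoring.
#' @param noise_range sub-periodic lag window (must be below \code{l_min})
#'   used to estimate the interaction-curve level.
#' @param loss_tol_change minimal loss decrease required before an
#'   additional periodicity is accepted.
#' @param curve_fit logical: refine sigma per candidate by least squares?
#' @param sigma_init initial interval standard deviation; \code{NULL} means
#'   \code{floor(log(l_min))} (at least 0.5).
#' @return list of class \code{"gmpda_config"}.
#' @export
gmpda_config <- function(model = c("random_walk", "clock"),
                         l_min = 5L,
                         l_max = 350L,
                         loss_length = 400L,
                         max_periods = 5L,
                         max_candidates = 15L,
                         max_iterations = 5L,
                         noise_range = 5L,
                         loss_tol_change = 0.01,
                         curve_fit = TRUE,
                         sigma_init = NULL) {
  model <- match.arg(model)
  if (!(noise_range <= l_min && l_min <= l_max && l_max <= loss_length)) {
    stop("need noise_range <= l_min <= l_max <= loss_length")
  }
  if (noise_range < 1) stop("noise_range must be >= 1")
  if (max_periods < 1) stop("max_periods must be >= 1")
  if (is.null(sigma_init)) sigma_init <- max(0.5, floor(log(l_min)))
  structure(list(model = model, l_min = as.integer(l_min),
                 l_max = as.integer(l_max),
                 loss_length = as.integer(loss_length),
                 max_periods = as.integer(max_periods),
                 max_candidates = as.integer(max_candidates),
                 max_iterations = as.integer(max_iterations),
                 noise_range = as.integer(noise_range),
                 loss_tol_change = loss_tol_change,
                 curve_fit = isTRUE(curve_fit),
                 sigma_init = sigma_init),
            class = "gmpda_config")
}

#' @rdname gmpda_config
#' @param ... overrides passed to \code{gmpda_config}.
#' @export
sleep_bout_config <- function(...) {
  defaults <- list(l_min = 5L, l_max = 200L, loss_length = 400L,
                   max_periods = 5L, max_candidates = 15L,
                   max_iterations = 5L, noise_range = 5L,
                   loss_tol_change = 0.1, curve_fit = TRUE)
  do.call(gmpda_config, utils::modifyList(defaults, list(...)))
}
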