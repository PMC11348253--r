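# Accuracy scoring and benchmark execution.

#' Half-sigma correctness criterion
#'
#' A detected period is correct when it lies within
#' \code{mu_true +/- 0.5 * sigma_true}; with \code{sigma_true = 0} the
#' prediction must match the rounded truth exactly. E.g. for truth 350 with
#' sigma 44 any guess in 350 +/- 22 counts as correct.
#'
#' @param mu_pred predicted period (integer).
#' @param mu_true,sigma_true generative truth.
#' @return logical.
#' @export
is_correct <- function(mu_pred, mu_true, sigma_true) {
  stopifnot(sigma_true >= 0)
  if (sigma_true == 0) return(mu_pred == round(mu_true))
  abs(mu_pred - mu_true) <= 0.5 * sigma_true
}

#' Count correctly detected periodicities
#'
#' Greedy one-to-one matching, closest pair first: each truth is matched to
#' at most one prediction, so two near-identical predictions cannot both
#' claim the same true period.
#'
#' @param pred integer vector of predicted periods.
#' @param truths data.frame (or matrix) with columns \code{mu} and
#'   \code{sigma}, one row per true periodicity.
#' @return number of truths matched by a correct prediction.
#' @export
score_estimate <- function(pred, truths) {
  truths <- as.data.frame(truths)
  if (length(pred) == 0 || nrow(truths) == 0) return(0L)
  d <- abs(outer(pred, truths$mu, "-"))
  hits <- 0L
  while (length(d) > 0 && is.matrix(d) && nrow(d) > 0 && ncol(d) > 0) {
    ij <- arrayInd(which.min(d), dim(d))
    i <- ij[1]; j <- ij[2]
    if (is_correct(pred[i], truths$mu[j], truths$sigma[j])) hits <- hits + 1L
    pred <- pred[-i]; truths <- truths[-j, , drop = FALSE]
    if (length(pred) == 0 || nrow(truths) == 0) break
    d <- abs(outer(pred, truths$mu, "-"))
  }
  hits
}

# run one algorithm on one simulated series; returns matched-truth count
.run_algorithm <- function(algorithm, series, spec, l_min, l_max,
                           loss_length) {
  p <- length(spec$periods)
  truths <- data.frame(mu = spec$periods, sigma = spec$sigmas)
  pred <- tryCatch(switch(
    algorithm,
    gmpda = ,
    gmpda_nocf = {
      cfg <- gmpda_config(model = spec$model, l_min = l_min, l_max = l_max,
                          loss_length = loss_length,
                          max_periods = p + 2L,
                          curve_fit = (algorithm == "gmpda"),
                          sigma_init = max(0.5, mean(spec$sigmas)))
      gmpda(series, config = cfg)$periods
    },
    fft = fft_periods(series, p, l_min, l_max)$periods,
    acf = acf_fft_periods(series, p, l_min, l_max)$periods,
    hist = {
      h <- interval_counts(series, min(loss_length, series$n_t - 1))
      hist_fft_periods(h, p, l_min, l_max)$periods
    },
    eper = e_periodicity_periods(series, p, l_min, l_max)$periods,
    stop("unknown algorithm: ", algorithm)
  ), error = function(e) integer(0))
  score_estimate(pred, truths)
}

#' Run a benchmark of detectors over a grid of generative specifications
#'
#' Simulates every spec, runs each algorithm, and aggregates the half-sigma
#' accuracy per cell (model, sigma rule, beta, number of events,
#' algorithm). The detector is given \code{max_periods = P + 2} and, in the
#' curve-fitting configuration (\code{"gmpda"}), the generative sigma as
#' the initial value; baselines receive \code{k = P}, the true number of
#' periodicities. Failures of an individual run count as accuracy 0 and
#' never abort the sweep.
#'
#' @param grid list of \code{\link{generative_spec}} (see
#'   \code{\link{build_test_grid}}).
#' @param algorithms subset of \code{c("gmpda", "gmpda_nocf", "fft",
#'   "acf", "hist", "eper")}.
#' @param l_min,l_max period search range for all algorithms.
#' @param loss_length histogram / loss window length.
#' @return data.frame with one row per (cell, algorithm): \code{model},
#'   \code{sigma_rule}, \code{beta}, \code{n}, \code{algorithm},
#'   \code{reps}, \code{accuracy}.
#' @export
run_benchmark <- function(grid, algorithms = "gmpda",
                          l_min = 10, l_max = 350, loss_length = 400) {
  stopifnot(length(grid) >= 1)
  rows <- list()
  for (alg in algorithms) {
    hits <- list(); tot <- list()
    for (sp in grid) {
      key <- paste(sp$model, attr(sp, "sigma_rule") %||% NA, sp$beta,
                   sp$events_per_period, sep = "\r")
      series <- tryCatch(simulate_events(sp), error = function(e) NULL)
      h <- if (is.null(series)) 0L else {
        .run_algorithm(alg, series, sp, l_min, l_max, loss_length)
      }
      hits[[key]] <- (hits[[key]] %||% 0L) + h
      tot[[key]] <- (tot[[key]] %||% 0L) +
        c(length(sp$periods), 1L)  # truths, reps
    }
    for (key in names(hits)) {
      f <- strsplit(key, "\r", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        model = f[1], sigma_rule = f[2], beta = as.numeric(f[3]),
        n = as.integer(f[4]), algorithm = alg,
        reps = tot[[key]][2],
        accuracy = hits[[key]] / tot[[key]][1],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference loss on non-periodic series
#'
#' Builds the null distribution of the detector loss on series whose events
#' are uniformly distributed (no periodic structure), over a grid of event
#' counts and series lengths, and returns a low quantile of the pooled
#' losses. Observed losses below this reference are called significant
#' periodicities.
#'
#' @param event_counts,lengths grids of event counts and series lengths;
#'   defaults are the sleep-bout calibration grid.
#' @param reps series per (count, length) combination.
#' @param quantile_p quantile of the pooled loss distribution (default
#'   0.01).
#' @param cfg detector configuration (default \code{\link{sleep_bout_config}()}).
#' @param seed integer seed.
#' @return the loss quantile (numeric scalar), with the pooled losses
#'   attached as attribute \code{"losses"}.
#' @export
reference_loss <- function(event_counts = c(10, 30, 50, 100, 200, 400),
                           lengths = c(500, 1000, 2000, 4000, 8000, 16000),
                           reps = 100,
                           quantile_p = 0.01,
                           cfg = sleep_bout_config(),
                           seed = 1L) {
  stopifnot(quantile_p > 0, quantile_p <= 1, reps >= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  losses <- numeric(0)
  for (n in event_counts) {
    for (len in lengths) {
      for (r in seq_len(reps)) {
        ts <- unique(round(stats::runif(n, 1, len)))
        if (length(ts) < 2) next
        fit <- suppressWarnings(
          gmpda(event_series(ts, n_t = len), config = cfg))
        if (is.finite(fit$loss)) losses <- c(losses, fit$loss)
      }
    }
  }
  if (length(losses) == 0) stop("no finite losses collected")
  out <- unname(stats::quantile(losses, quantile_p))
  attr(out, "losses") <- losses
  out
}
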