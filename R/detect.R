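# Candidate search, sigma refinement and combinatorial period selection.

# comb-fold score of every lag q in [l_min, l_max]: background-corrected
# residual mass within +/- w(q) of each multiple m*q inside the window
# (smoothing half-width w(q) = max(1, round(log(q)))), summed over the K
# multiples and scaled by 1/sqrt(K). The sum part ranks a prime above its
# integer multiples (which capture only part of the comb's mass); the
# 1/sqrt(K) part ranks it above its subharmonics (which spread the same
# mass over empty extra windows); the background correction keeps flat
# noise from favouring short lags with many windows.
.comb_scores <- function(res, l_min, l_max) {
  n <- length(res)
  cs <- cumsum(c(0, res))
  wsum <- function(a, b) cs[pmin(b, n) + 1] - cs[pmax(a, 1) - 1 + 1]
  bg <- mean(res)
  qs <- seq.int(l_min, min(l_max, n))
  vapply(qs, function(q) {
    w <- max(1, round(log(q)))
    m <- seq_len(n %/% q)
    centers <- m * q
    width <- pmin(centers + w, n) - pmax(centers - w, 1) + 1
    sum(wsum(centers - w, centers + w) - width * bg) / sqrt(length(m))
  }, numeric(1))
}

#' Candidate period extraction by comb folding
#'
#' Scores every integer lag in \code{[l_min, l_max]} by folding the cleaned
#' histogram over its multiples (mass near \code{m * q}, averaged over the
#' multiples inside the window, with a log-width smoothing window). The
#' best-scoring lag is accepted, its fitted single-period comb subtracted
#' (clipped at 0), and the fold recomputed, for up to \code{max_iterations}
#' sweeps; remaining candidate slots are filled from the initial ranking.
#' Averaging over multiples and iterative subtraction both counteract the
#' classic confusion of a prime period with its integer multiples.
#'
#' @param cleaned denoised histogram over lags \code{1..max_lag}.
#' @param cfg a \code{\link{gmpda_config}}.
#' @param n_t series length (sets comb weights during subtraction).
#' @return integer vector of up to \code{max_candidates} candidate periods,
#'   strongest first; empty when the histogram is flat.
#' @export
find_candidates <- function(cleaned, cfg, n_t) {
  n <- length(cleaned)
  if (n < cfg$l_min || sum(cleaned) <= 0) return(integer(0))
  l_max <- min(cfg$l_max, n)
  qs <- seq.int(cfg$l_min, l_max)
  scores0 <- .comb_scores(cleaned, cfg$l_min, l_max)
  accepted <- integer(0)
  res <- cleaned
  for (it in seq_len(cfg$max_iterations)) {
    sc <- if (it == 1) scores0 else .comb_scores(res, cfg$l_min, l_max)
    sc[qs %in% accepted] <- -Inf
    best <- which.max(sc)  # ties break toward the smaller lag
    if (!is.finite(sc[best]) || sc[best] <= 0) break
    q <- qs[best]
    accepted <- c(accepted, q)
    if (length(accepted) >= cfg$max_candidates) break
    g <- mixture_curve(seq_len(n), cfg$model, q, cfg$sigma_init, n_t)
    a <- sum(res * g) / sum(g * g)
    if (is.finite(a) && a > 0) res <- pmax(res - a * g, 0)
  }
  slots <- cfg$max_candidates - length(accepted)
  if (slots > 0) {
    ord <- order(-scores0, qs)  # score desc, smaller lag first on ties
    fill <- qs[ord]
    fill <- setdiff(fill, accepted)
    pos <- scores0[match(fill, qs)] > 0
    accepted <- c(accepted, utils::head(fill[pos], slots))
  }
  as.integer(accepted)
}

# sigma search interval for candidate period q: a refinement neighbourhood
# of the initial guess (a quarter to four times sigma_init), capped at q/2.
# An unconstrained upper bound lets a near-flat wide component win the
# normalized loss by soaking up residual background instead of the comb.
.sigma_bounds <- function(q, sigma_init) {
  lo <- max(0.5, sigma_init / 4)
  hi <- min(max(0.6, q / 2), max(1, sigma_init * 4))
  if (hi <= lo) hi <- lo + 0.1
  c(lo, hi)
}

# squared error of the best non-negative rescaling of the single-period
# curve against the residual histogram
.sigma_objective <- function(sig, q, cleaned, model, n_t) {
  g <- mixture_curve(seq_along(cleaned), model, q, sig, n_t)
  gg <- sum(g * g)
  if (gg <= 0) return(sum(cleaned^2))
  a <- max(0, sum(cleaned * g) / gg)
  sum((cleaned - a * g)^2)
}

#' Least-squares refinement of the interval standard deviations
#'
#' For each candidate period, searches sigma on \code{[0.5, mu / 2]} for the
#' value whose single-period comb best matches the cleaned histogram in
#' squared error (with a free non-negative amplitude, so mass belonging to
#' other periodicities does not bias the width). With \code{curve_fit}
#' disabled every candidate keeps \code{sigma_init}.
#'
#' @param cleaned denoised histogram over lags \code{1..max_lag}.
#' @param candidates integer candidate periods.
#' @param cfg a \code{\link{gmpda_config}}.
#' @param n_t series length.
#' @return numeric vector of sigma estimates, one per candidate.
#' @export
fit_sigmas <- function(cleaned, candidates, cfg, n_t) {
  stopifnot(length(candidates) >= 1)
  if (!cfg$curve_fit) {
    return(rep(cfg$sigma_init, length(candidates)))
  }
  vapply(candidates, function(q) {
    fit <- tryCatch(
      stats::optimize(.sigma_objective, .sigma_bounds(q, cfg$sigma_init),
                      q = q,
                      cleaned = cleaned, model = cfg$model, n_t = n_t),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) {
      warning("sigma fit failed for candidate ", q, "; using sigma_init")
      return(cfg$sigma_init)
    }
    fit$minimum
  }, numeric(1))
}

#' Combinatorial selection of the best period subset
#'
#' Evaluates the normalized L1 loss of the mixture curve for every subset of
#' the candidates of size 1 up to \code{max_periods}. The best subset of
#' size k+1 replaces the best of size k only when it lowers the loss by more
#' than \code{loss_tol_change}. When \code{curve_fit} is on, the sigmas of
#' the winning subset are refitted jointly (coordinate-wise, minimizing the
#' mixture loss) and the loss updated.
#'
#' @param cleaned denoised histogram over lags \code{1..max_lag}.
#' @param candidates integer candidate periods.
#' @param sigmas per-candidate sigma estimates.
#' @param cfg a \code{\link{gmpda_config}}.
#' @param n_t series length.
#' @return list with \code{periods}, \code{sigmas}, \code{loss},
#'   \code{model}, \code{candidates_considered}.
#' @export
select_best <- function(cleaned, candidates, sigmas, cfg, n_t) {
  stopifnot(length(candidates) >= 1, length(sigmas) == length(candidates))
  n <- length(cleaned)
  window <- seq.int(cfg$l_min, n)
  target <- cleaned[window]
  st <- sum(target)
  if (st <= 0) {
    return(list(periods = integer(0), sigmas = numeric(0), loss = NA_real_,
                model = cfg$model, candidates_considered = candidates))
  }
  tnorm <- target / st
  nc <- length(candidates)
  curves <- vapply(seq_len(nc), function(j) {
    mixture_curve(window, cfg$model, candidates[j], sigmas[j], n_t)
  }, numeric(length(window)))
  curves <- matrix(curves, nrow = length(window))

  best <- NULL
  for (k in seq_len(min(cfg$max_periods, nc))) {
    idx <- utils::combn(nc, k)
    Z <- matrix(0, nc, ncol(idx))
    Z[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = k))] <- 1
    M <- curves %*% Z
    s <- colSums(M)
    s[s <= 0] <- NA
    L <- colSums(abs(sweep(M, 2, s, "/") - tnorm))
    L[is.na(L)] <- 2
    j <- which.min(L)
    cand_k <- list(subset = idx[, j], loss = L[j])
    if (is.null(best)) {
      best <- cand_k
    } else if (cand_k$loss < best$loss - cfg$loss_tol_change) {
      best <- cand_k
    }
  }
  periods <- candidates[best$subset]
  sig <- sigmas[best$subset]
  loss <- best$loss

  if (cfg$curve_fit && length(periods) > 0) {
    # joint refinement: one coordinate-wise pass on the mixture loss
    for (p in seq_along(periods)) {
      obj <- function(sg) {
        s2 <- sig; s2[p] <- sg
        g <- mixture_curve(window, cfg$model, periods, s2, n_t)
        gmpda_loss(target, g)
      }
      fit <- tryCatch(
        stats::optimize(obj, .sigma_bounds(periods[p], cfg$sigma_init)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$objective) &&
          fit$objective <= loss) {
        sig[p] <- fit$minimum
        loss <- fit$objective
      }
    }
  }
  ord <- order(periods)
  list(periods = periods[ord], sigmas = sig[ord], loss = loss,
       model = cfg$model, candidates_considered = candidates)
}

#' Fit the Gaussian mixture periodicity model to an event series
#'
#' The full detection pipeline: build the all-order inter-event interval
#' histogram, estimate and subtract the uniform interaction curve, extract
#' candidate periods by comb folding, refine their variances by least
#' squares, and select the subset of periods minimizing the normalized L1
#' loss between histogram and mixture curve. Deterministic given the input
#' and configuration.
#'
#' @param x an \code{\link{event_series}}, or a numeric vector of
#'   timestamps.
#' @param model convenience override for \code{config$model}.
#' @param config a \code{\link{gmpda_config}}.
#' @param ... individual \code{\link{gmpda_config}} overrides
#'   (e.g. \code{l_min = 10}).
#' @return An object of class \code{"gmpda"}: the selected \code{periods}
#'   and \code{sigmas}, final \code{loss}, \code{model}, candidate list,
#'   noise level \code{z_hat}, the histogram and cleaned histogram, the
#'   configuration and the input series. Fewer than two events or no usable
#'   candidates give an empty estimate with \code{NA} loss.
#' @examples
#' s <- simulate_events(generative_spec("clock", 50, sigmas = 1,
#'                                      events_per_period = 100, seed = 7))
#' fit <- gmpda(s, model = "clock", l_min = 10)
#' fit$periods
#' @export
gmpda <- function(x, model = NULL, config = gmpda_config(), ...) {
  if (!inherits(x, "event_series")) x <- event_series(x)
  dots <- list(...)
  if (length(dots) > 0 || !is.null(model)) {
    fields <- utils::modifyList(unclass(config), dots)
    if (!is.null(model)) fields$model <- model
    config <- do.call(gmpda_config, fields)
  }
  out <- structure(list(periods = integer(0), sigmas = numeric(0),
                        loss = NA_real_, model = config$model,
                        candidates = integer(0), z_hat = NA_real_,
                        hist = NULL, cleaned = NULL,
                        config = config, events = x,
                        call = match.call()),
                   class = "gmpda")
  if (length(x$timestamps) < 2 || x$n_t <= config$l_min) return(out)
  hist <- interval_counts(x, config$loss_length)
  noise <- estimate_z(hist, min(config$noise_range, config$l_min - 1L),
                      config$l_min)
  cleaned <- denoise(hist, noise)
  out$hist <- hist
  out$cleaned <- cleaned
  out$z_hat <- noise$z_hat
  cand <- find_candidates(cleaned, config, x$n_t)
  out$candidates <- cand
  if (length(cand) == 0) return(out)
  sig <- fit_sigmas(cleaned, cand, config, x$n_t)
  sel <- select_best(cleaned, cand, sig, config, x$n_t)
  out$periods <- sel$periods
  out$sigmas <- sel$sigmas
  out$loss <- sel$loss
  out
}
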