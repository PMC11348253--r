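#' Resolve a sigma rule at a given period
#'
#' Benchmark variance levels are specified as rules relative to the drawn
#' period: \code{"1"}, \code{"log(mu)"}, \code{"mu/16"}, \code{"mu/8"},
#' \code{"mu/4"}, \code{"mu/3"}.
#'
#' @param rule character rule name.
#' @param mu period at which to resolve it.
#' @return numeric sigma value.
#' @export
resolve_sigma <- function(rule, mu) {
  switch(rule,
         "1"       = 1,
         "log(mu)" = log(mu),
         "mu/16"   = mu / 16,
         "mu/8"    = mu / 8,
         "mu/4"    = mu / 4,
         "mu/3"    = mu / 3,
         stop("unknown sigma rule: ", rule))
}

# draw P periods as integers in [10, 350] obeying the separation rule:
# pairwise differences must exceed log of the larger period involved
.draw_periods <- function(p, lo = 10, hi = 350) {
  repeat {
    mu <- sort(sample(lo:hi, p, replace = FALSE))
    if (p == 1) return(mu)
    ok <- TRUE
    for (a in seq_len(p - 1)) {
      for (b in seq((a + 1), p)) {
        if (abs(mu[a] - mu[b]) <= log(max(mu[a], mu[b]))) ok <- FALSE
      }
    }
    if (ok) return(mu)
  }
}

#' Build the benchmark grid of generative specifications
#'
#' Constructs the full factorial benchmark design for one generative model.
#' For single-period cases the factors are sigma rule (6 levels), number of
#' events (6), and noise rate beta (8); for two- and three-period cases 4
#' sigma rules, 4 event counts and 5 noise levels are used. Each cell is
#' replicated with freshly drawn random integer periods in [10, 350]
#' (multi-period draws obey the separation rule that periods differ by more
#' than \code{log} of the larger one). At the default 100 replicates this
#' yields 28,800 specs (single) and 8,000 (multi2 / multi3).
#'
#' @param kind \code{"single"}, \code{"multi2"} or \code{"multi3"}.
#' @param model generative model for every spec.
#' @param replicates specs per cell (default 100, the full design).
#' @param seed master seed; per-spec seeds are derived deterministically.
#' @return list of \code{\link{generative_spec}} objects; each carries
#'   attributes \code{sigma_rule} and \code{cell} for aggregation.
#' @export
build_test_grid <- function(kind = c("single", "multi2", "multi3"),
                            model = c("clock", "random_walk"),
                            replicates = 100,
                            seed = 1L) {
  kind <- match.arg(kind)
  model <- match.arg(model)
  if (kind == "single") {
    sig_rules <- c("1", "log(mu)", "mu/16", "mu/8", "mu/4", "mu/3")
    ns <- c(10, 30, 50, 100, 300, 500)
    betas <- c(0, 0.1, 0.5, 0.7, 1, 2, 4, 8)
    p <- 1
  } else {
    sig_rules <- c("1", "log(mu)", "mu/16", "mu/8")
    ns <- c(50, 100, 300, 500)
    betas <- c(0, 0.1, 0.5, 0.7, 1)
    p <- if (kind == "multi2") 2 else 3
  }
  cells <- expand.grid(sigma_rule = sig_rules, n = ns, beta = betas,
                       stringsAsFactors = FALSE)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  specs <- vector("list", nrow(cells) * replicates)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (r in seq_len(replicates)) {
      mu <- .draw_periods(p)
      sg <- vapply(mu, function(m) resolve_sigma(cells$sigma_rule[ci], m),
                   numeric(1))
      k <- k + 1L
      sp <- generative_spec(model = model, periods = mu, sigmas = sg,
                            beta = cells$beta[ci],
                            events_per_period = cells$n[ci],
                            seed = sample.int(.Machine$integer.max, 1))
      attr(sp, "sigma_rule") <- cells$sigma_rule[ci]
      attr(sp, "cell") <- ci
      specs[[k]] <- sp
    }
  }
  specs
}
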