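cfg10 <- function(model = "clock", ...) {
  gmpda_config(model = model, l_min = 10, ...)
}

cleaned_of <- function(s, cfg) {
  h <- interval_counts(s, min(cfg$loss_length, s$n_t - 1))
  denoise(h, estimate_z(h, min(cfg$noise_range, cfg$l_min - 1), cfg$l_min))
}

test_that("the comb fold ranks the prime period first, not its multiples", {
  cfg <- cfg10()
  s <- quick_series("clock", 50, 1, 300, seed = 13)
  cand <- find_candidates(cleaned_of(s, cfg), cfg, s$n_t)
  expect_equal(cand[1], 50)
  expect_false(cand[1] %in% c(100, 150))

  expect_identical(find_candidates(numeric(400), cfg, 1000), integer(0))
  expect_lte(length(cand), cfg$max_candidates)
})

test_that("both periods of a two-period series appear among top candidates", {
  cfg <- cfg10()
  ok <- 0
  for (seed in 1:20) {
    sp <- generative_spec("clock", c(60, 97), sigmas = c(1, 1),
                          events_per_period = 300, seed = seed)
    s <- simulate_events(sp)
    top4 <- utils::head(find_candidates(cleaned_of(s, cfg), cfg, s$n_t), 4)
    if (any(abs(top4 - 60) <= 1) && any(abs(top4 - 97) <= 1)) ok <- ok + 1
  }
  expect_gte(ok, 18)  # >= 90% recall
})

test_that("sigma fitting recovers the width of a known generative curve", {
  cfg <- cfg10()
  n_t <- 4000
  cleaned <- mixture_curve(1:400, "clock", 100, 3, n_t)
  sg <- fit_sigmas(cleaned, 100, cfg, n_t)
  expect_gte(sg, 2.7)
  expect_lte(sg, 3.3)

  # curve_fit off: every candidate keeps sigma_init = floor(log(l_min))
  cfg_off <- cfg10(curve_fit = FALSE)
  expect_equal(fit_sigmas(cleaned, c(50, 100, 150), cfg_off, n_t),
               rep(2, 3))
  # flat window: fall back to sigma_init
  expect_warning(sg0 <- fit_sigmas(numeric(400), 50, cfg, n_t),
                 regexp = NA)  # optimizer runs, no failure expected
  expect_true(is.finite(sg0))
})

test_that("subset selection keeps the prime and rejects redundant multiples", {
  cfg <- cfg10()
  s <- quick_series("clock", 50, 1, 300, seed = 3)
  cleaned <- cleaned_of(s, cfg)
  sel <- select_best(cleaned, c(50L, 100L), c(1, 1), cfg, s$n_t)
  expect_equal(sel$periods, 50L)

  one <- select_best(cleaned, 50L, 1, cfg, s$n_t)
  expect_equal(one$periods, 50L)
  expect_true(is.finite(one$loss))
})

test_that("two random-walk periods are jointly recovered", {
  ok <- 0
  for (seed in 1:20) {
    mu <- c(60, 97)
    sp <- generative_spec("random_walk", mu, sigmas = log(mu),
                          events_per_period = 300, seed = seed)
    fit <- gmpda(simulate_events(sp), model = "random_walk", l_min = 10,
                 max_periods = 4, sigma_init = mean(log(mu)))
    hit <- score_estimate(fit$periods,
                          data.frame(mu = mu, sigma = log(mu)))
    if (hit == 2) ok <- ok + 1
  }
  expect_gte(ok, 16)  # >= 80%
})

test_that("detection is exact on noiseless data and fully deterministic", {
  s <- quick_series("clock", 50, 0, 100)
  fit <- suppressWarnings(gmpda(s, model = "clock", l_min = 10))
  expect_equal(fit$periods, 50L)

  s2 <- quick_series("random_walk", 123, log(123), 300, beta = 1, seed = 5)
  f1 <- gmpda(s2, model = "random_walk", l_min = 10)
  f2 <- gmpda(s2, model = "random_walk", l_min = 10)
  expect_identical(f1$periods, f2$periods)
  expect_identical(f1$loss, f2$loss)
  # permutation safety: timestamp order cannot matter
  shuffled <- event_series(sample(s2$timestamps), n_t = s2$n_t)
  f3 <- gmpda(shuffled, model = "random_walk", l_min = 10)
  expect_identical(f1$periods, f3$periods)
})

test_that("degenerate inputs give an empty estimate, not an error", {
  fit <- gmpda(event_series(5, n_t = 100), model = "clock")
  expect_length(fit$periods, 0)
  expect_true(is.na(fit$loss))
  fit2 <- suppressWarnings(gmpda(event_series(c(3, 4), n_t = 2000),
                                 model = "clock", l_min = 10))
  expect_length(fit2$periods, 0)
})

test_that("the selected period is never an integer multiple of the truth", {
  set.seed(61)
  for (rep in 1:15) {
    mu <- sample(15:170, 1)
    s <- quick_series("clock", mu, 0, 80, seed = sample.int(1e6, 1))
    fit <- suppressWarnings(gmpda(s, model = "clock", l_min = 10))
    expect_length(fit$periods, 1)
    expect_false(fit$periods %in% (mu * 2:10))
    expect_equal(fit$periods, mu)
  }
})

test_that("fitted model methods are coherent", {
  s <- quick_series("random_walk", 50, 2, 200, seed = 2)
  fit <- gmpda(s, model = "random_walk", l_min = 10)
  expect_s3_class(fit, "gmpda")
  expect_output(print(fit), "periods")
  expect_output(print(summary(fit)), "candidates")
  cf <- coef(fit)
  expect_equal(colnames(cf), c("period", "sigma"))
  expect_equal(unname(cf[, "period"]), as.numeric(fit$periods))
  r <- residuals(fit)
  expect_equal(length(r), length(fit$cleaned) - fit$config$l_min + 1)
  expect_lt(sum(abs(r)), 2 + 1e-12)
  sim <- simulate(fit, seed = 9)
  expect_s3_class(sim, "event_series")
  refit <- gmpda(sim, model = "random_walk", l_min = 10)
  expect_true(any(abs(refit$periods - fit$periods[1]) <= 2))
})
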