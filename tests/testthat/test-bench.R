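test_that("half-sigma criterion matches the worked boundary cases", {
  expect_true(is_correct(372, 350, 44))
  expect_false(is_correct(373, 350, 44))
  expect_true(is_correct(16, 15, 2))
  expect_false(is_correct(17, 15, 2))
  expect_true(is_correct(100, 100, 0))
  expect_false(is_correct(101, 100, 0))
})

test_that("scoring matches predictions to truths one-to-one", {
  truths <- data.frame(mu = c(60, 97), sigma = c(2, 3))
  expect_equal(score_estimate(c(60, 97), truths), 2L)
  expect_equal(score_estimate(c(60, 61), truths), 1L)  # no double counting
  expect_equal(score_estimate(integer(0), truths), 0L)
  expect_equal(score_estimate(c(97, 60), truths), 2L)  # order-free
  expect_equal(score_estimate(c(55, 200), truths), 0L)
})

test_that("benchmark aggregates accuracy per cell and never aborts", {
  grid <- build_test_grid("single", "clock", replicates = 2, seed = 3)
  # restrict to a corner of the design to keep the sweep small
  keep <- vapply(grid, function(sp) {
    attr(sp, "sigma_rule") %in% c("1") && sp$beta %in% c(0, 1) &&
      sp$events_per_period %in% c(50, 100)
  }, logical(1))
  res <- run_benchmark(grid[keep], algorithms = c("gmpda", "hist"))
  expect_s3_class(res, "data.frame")
  expect_setequal(res$algorithm, c("gmpda", "hist"))
  expect_equal(nrow(res), 2 * 2 * 2)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_true(all(res$reps == 2))
})

test_that("noiseless clock cells are detected perfectly", {
  set.seed(5)
  specs <- lapply(1:6, function(i) {
    mu <- sample(15:300, 1)
    sp <- generative_spec("clock", mu, sigmas = 0, beta = 0,
                          events_per_period = 100,
                          seed = sample.int(1e6, 1))
    attr(sp, "sigma_rule") <- "0"
    sp
  })
  res <- suppressWarnings(run_benchmark(specs, algorithms = "gmpda"))
  expect_equal(res$accuracy, 1)
})

test_that("detector accuracy trends follow noise, sample size and method", {
  set.seed(17)
  mk <- function(n, beta, reps, rule = "log(mu)") {
    lapply(seq_len(reps), function(i) {
      mu <- sample(10:350, 1)
      sp <- generative_spec("random_walk", mu,
                            sigmas = resolve_sigma(rule, mu), beta = beta,
                            events_per_period = n,
                            seed = sample.int(1e6, 1))
      attr(sp, "sigma_rule") <- rule
      sp
    })
  }
  acc <- function(grid, alg = "gmpda") {
    mean(run_benchmark(grid, algorithms = alg)$accuracy)
  }
  # (a) non-increasing in beta at fixed n, sigma (wide-gap comparison)
  expect_gte(acc(mk(100, 0, 12)) + 0.1, acc(mk(100, 2, 12)))
  expect_gt(acc(mk(100, 0, 12)), acc(mk(100, 8, 12)))
  # (b) non-decreasing in n at beta = 0
  expect_gt(acc(mk(300, 0, 12)), acc(mk(10, 0, 12)))
  # (c, d) method ordering on a common grid: detector beats e-periodicity,
  # histogram baseline is worst
  grid <- c(mk(100, 0, 10), mk(100, 1, 10))
  a <- vapply(c("gmpda", "fft", "eper", "hist"),
              function(al) acc(grid, al), numeric(1))
  expect_gte(a["gmpda"], a["eper"])
  expect_true(all(a["hist"] <= a[c("gmpda", "fft", "eper")]))
})

test_that("reference loss is a quantile with the documented edge cases", {
  rl <- reference_loss(event_counts = c(30, 100), lengths = c(500, 2000),
                       reps = 4, quantile_p = 0.01, seed = 11)
  losses <- attr(rl, "losses")
  expect_true(all(is.finite(losses)))
  expect_true(rl >= min(losses) && rl <= max(losses))
  # q = 1 is the maximum observed loss; monotone in the quantile
  rl_max <- reference_loss(event_counts = c(30, 100),
                           lengths = c(500, 2000),
                           reps = 4, quantile_p = 1, seed = 11)
  expect_equal(as.numeric(rl_max), max(attr(rl_max, "losses")))
  expect_lte(rl, rl_max)
  # reps = 1, single cell: that run's loss
  one <- reference_loss(event_counts = 50, lengths = 1000, reps = 1,
                        quantile_p = 0.5, seed = 3)
  expect_length(attr(one, "losses"), 1)
  expect_equal(as.numeric(one), attr(one, "losses"))
})
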