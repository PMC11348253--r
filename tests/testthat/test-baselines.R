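impulse_train <- function(period, n) {
  event_series(period * seq_len(n))
}

test_that("all four baselines find the period of a noiseless impulse train", {
  s <- impulse_train(40, 100)  # n_t = 4000
  h <- interval_counts(s, 400)
  expect_equal(fft_periods(s, 1)$periods, 40L)
  expect_equal(acf_fft_periods(s, 1)$periods, 40L)
  expect_equal(hist_fft_periods(h, 1)$periods, 40L)
  expect_equal(e_periodicity_periods(s, 1)$periods, 40L)
})

test_that("baselines recover a range of train periods as the top hit", {
  for (p in c(11, 25, 60, 173, 349)) {
    s <- impulse_train(p, 30)
    # full-span histogram: the transform length then holds a whole number
    # of comb cycles and the fundamental sits on a frequency bin
    h <- interval_counts(s, s$n_t - 1)
    for (res in list(fft_periods(s, 1), acf_fft_periods(s, 1),
                     hist_fft_periods(h, 1), e_periodicity_periods(s, 1))) {
      # spectral bin resolution allows +/-1 at long periods
      expect_lte(abs(res$periods[1] - p), 1)
    }
  }
})

test_that("baseline error contracts hold", {
  # constant all-ones series: DC only, no peak in range
  ones <- event_series(0:100, n_t = 100)
  expect_error(fft_periods(ones, 1), "constant|peak")
  # series too short for spectral analysis
  expect_error(fft_periods(event_series(c(2, 5), n_t = 10), 1),
               "insufficient")
  # flat histogram
  expect_error(hist_fft_periods(fake_hist(rep(1, 400), 1000), 1),
               "constant|peak")
  expect_error(e_periodicity_periods(event_series(5, n_t = 100), 1),
               "two events")
})

test_that("requesting more peaks than exist pads with a warning", {
  # short series: few frequency bins map into the period range, so the
  # +/- 1 exclusion exhausts the isolated peaks before k is reached
  s <- impulse_train(20, 6)  # n_t = 120
  expect_warning(res <- fft_periods(s, 6, l_min = 10, l_max = 60),
                 "padding")
  expect_length(res$periods, 6)
})

test_that("e-periodicity scores arithmetic progressions correctly", {
  expect_equal(e_periodicity_periods(event_series(c(10, 20, 30, 40)),
                                     1)$periods, 10L)
  for (g in c(12, 33, 101)) {
    s <- event_series(g * (1:20))
    expect_equal(e_periodicity_periods(s, 1)$periods, g)
  }
})

test_that("baselines are deterministic and scores are non-increasing", {
  s <- quick_series("random_walk", 50, 2, 200, beta = 1, seed = 8)
  h <- interval_counts(s, 400)
  a <- hist_fft_periods(h, 3)
  b <- hist_fft_periods(h, 3)
  expect_identical(a, b)
  expect_true(all(diff(a$scores) <= 0))
  e <- e_periodicity_periods(s, 3)
  expect_true(all(diff(e$scores) <= 0))
  expect_true(all(e$periods >= 10 & e$periods <= 350))
})

test_that("spectral baselines track each other on moderate clock data", {
  acc <- c(fft = 0, acf = 0)
  set.seed(12)
  for (r in 1:20) {
    mu <- sample(10:350, 1)
    s <- quick_series("clock", mu, log(mu), 300, seed = sample.int(1e6, 1))
    t <- data.frame(mu = mu, sigma = log(mu))
    p1 <- tryCatch(fft_periods(s, 1)$periods, error = function(e) integer(0))
    p2 <- tryCatch(acf_fft_periods(s, 1)$periods,
                   error = function(e) integer(0))
    acc["fft"] <- acc["fft"] + score_estimate(p1, t)
    acc["acf"] <- acc["acf"] + score_estimate(p2, t)
  }
  expect_lte(abs(acc["fft"] - acc["acf"]) / 20, 0.2)
})
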