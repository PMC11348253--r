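# shared test helpers

# O(n^2) brute-force oracle for the all-order forward interval histogram
brute_interval_counts <- function(timestamps, max_lag) {
  s <- sort(unique(timestamps))
  counts <- numeric(max_lag)
  n <- length(s)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        d <- s[j] - s[i]
        if (d >= 1 && d <= max_lag) counts[d] <- counts[d] + 1
      }
    }
  }
  counts
}

# closed-form expected count of forward pairwise differences equal to mu,
# for n independent uniform events on [1, n_t]: the (n^2 - n)/2 unordered
# pairs each hit |A - B| = mu with probability 2 (n_t - mu) / n_t^2
uniform_interaction <- function(n, n_t, mu) {
  (n^2 - n) * (n_t - mu) / n_t^2
}

# histogram object with prescribed counts, for unit tests of estimators
fake_hist <- function(counts, n_t) {
  structure(list(counts = counts, max_lag = length(counts),
                 n_t = n_t, n_events = NA_integer_),
            class = "interval_histogram")
}

quick_series <- function(model, mu, sigma, n, beta = 0, seed = 1) {
  simulate_events(generative_spec(model, mu, sigmas = sigma, beta = beta,
                                  events_per_period = n, seed = seed))
}
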