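# gmpda

Detection of one or more periodicities in binary event-onset time series,
by fitting Gaussian mixture models to the histogram of inter-event
intervals.

## The problem

Many biomedical signals are not continuous traces but *event onsets*: a
binary series `X_t` with `x_t = 1` whenever something happened — a leg
movement during sleep, a heartbeat, a spike. Equivalently the data are the
set of timestamps `S = {s_i}`. The question is whether the events recur
periodically, with which period(s) `mu`, and with how much variability
`sigma` — in the presence of false-positive events, several overlapping
rhythms, and integer-multiple ambiguity (a series with period 11 is also
"explained" by 22 and 33; only the *prime* period 11 is wanted).

The motivating application is periodic leg movements during sleep (PLMS),
which recur at typical intervals of 20–40 s in noisy annotation data.

## The model and the detector

Two generative schemes describe periodic event data:

* **Clock model** — `s_i = alpha + i * mu + eps`, `eps ~ N(0, sigma^2)`.
  A pacemaker dictates the grid; jitter does not accumulate, so every
  future event is predictable with the same accuracy.
* **Random-walk model** — `s_{i+1} = s_i + mu + eps`. The next event
  depends only on the last one (Markov); the variance of the m-step
  interval is `m * sigma^2`, growing linearly with the horizon.

False positives are modelled as `round(beta * n_periodic)` events placed
uniformly on the series.

The detector works on `D(mu)`, the histogram of **all** forward pairwise
inter-event intervals, which for a periodic series shows peaks at the
period and its integer multiples. Its expectation under either model is a
comb of Gaussians at `m * mu` with weights `N_T / mu - (m - 1)` and
variances `sigma^2` (clock) or `m * sigma^2` (random walk). Intervals
that cross periodicities or involve noise events ("interaction
intervals") contribute a linearly decaying background `z * (1 - mu/N_T)`,
whose level `z` is estimated from the sub-periodic lags and subtracted.
The algorithm then

1. extracts candidate periods by comb-folding the cleaned histogram
   (iteratively subtracting the best-explained comb, which resolves the
   prime-versus-multiple ambiguity),
2. refines each candidate's `sigma` by least squares,
3. evaluates every subset of up to `max_periods` candidates and keeps the
   subset minimizing the normalized L1 loss between the cleaned histogram
   and the mixture curve (an extra period must improve the loss by more
   than `loss_tol_change`).

The loss lives on `[0, 2]`; losses below a *reference loss* — a low
quantile of the loss distribution on purely uniform event series — mark
significant periodicity.

## Worked example

```r
library(gmpda)

spec <- generative_spec("random_walk", periods = c(60, 97),
                        sigmas = log(c(60, 97)), beta = 0.5,
                        events_per_period = 300, seed = 42)
events <- simulate_events(spec)
events
#> Event series: 888 events on [0, 29062]
#>   s: 37 45 66 97 123 185 197 247 295 309 ...

fit <- gmpda(events, model = "random_walk", l_min = 10, max_periods = 4,
             sigma_init = 4)
summary(fit)
#> Gaussian mixture periodicity fit (random_walk model)
#>   888 events on [0, 29062]
#>   interaction level z_hat = 20.202
#>   candidates: 60, 97, 112, 312, 122, 98, 96, 294, 295, 59, 293, 61, 297, 296, 292
#>  period  sigma
#>      60  5.439
#>      97  3.985
#>     294 14.850
#>   loss: 0.4132  (0 = perfect shape match, 2 = disjoint)
```

Both true periods (60 and 97, generated with sigmas 4.09 and 4.57) are
recovered with sigma estimates close to the truth. The third, weak
component at 294 absorbs residual structure near `3 * 97`; with the
stricter tolerance used for real data (`loss_tol_change = 0.1`) such weak
components are dropped. `plot(fit)` overlays the fitted comb on the
histogram; `coef`, `residuals`, `predict` and `simulate` behave as for
any fitted model object.

Four baseline detectors operating on the same inputs are included for
comparison (`fft_periods`, `acf_fft_periods`, `hist_fft_periods`,
`e_periodicity_periods`), together with a benchmark harness
(`build_test_grid`, `run_benchmark`) scoring every method by the
half-sigma criterion: a prediction is correct when it falls within
`mu ± 0.5 sigma`.

A command-line front end for shell use is installed at
`inst/cli/gmpda.R` (subcommands `simulate`, `detect`, `benchmark`,
`refloss`).

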