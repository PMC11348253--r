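---
title: "Gaussian mixture periodicity detection: models, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian mixture periodicity detection: models, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmpda)
```

This vignette is the package's account of its science: the generative
models, the detection algorithm, every tunable parameter, and the design
decisions taken where the method left genuine freedom. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Generative models

An event series is a binary sequence $X_t$, $t = 1,\dots,N_T$, condensed
into the timestamps $S = \{s_i\}$. Events may arise from $P$ overlapping
periodicities and from false-positive noise.

**Clock model.** $s_i^p = \alpha_p + i\,\mu_p + \epsilon$ with
$\epsilon \sim N(0, \sigma_p^2)$. The jitter of one event does not
propagate: a pacemaker holds the grid. The variance of the interval
between events $m$ steps apart is constant in $m$.

**Random-walk model.** $s_{i+1}^p = s_i^p + \mu_p + \epsilon$ with
i.i.d. $\epsilon \sim N(0, \sigma_p^2)$. The process is Markov; the
$m$-step interval is a sum of $m$ independent increments, so its variance
is $m\,\sigma_p^2$ — linear growth in the horizon. (One printed form of
the recurrence suggests increment standard deviations growing with the
index $i$; we use i.i.d. increments, which is the only reading consistent
with the linear variance growth that the mixture curves below assume, and
the simulator's $m$-step variance is verified against $m\sigma^2$ by a
Monte-Carlo test.)

**Noise.** $\mathrm{round}(\beta \cdot |S_{\mu}|)$ false positives are
drawn uniformly on $[0, N_T]$, where $|S_{\mu}|$ is the number of
periodic events across all periodicities; $\beta = 2$ means one periodic
event per two noise events.

Simulator conventions, chosen once:

* $N_T$ is the largest periodic timestamp before noise is added, so that
  $n \approx N_T/\mu$ holds — the mixture-curve weights rely on this.
* Timestamps are rounded to integers and deduplicated (a binary series
  cannot hold two events at one time); noise may collide with periodic
  events and is deduplicated too.
* Start offsets $\alpha_p$ default to 0.
* Random-walk increments are not forced positive; with the benchmark's
  $\sigma \le \mu/3$ reversals are rare, and a reversed draw is simply
  recorded at its rounded value.
* A spec whose events collapse at or below zero is rejected as degenerate
  rather than silently producing an empty series.

What the generator does **not** emulate: false negatives (missed events),
non-stationary switching between regimes, and non-Gaussian interval
distributions. Passing tests therefore show correct behaviour under
Gaussian-interval, stationary conditions with uniform false positives —
not robustness to missed events or drifting periods.

## The interval histogram and the noise curve

$D(\mu)$ counts all forward pairwise differences $s_{i+m} - s_i = \mu$,
over every order $m > 0$, up to `loss_length` lags. For a periodic series
it is a comb with peaks at $\mu^*, 2\mu^*, 3\mu^*, \dots$; counting *all*
orders rather than only adjacent gaps is what makes the prime period
identifiable in noise.

Differences between events of distinct periodicities, or involving noise
events, form a background. For uniformly distributed events the expected
count of forward differences equal to $\mu$ decays linearly,
$z\,(1 - \mu/N_T)$: two independent uniform draws on $[1, N_T]$ have
$P[|A - B| = \mu] = 2(N_T - \mu)/N_T^2$, and summing over the
$(n^2 - n)/2$ pairs gives $z = (n^2 - n)/N_T$ at $\mu \to 0$. (The test
suite verifies this closed form by Monte Carlo; only the *shape*
$1 - \mu/N_T$ enters the algorithm, because the level is always estimated
from data.)

The level estimate is
$\hat z = \mathrm{mean}_{\mu \le \texttt{noise\_range}}\,
D(\mu) / (1 - \mu/N_T)$: lags below the smallest admissible period can
contain only background, so the estimator inverts the linear curve
pointwise there. A least-squares fit over the same window would be the
obvious alternative; with a handful of lags the two are nearly identical
and the mean is simpler. When `noise_range` equals `l_min` (both default
to 5) the window is capped at `l_min - 1` so no admissible period
contaminates it.

## Mixture curves and loss

The expected histogram for estimates $(\hat\mu_p, \hat\sigma_p)$ is a sum
of Gaussian components at $m \hat\mu_p$ with weights
$c_m = N_T/\hat\mu_p - (m - 1)$ (floored at zero) and variances
$\hat\sigma_p^2$ (clock) or $m \hat\sigma_p^2$ (random walk). Components
are evaluated while $m\hat\mu_p$ lies within four component standard
deviations of the largest lag; beyond that they contribute negligibly.
Two printed-formula issues are resolved on physical grounds: the Gaussian
exponent carries its standard negative sign, and the random-walk
component variance is $m\sigma^2$ (linear growth), not $(m\sigma)^2$.
A requested $\sigma = 0$ is replaced by 0.5 — sub-sample resolution —
with a warning.

The loss is the L1 distance between the cleaned histogram and the mixture
curve after both are normalized to unit sum on the window
$[\,l_\min, \min(\texttt{loss\_length}, N_T - 1)\,]$. It lives on
$[0, 2]$ (0 = identical shapes, 2 = disjoint support) and is invariant to
the overall event count, which makes loss values comparable across series
and makes a universal reference threshold meaningful. The curve side
deliberately contains *only* the periodic mixture: modelling the
background on both sides would let any series — including pure noise —
achieve a near-zero loss and would destroy the reference-loss calibration
below.

## The algorithm and its parameters

| parameter | default | role |
|---|---|---|
| `model` | `random_walk` | generative scheme fitted to the histogram |
| `l_min`, `l_max` | 5, 350 | period search range (samples) |
| `loss_length` | 400 | largest lag in histogram and loss |
| `max_periods` | 5 | maximal number of reported periods |
| `max_candidates` | 15 | candidate pool size |
| `max_iterations` | 5 | subtraction sweeps of the candidate search |
| `noise_range` | 5 | sub-periodic window for $\hat z$ |
| `loss_tol_change` | 0.01 | required loss gain per extra period |
| `curve_fit` | `TRUE` | refine $\sigma$ by least squares |
| `sigma_init` | $\lfloor \log l_\min \rfloor$ | initial $\sigma$ guess |

`sleep_bout_config()` is the sleep-bout preset (`l_max = 200`,
`loss_tol_change = 0.1`): leg-movement periods are short, and on noisy
real data an extra periodicity should only be reported when it buys a
substantial loss improvement.

**Candidate extraction.** Computing the loss for every admissible period
is wasteful; instead each lag $q$ is scored by folding the cleaned
histogram over its multiples: the mass within $\pm w(q)$ of each $m q$,
$w(q) = \max(1, \mathrm{round}(\log q))$, background-corrected and summed
over the $K$ multiples inside the window, scaled by $1/\sqrt K$. The
components of this score were chosen to defeat the two classic failure
modes: summing over multiples ranks a prime above its integer multiples
(which capture only part of the comb), while the $1/\sqrt K$ factor ranks
it above its subharmonics (which spread the same mass over empty extra
windows); the background correction keeps flat noise from favouring short
lags. After each accepted candidate its fitted single-period comb is
subtracted (clipped at zero) and the fold recomputed — up to
`max_iterations` sweeps — so a second periodicity hidden under the first
one's comb becomes visible. Remaining candidate slots are filled from the
initial ranking. Ties break toward the smaller lag: the prime period is
the smallest explanatory interval.

**Sigma refinement.** For each candidate, $\sigma$ is searched on a
multiplicative neighbourhood of the initial guess —
$[\hat\sigma_0/4,\; 4\hat\sigma_0]$, capped at $\hat\mu/2$ — minimizing
the squared error of the best non-negatively rescaled single-period comb
against the cleaned histogram. The free amplitude keeps mass belonging to
*other* periodicities from biasing the width. The neighbourhood bound is
deliberate: this step refines an initial guess, and an unconstrained
search lets a near-flat, huge-$\sigma$ component win the normalized loss
by soaking up residual background instead of matching the comb — a
failure mode we observed at high noise rates. Optimizer failure falls
back to `sigma_init` with a warning, never an error.

**Subset selection.** The loss is evaluated for every candidate subset of
size $1 \dots$ `max_periods` (single-period curves are cached, so a
subset's curve is a sum of columns and the whole search is a matrix
product). The best subset of size $k+1$ replaces the best of size $k$
only when it improves the loss by more than `loss_tol_change`. Finally,
with `curve_fit` on, the selected subset's sigmas are refitted jointly —
one coordinate-wise pass of 1-D optimization on the mixture loss, which
is cheap and in practice converges in that single pass because the
periods' combs overlap little.

**Degenerate inputs.** Fewer than two events, a series shorter than
`l_min`, or a flat histogram yield an empty estimate with `NA` loss —
never an error. The fit is a pure function of (series, configuration);
timestamp order is irrelevant.

## Baselines

The four comparison detectors share the period range and, in benchmarks,
receive the true number of periodicities $k$ — a favourable treatment
they are given deliberately, since none has a stopping rule.

* `fft_periods`: raw periodogram of the mean-removed binary series;
  top-$k$ peaks with $\pm 1$-bin exclusion; periods are rounded inverse
  frequencies.
* `acf_fft_periods`: periodogram of the *full-length* linear
  autocorrelation (computed via zero-padded FFT). Truncating the ACF to a
  few hundred lags would make every period beyond ~200 unresolvable, so
  full length is used to preserve the raw periodogram's resolution.
* `hist_fft_periods`: periodogram of $D(1..\texttt{loss\_length})$. Its
  frequency resolution is intrinsically limited by the histogram length —
  a period $p$ is resolvable to $\pm 1$ only when $p^2 \lesssim$ the
  transform length — which is why this baseline fares worst in the
  benchmark.
* `e_periodicity_periods`: modulus folding; score of $p$ = number of
  event pairs whose interval is an integer multiple of $p$ within
  $\pm 1$, normalized by the whole periods in the span; near-multiples of
  selected periods are suppressed.

One numerical choice deserves emphasis: a noiseless event comb has equal
spectral power at every harmonic, so "take the maximum power" is
ill-defined on exact trains. Peak picking therefore tie-breaks
near-maximal bins (within 10%) toward the lowest frequency — the
fundamental, whose inverse is the prime period rather than a
sub-multiple. With jittered data the jitter acts as a low-pass filter and
the fundamental dominates anyway.

## Benchmark and reference loss

A detected period is *correct* when it lies within
$\mu^* \pm 0.5\,\sigma^*$ (exact match when $\sigma^* = 0$). Predictions
are matched to truths greedily, closest pair first, one-to-one — so two
near-identical predictions cannot both claim one truth. The full factorial
design (6 sigma rules × 6 event counts × 8 noise rates × 100 replicates =
28,800 single-period cases per model; 4 × 4 × 5 × 100 = 8,000 for two and
three periods, with periods separated by more than $\log \mu$) is built by
`build_test_grid`; replicate counts are configurable because the full
design exceeds desk scale, and all per-spec seeds derive deterministically
from one master seed. The detector is run with `max_periods` set to the
true period count plus two; with curve fitting it is initialized at the
generative $\sigma^*$, without it at $\lfloor\log l_\min\rfloor$ —
mirroring the two study configurations. Failed runs count as misses and
never abort a sweep.

The *reference loss* calibrates significance: uniform (non-periodic)
series are generated for all combinations of event counts
{10, 30, 50, 100, 200, 400} and lengths {500 … 16,000}, the detector is
run on each, and a low quantile (default 0.01) of the pooled losses is
the threshold below which an observed loss indicates genuine
periodicity. Undefined losses are skipped; the quantile is monotone in
its argument by construction.

Problem sizes used by the shipped tests and acceptance script: 20
replicates per benchmark cell, 10 uniform series per reference-loss cell,
and Monte-Carlo property checks at 15–30 seeds — sizes chosen so the whole
verification runs in minutes on a single CPU while keeping binomial
standard errors around 2 percentage points on aggregate accuracies.

## Known limitations

* More than two overlapping periodicities are rarely all recovered; the
  interaction background grows with $P$ and the random-walk combs flatten
  at high orders.
* Fewer than ~30 periodic events seldom support detection; the reference
  loss on sparse series is close to losses of genuinely periodic sparse
  series.
* The uniform-background approximation treats cross-periodicity intervals
  as noise; strongly commensurate periods (separation below $\log\mu$)
  are not handled by design.
* Periods are searched on an integer lattice; sub-sample periods are out
  of scope, as is missing-data (false-negative) handling.
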