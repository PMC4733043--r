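---
title: "Exact equilibrium analysis of stochastic organelle production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact equilibrium analysis of stochastic organelle production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgdist)
```

## The model

A cell carries an integer number $n$ of copies of an organelle. Four
elementary processes change $n$, each first-order in a short window
$\delta t$:

| process | propensity | effect |
|---|---|---|
| de novo synthesis | $k_{\mathrm{de\,novo}}$ | $n \to n+1$ |
| fission | $k_{\mathrm{fission}}\, n$ | $n \to n+1$ |
| decay | $\gamma\, n$ | $n \to n-1$ |
| fusion | $k_{\mathrm{fusion}}\, n(n-1)$ | $n \to n-1$ |

This is a birth–death chain with immigration (de novo), linear birth
(fission), linear death (decay) and a quadratic loss term (fusion, which
needs a pair). Time units are arbitrary: scaling all four rates by a common
factor only rescales time, so the limiting distribution depends on the three
ratios $k_{\mathrm{de\,novo}}/\gamma$, $k_{\mathrm{fission}}/\gamma$,
$k_{\mathrm{fusion}}/\gamma$. The fusion propensity is taken verbatim as
$k_{\mathrm{fusion}}\,n(n-1)$ — the ordered-pair count, with no factor of
$\tfrac12$ — because that expression *defines* the model; a symmetrised
convention would simply rescale $k_{\mathrm{fusion}}$ by 2.

## The exact solver

Because all jumps are $\pm 1$, stationarity forces *detailed balance*: the
probability flux from $n$ to $n+1$ must equal the flux back (any net
circulation would require a cycle, and a birth–death chain has none). The
flux balance

$$(k_{\mathrm{de\,novo}} + k_{\mathrm{fission}} n)\, f_n
 = (\gamma + k_{\mathrm{fusion}} n)(n+1)\, f_{n+1}$$

gives a term ratio, and the whole distribution follows by running the
recurrence from an arbitrary seed value and normalising — the seed cancels
exactly. `stationary_distribution()` implements this with three numerical
safeguards:

* **Log-space accumulation.** Unnormalised terms of a large-mean model
  overflow doubles well before the distribution is exhausted (a Poisson-type
  model with mean $5\times 10^4$ is handled in the tests), so the recurrence
  runs on $\log f_n$ throughout.
* **Truncation rule.** The support is extended until the current relative
  term falls below `tail_tolerance * 1e-3` *and* the term ratio has dropped
  below 1 (past the mode), at which point the remaining mass is bounded by a
  geometric series; that bound is reported as `tail_bound` and the retained
  probabilities are normalised so retained mass plus `tail_bound` equals 1.
  The default `tail_tolerance = 1e-12` makes truncation error negligible
  against the 1e-10 agreement demanded of the closed-form cross-checks. A
  hard cap (`n_cap`, default $10^5$ support points) turns a near-critical
  model into an informative error rather than an unbounded loop.
* **Regime gate.** The solver refuses rates without a limiting distribution
  instead of silently normalising a divergent sequence.
  `classify_regime()` is the single source of truth: with no fusion,
  $k_{\mathrm{fission}} \ge \gamma$ (including equality, where the mean and
  Fano factor diverge) means no limiting law; with no de novo synthesis,
  state 0 is absorbing when decay is present (the limiting law is the point
  mass at 0, which the recurrence produces naturally) or unreachable when it
  is not (the chain lives on $n \ge 1$ and the recurrence starts there).

```{r solver}
rates <- model_rates(k_de_novo = 2, k_fission = 0.9, gamma = 1,
                     k_fusion = 0.02)
d <- stationary_distribution(rates)
distribution_stats(d)[c("mean", "fano")]
```

`stationarity_residual()` measures the maximum flux imbalance of *any*
distribution against a model — by construction near machine precision for
solver output, and a useful distance-from-equilibrium diagnostic for
empirical histograms.

## Closed-form limiting laws

Three classic sub-models have limiting laws in standard families, read off
from the term ratio:

* **\{de novo; decay\}** — ratio $\lambda/(n+1)$ with
  $\lambda = k_{\mathrm{de\,novo}}/\gamma$: Poisson($\lambda$).
* **\{fission; fusion\}** — on $n \ge 1$ the ratio is $\lambda/(n+1)$ with
  $\lambda = k_{\mathrm{fission}}/k_{\mathrm{fusion}}$: the *zero-truncated*
  Poisson (Poisson conditioned on $n \ge 1$), not the shifted Poisson
  ($1 + \mathrm{Pois}$) sometimes used for this model. The two differ subtly
  in the pmf but sharply in the Fano–mean curve: the truncated Poisson's
  Fano factor approaches 1 from below like $\lambda e^{-\lambda}$, the
  shifted Poisson's like the power law $\lambda/(1+\lambda)$.
  `fano_mean_curve()` generates both curves; the shifted Poisson is kept in
  the package precisely for this comparison.
* **\{de novo, fission; decay\}** — the peroxisome-style model: a negative
  binomial with size $r = k_{\mathrm{de\,novo}}/k_{\mathrm{fission}}$ and
  success probability $p = k_{\mathrm{fission}}/\gamma$, giving the exact
  moments
  $$\langle n\rangle = \frac{k_{\mathrm{de\,novo}}}{\gamma - k_{\mathrm{fission}}},
  \qquad
  \frac{\sigma^2}{\langle n\rangle} = \frac{\gamma}{\gamma - k_{\mathrm{fission}}}
  = 1 + \frac{k_{\mathrm{fission}}\langle n\rangle}{k_{\mathrm{de\,novo}}}.$$
  Both moments diverge as $k_{\mathrm{fission}} \uparrow \gamma$, which is
  why that boundary is classified as divergent.

The closed forms are evaluated with `stats::dpois()`/`stats::dnbinom()` and
serve as independent oracles for the recurrence: the test suite demands
total-variation agreement within $10^{-10}$ over 20+ random parameter sets
per family.

```{r closedform}
peroxisome_mean(model_rates(2.7, 0.1, 1))   # 2.7 / (1 - 0.1)
peroxisome_fano(model_rates(2.7, 0.1, 1))   # 1 / (1 - 0.1)
```

## Simulation

`simulate_trajectory()` and `simulate_ensemble()` provide two schemes in a
small C++ core:

* **event_driven** (default): the exact stochastic simulation algorithm
  (Gillespie direct method) — exponential waiting times from the summed
  propensity, one event per draw.
* **fixed_step**: time advances in steps of `dt` (default $10^{-4}$) and a
  single uniform draw against the cumulative first-order probabilities fires
  at most one event per step. Multi-event probability within a step is
  $O(dt^2)$; the scheme errors out rather than proceeding if the summed
  per-step probability reaches 1. The two schemes agree within sampling
  error in the tests, which is the adopted correctness criterion for the
  fixed-step approximation.

Reproducibility is contract-level: the core uses its own `mt19937_64`
stream seeded through `splitmix64`, so a given configuration and seed give
byte-identical output on any platform, and ensembles derive per-cell
streams from the master seed by a counter split, independent of execution
order. A divergence guard (default cap $10^6$ organelles) terminates
runaway-fission runs with an error naming the `classify_regime()` verdict.

Equilibrium can be sampled two equivalent ways — time-averaging one long
trajectory (`trajectory_stats()`, which discards a default 20% burn-in so
the run forgets its arbitrary starting point) or observing many cells at
one time (`simulate_ensemble()`); the tests verify the two agree.

```{r simulate}
cfg <- simulation_config(rates, n0 = 1, t_end = 15, seed = 1)
snap <- simulate_ensemble(cfg, n_cells = 2000, tau = 15)
snapshot_tv_distance(snap, d)   # close to the limiting distribution
```

## Inference

For the \{de novo, fission; decay\} model the exact moment formulas invert
in closed form, which is the basis of three small inference tools:

* `decompose_production(fano)` splits total production between the de novo
  route ($1/F$ of it) and fission ($(F-1)/F$), using only the Fano factor
  $F$. $F = 1$ is purely de novo; equal contributions require $F = 2$; the
  fission share grows only slowly beyond that ($F = 3$ for fission to be
  double de novo). An observed $F$ slightly below 1 (sampling noise) can be
  clamped to 1 via a `tolerance` argument, but the default is strict: a
  sub-Poisson histogram is evidence *against* this model (fusion, or a
  non-equilibrium population) and should be surfaced, not absorbed.
* `invert_rates(mean, fano)` recovers $k_{\mathrm{fission}}/\gamma = 1 - 1/F$
  and $k_{\mathrm{de\,novo}}/\gamma = \langle n\rangle/F$ — an exact
  algebraic inverse, verified by round-trip in the tests. Fusion-inclusive
  inversion is refused rather than approximated, since the formulas hold
  only with $k_{\mathrm{fusion}} = 0$.
* `knockout_prediction()` turns inferred rates into the predicted relative
  drop in the equilibrium mean if fission is deleted:
  $100\,k_{\mathrm{fission}}/\gamma$ percent.

```{r infer}
inf <- invert_rates(mean = 3, fano = 1.1)
inf
knockout_prediction(inf)
```

A glucose-grown yeast population with $\langle n\rangle = 3$ and $F = 1.1$
thus implies $k_{\mathrm{de\,novo}} \approx 2.7\gamma$,
$k_{\mathrm{fission}} \approx 0.1\gamma$: fission contributes under 10% of
production, and its knockout should lower the mean count by only 10% — a
directly testable prediction, and one that published deletion-strain counts
(which drop far more) sit uneasily with.

`observed_moments()` estimates mean, variance (unbiased, $n-1$ denominator
— reported Fano values in this literature rarely state their estimator, so
the choice is declared here to make results reproducible) and Fano factor
from per-cell counts, with percentile-bootstrap confidence intervals over
cells on request.

## What the synthetic data does and does not show

All validation data are generated by the package's own simulator, which
emulates exactly the model's four processes — so round-trip tests
(simulate → estimate → invert) demonstrate self-consistency of solver,
simulator and inference, not fidelity of the model to real organelle
biology. Real count data add at least: detection limits (small, dim
organelles are undercounted), cell-division partitioning, cell-cycle and
growth-condition non-stationarity, and possible feedback on the rates. None
of these are modelled; a failure of the model on real data (e.g. a
sub-Poisson Fano factor, or knockout responses far exceeding the predicted
drop) is informative precisely because the package computes the model's own
predictions exactly.

## Problem sizes and numerical choices

The shipped tests use ensembles of $2\,000$–$50\,000$ cells and trajectories
of a few thousand time units — sizes at which Monte-Carlo standard errors
are an order of magnitude below the asserted tolerances, chosen so the
checks are sharp while the whole suite stays interactive. Monte-Carlo
tolerances in the tests are set from the usual
$\sqrt{2\tau_c \sigma^2 / T}$ (time averages, correlation time
$\tau_c \approx 1/\gamma$) and $\sqrt{\sigma^2/N}$ (ensembles) scalings,
at 3–4 standard errors under the fixed test seeds. Tie-break and degenerate
cases are pinned down explicitly: all-zero rates are refused at
construction; a state from which nothing can fire yields a constant
trajectory; an all-zero-count histogram has an *undefined* Fano factor
(flagged, never silently 0, which would corrupt Fano–mean curves).
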