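# orgdist

Exact equilibrium analysis of the stochastic model of organelle production.

Organelle copy numbers (peroxisomes, Golgi cisternae, vacuoles) fluctuate
from cell to cell, and the *shape* of the count distribution carries
information about how the organelles are made and lost. `orgdist` implements
the four-process birth–death model of a single cell's organelle count
n — de novo synthesis (propensity k_de_novo), fission (k_fission·n),
first-order decay (γ·n) and pairwise fusion (k_fusion·n(n−1)) — and computes
its limiting distribution **exactly**, via the detailed-balance recurrence

    f(n+1) = (k_de_novo + k_fission·n) / ((γ + k_fusion·n)(n+1)) · f(n)

instead of relying on stochastic simulation or fluctuation–dissipation
approximations. It is aimed at quantitative cell biologists who want to
confront organelle count histograms with this class of model, and at
modellers who need a reference implementation to test approximations
against.

What it provides:

* **Exact solver** — `stationary_distribution()` runs the recurrence in log
  space with a controlled truncation tail bound; `classify_regime()` decides
  first whether a limiting distribution exists at all (with no fusion it
  requires k_fission < γ).
* **Closed-form laws** — the three classic sub-models resolve to standard
  families: {de novo; decay} → Poisson(k_de_novo/γ); {fission; fusion} →
  zero-truncated Poisson(k_fission/k_fusion); {de novo, fission; decay} →
  negative binomial with exact moments ⟨n⟩ = k_de_novo/(γ − k_fission) and
  Fano factor σ²/⟨n⟩ = γ/(γ − k_fission) = 1 + k_fission⟨n⟩/k_de_novo.
  The (incorrect for this model, historically used) shifted Poisson is kept
  for Fano–mean curve comparison (`fano_mean_curve()`).
* **Simulator** — exact (Gillespie) and fixed-step schemes in C++, for
  single-cell trajectories and cell-ensemble snapshots, fully reproducible
  from a seed, with a divergence guard for runaway-fission regimes.
* **Inference** — `decompose_production()` (de novo fraction = 1/Fano),
  `invert_rates()` (mean + Fano → rate constants in units of γ),
  `knockout_prediction()` (expected drop in ⟨n⟩ if fission is deleted) and
  `observed_moments()` (sample moments with bootstrap CIs).
* **CLI** — a thin command-line wrapper with subcommands
  `solve | simulate | curve | decompose | invert | moments` at
  `system.file("cli", "orgdist.R", package = "orgdist")`.

## Worked example

```r
library(orgdist)

rates <- model_rates(k_de_novo = 2, k_fission = 0.9, gamma = 1,
                     k_fusion = 0.02)
d <- stationary_distribution(rates)
d
#> Organelle count distribution on n = 0..64 (tail bound 4.05e-16)
#>   mean 7.193, variance 19.48, Fano 2.708
```

The exact limiting distribution of this fusion-regularised model has mean
7.19 and Fano factor 2.71; a 2000-cell simulated ensemble observed at
τ = 15 has converged to it:

```r
cfg <- simulation_config(rates, n0 = 1, t_end = 15, seed = 1)
snap <- simulate_ensemble(cfg, n_cells = 2000, tau = 15)
observed_moments(snap)
#> Observed moments over 2000 cells:
#>   mean 7.253, variance 19.7, Fano 2.717
snapshot_tv_distance(snap, d)
#> [1] 0.04212907
```

Inference from observed moments: a population with mean count 3 and Fano
factor 1.1 pins the rates of the {de novo, fission; decay} model to

```r
inf <- invert_rates(mean = 3, fano = 1.1)
inf
#> Inferred rates: k_de_novo = 2.727*gamma, k_fission = 0.09091*gamma
knockout_prediction(inf)
#> [1] 9.090909
decompose_production(2.4)
#> Production decomposition at Fano = 2.4:
#>   de novo 42%  |  fission 58%
```

so fission contributes only ~9% of production and deleting it should lower
the mean count by only ~9% — while at Fano 2.4 the two routes are near
parity (42%/58%), not "fission dominance".

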