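# mmcsim

Simulation and verification of multiple-merger (Λ-) coalescents arising
from Cannings population models with fluctuating population size.

## The problem

Genealogies of samples from species with sweepstake reproduction — a few
individuals occasionally contributing a large fraction of the next
generation — are not well described by Kingman's n-coalescent. Their limits
are **Λ-n-coalescents**: partition-valued Markov processes on a sample
{1, …, n} in which any k of b ancestral lineages merge at rate

    λ_{b,k} = ∫₀¹ x^(k−2) (1−x)^(b−k) Λ(dx),

for a finite measure Λ on [0, 1] (the point mass at 0 gives Kingman's
coalescent; Beta(a, b) measures give the Beta coalescents; Beta(1, 1) is
the Bolthausen–Sznitman coalescent). When the population size also changes
— by a deterministic profile ν(t) of order N, with ν(0) = 1 — the limit is
the same coalescent run through a deterministic clock

    G(t) = ∫₀ᵗ ν(s)^(−γ) ds,

where γ is the scaling exponent of the discrete model's pairwise
coalescence probability c_N (one coalescent unit = 1/c_N generations).
Under exponential growth, waiting times between mergers become Gompertz
distributed.

`mmcsim` implements, in one package:

* **Discrete models.** Modified Moran models (one multiplying parent with
  U_N ≥ 2 offspring per generation) with the skewed law U′_N induced by a
  Λ measure, its *rarefied* variant calibrated so that c_N = N^(−γ)
  exactly, and Schweinsberg's heavy-tailed Cannings model
  (P(X ≥ k) = k^(−α), 1 ≤ α < 2) — all with variable population sizes,
  hypergeometric subsampling under decline, and three growth-allocation
  schemes (to the multiplier, to non-reproducers, proportional).
* **Exact limits.** The (time-changed) Λ-n-coalescent simulated exactly,
  Gompertz waiting-time closed forms, and a neutral-mutation overlay.
* **Diagnostics.** Exact and Monte-Carlo checks that the discrete models
  match their limits: merger-pattern probabilities Φ, Möhle–Sagitov ratios
  c_N⁻¹Φ → λ, discrete time-scale tables F_N and their pseudo-inverse,
  distributional tests (KS, χ²) on simulated genealogies, scaling-exponent
  regression for c_N, and the abrupt-expansion counterexample showing why
  instantaneous size jumps must be spread over ~1/√c_N generations.

Genealogies are exported as (multifurcating) Newick text, event tables
(TSV) and provenance records (JSON); `as_phylo()` hands trees to `ape`.

## Worked example

```r
library(mmcsim)
set.seed(7)

meas <- lambda_measure("beta", a = 1, b = 1)   # Bolthausen-Sznitman
total_rate(meas, 10)
#> [1] 9                       # lambda_b = b - 1 for Beta(1,1)

m <- moran_model(100, "uprime", measure = meas)
g <- simulate_genealogy(m, 8)
g
#> Modified-Moran genealogy of n = 8 (uprime offspring, constant profile, N = 100)
#>   4 merger events, TMRCA 10 generations, total length 57
events_table(g)
#>   generation  coal_time merged_blocks block_count_after
#> 1          1 0.01010101           4,7                 7
#> 2          5 0.05050505         3,4,8                 5
#> 3          6 0.06060606           3,6                 4
#> 4         10 0.10101010       1,2,3,5                 1
```

The genealogy coalesces in 10 generations (0.101 coalescent units at
c_N = 1/99): the skewed offspring law produces a triple and a quadruple
merger alongside binary ones. The finite-N convergence ratio towards the
limit is exact for these laws at every N, not just asymptotically:

```r
moehle_sagitov_check(function(N) moran_model(N, "uprime", measure = meas),
                     N_grid = c(50, 200), patterns = list(3L), measure = meas)
#>     N pattern ratio se phi
#> 1  50       3   0.5  0 0.5
#> 2 200       3   0.5  0 0.5
```

— the triple-merger ratio c_N⁻¹Φ₁(3) equals E(X) = 1/2 for Beta(1,1) at
both sizes, the limit rate λ₃,₃ = 0.5.

A JSON-configured run from the shell:

```sh
Rscript inst/cli/mmc.R simulate --config run.json --out out/run1
```

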