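---
title: "Multiple-merger coalescents from Cannings models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-merger coalescents from Cannings models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmcsim)
```

## The models

A **Λ-n-coalescent** is a Markov process on partitions of a sample
$\{1,\dots,n\}$ in which every fixed set of $k$ of $b$ ancestral lineages
merges at rate
$$\lambda_{b,k} = \int_0^1 x^{k-2}(1-x)^{b-k}\,\Lambda(dx),$$
with $\Lambda$ a finite measure on $[0,1]$. `mmcsim` supports point masses
(Dirac coalescents; $\psi = 0$ is Kingman, $\psi = 1$ star-like) and the
Beta$(a,b)$ family, plus a `rate_multiplier` that rescales every rate
uniformly (equivalently, a linear change of time units). Rates are always
evaluated through log-Beta or log-power differences, never factorials, so
tables remain accurate for thousands of lineages.

Three discrete population models stand behind these limits:

1. **Modified Moran** (`moran_model`): each generation one uniformly
   chosen parent (the *multiplier*) has $U_N \ge 2$ offspring, $U_N - 1$
   parents none, everyone else exactly one. With the skewed law
   $$P(U'_N = j) = \lambda_N^{-1}\binom{N}{j}E\!\left(X^{j-2}(1-X)^{N-j}\right),
   \qquad X \sim \Lambda,$$
   ($U'_N$ is distributed like the first merger size of the
   Λ-N-coalescent) the model's rescaled genealogies converge to the
   Λ-n-coalescent. The pairwise coalescence probability is then exactly
   $c_N = 1/\lambda_N$.
2. **Rarefied modified Moran** (`rarefy`): the skewed reproduction is
   *activated* only with probability $P(A_N) = N^{-\gamma}\lambda_N$,
   otherwise the generation is standard Moran ($U = 2$). The calibration
   makes $c_N = N^{-\gamma} + (1-P(A_N))\,2/(N)_2$ with
   $\gamma \in (1,2)$, the regime in which size changes induce the
   time-change exponent $\gamma$.
3. **Heavy-tailed Cannings** (`schweinsberg_model`): every parent draws
   i.i.d. potential offspring with $P(X \ge k) = k^{-\alpha}$,
   $\alpha \in [1,2)$; the next generation is a uniform
   without-replacement sample from the pool. Here
   $c_N \sim C\alpha B(2-\alpha,\alpha)E(X)^{-\alpha}N^{1-\alpha}$ and the
   limit is the Beta$(2-\alpha,\alpha)$-coalescent. The tail law is the
   simplest distribution satisfying the required asymptotics *exactly*
   (tail constant $C = 1$, mean $\zeta(\alpha) > 1$); this concrete choice
   is ours, since only tail asymptotics are prescribed by the theory.
   $\alpha = 1$ is accepted by the sampler but refused by
   `shortfall_bound` and `empirical_cN_exponent` (infinite mean).

### Variable population size

A profile $\nu(t)$ with $\nu(0) = 1$ gives sizes
$N_r \approx N\,\nu(r\,c_N)$ going $r$ generations into the past
(`discretize_profile`; built-ins: constant, exponential
$\nu(t) = e^{-\rho t}$, piecewise-constant bottlenecks, tabulated with
linear interpolation). Exponential profiles use the geometric recursion
$N_r = \lfloor N(1-\rho c_N)^r\rfloor$ evaluated in closed form on demand.
Two printed forms of this recursion circulate with opposite index
directions; we use the one under which sizes *shrink* going back in time
when $\rho > 0$ (growth forward in time), which is the direction required
for $N^{-1}N_{\lfloor t/c_N\rfloor} \to e^{-\rho t}$. Generic profiles are
materialized with banker's rounding and clamped below at $\max(2, n)$ with
a warning; profiles dipping below that floor on the horizon are an error.

Under **decline**, the next generation is a uniform without-replacement
subsample of the offspring; the surviving multiplier brood is
hypergeometric, which preserves every merger functional exactly:
$E((U_\mathrm{eff})_a)/(\text{target})_a = E((U)_a)/(N_r)_a$. Under
**growth**, the $d$ added individuals are allocated by one of three
schemes: all to the multiplier, all to previously childless parents
(feasible only when $d \le U-1$), or `proportional`
($A \sim \mathrm{Binomial}(d, U/N_r)$ to the multiplier). For
`proportional` we resolve the feasibility constraint $d - A \le U - 1$ by
*pushing overflow up* to the multiplier deterministically after the draw
(not by renormalized conditioning): it is the constraint's own statement
— offspring that cannot be attached anywhere else go to the multiplier —
and keeps the draw a plain binomial whenever the constraint does not
bind. An instantaneous change of size $mN$ on the coalescent scale is
realized by `spread_jump`: $\lceil 1/\sqrt{c_N}\rceil$ consecutive
generations each changing by $\approx mN\sqrt{c_N}$ (integer-ramped so the
total is exact), so per-generation relative increments vanish as
$N \to \infty$. `abrupt_expansion_demo` shows why this is necessary: dumping
$\lfloor mN \rfloor$ individuals on the multiplier in a *single*
generation keeps the pairwise coalescence probability above
$(mN-1)^2/(N_{r-1})_2$, which does not vanish.

### The time change and Gompertz waiting times

In the limit, size change survives only as the deterministic clock
$\mathcal{G}(t) = \int_0^t \nu(s)^{-\gamma}ds$, where $\gamma$ is the
exponent of $c_N$ ($\gamma = 2$ for the standard Moran model, $\gamma$
itself for the rarefied model, $\alpha - 1$ for the heavy-tailed model;
$\gamma = 0$ encodes logarithmic $c_N$ and makes $\mathcal{G}$ the
identity). Because the theory pairs $\gamma$ with the discrete model, the
package never infers it: `time_change(profile, gamma)` takes it
explicitly. `simulate_lambda_coalescent` draws internal waits
$W \sim \mathrm{Exp}(\lambda_b)$ and maps them through
$\mathcal{G}^{-1}$; the jump chain is untouched, so matched seeds give
identical merger sequences with and without time change (a property the
tests assert). For exponential profiles
$\mathcal{G}(t) = (\rho\gamma)^{-1}(e^{\rho\gamma t}-1)$ in closed form,
and the waiting time to the next merger given $b$ blocks at $t_0$ is
Gompertz:
$$P(T \le t) = 1 - \exp\!\left(-\tfrac{\lambda_b}{\rho\gamma}
  e^{\rho\gamma t_0}(e^{\rho\gamma t}-1)\right).$$
(The widely printed version of this display sometimes drops the leading
minus sign in the exponent; the form above is the one that equals
$1 - e^{-\lambda_b(\mathcal{G}(t_0+t)-\mathcal{G}(t_0))}$ and integrates
to a distribution.) Other profiles invert $\mathcal{G}$ by bracketing plus
`uniroot` at absolute tolerance $10^{-10}$; quadrature uses
`stats::integrate` at relative tolerance $10^{-12}$.

## Simulation internals

Only the at most $n$ sample lineages are tracked, never the pedigree. By
exchangeability the lineages occupy a uniform random subset of each
generation's offspring, so for the Moran engines the number falling into
the multiplier's brood is hypergeometric — one draw per generation —
and for the heavy-tailed engine parents are drawn sequentially,
proportional to remaining multiplicities, without materializing pools
(realized multiplicities given the pool are multivariate hypergeometric;
shortfalls attach the missing individuals to uniform parents, preserving
exchangeability).

Across stretches of constant size the generations are i.i.d., so the wait
to the next generation containing a merger is geometric with success
probability $p_b = \sum_u P(U_\mathrm{eff}=u)\,q_b(u)$,
$q_b(u) = P(\text{hypergeometric} \ge 2)$; `mmcsim` draws that gap in one
step (by inversion, avoiding integer overflow at tiny $c_N$) and then the
merger size from the exact conditional law. This is an *exact*
acceleration, not an approximation, and makes Kingman-scale horizons
($\sim N^2/2$ generations) costless. Non-constant trajectories run
generation by generation.

Monte-Carlo pairwise estimators use conditional Bernoulli draws: given a
realized generation, two uniformly chosen distinct offspring share a
parent with an exactly computable probability (e.g.
$\sum_i (X_i)_2/(S)_2$ for the pool model, using the fact that a uniform
pair from a uniform subsample is a uniform pair from the pool), and one
Bernoulli trial per replicate is drawn with that probability. The
estimate is the plain MC frequency of the defining event, but each
replicate costs $O(N)$ instead of a full assignment.

The mutation overlay is Poisson with intensity $\theta$ per unit branch
length on limit trees; on discrete genealogies it is the matched
per-generation probability $\mu_N = \theta c_N$, applied per branch as a
binomial after simulation (distributionally identical to flagging
generations during the run).

## Diagnostics and their calibration

* `estimate_phi` / `moehle_sagitov_check`: merger-pattern probabilities
  and their ratios to $c_N$. For skewed Moran laws the $l = 1$ ratios are
  computed exactly and equal $E(X^{a-2})$ at *every* N — an algebraic
  identity, asserted to $10^{-10}$ in the tests. Simultaneous patterns
  are exactly zero for single-multiplier models.
* `empirical_time_scale`: the table $F_N(s) = \sum_{r \le s} c_{N,r}$ and
  its shifted pseudo-inverse $\inf\{s: F_N(s) > t\} - 1$; exact
  per-generation $c_{N,r}$ for Moran models (decline generations inherit
  the fixed-size value by the neutrality identity; growth generations use
  the scheme's conditional law of $A$).
* `genealogy_convergence_test`: two-sample KS on pairwise times and
  TMRCA, $\chi^2$ on first-merger sizes against the limit jump chain
  $\binom{n}{k}\lambda_{n,k}/\lambda_n$, expected counts below 5 pooled
  with the largest-size bin; a category that is impossible under the
  limit but observed forces $p = 0$. The automated significance level is
  0.01 throughout, with fixed seeds; tolerances of MC assertions are
  expressed in standard-error multiples, never absolute constants.

All distributional tests are run at desk scale — e.g. 2000 pairwise
replicates at $N = 300$, 5000 Gompertz waits, $2\times10^5$ Bernoulli
replicates per size on the grid $\{50,\dots,800\}$ for the
$N^{1-\alpha}$ slope (asserted within $\pm 0.15$ of $-0.5$ at
$\alpha = 1.5$) — sizes chosen so the whole suite runs in about a minute
while keeping MC error well inside the asserted margins.

### Finite-size effects the tests exhibit

Theory here is asymptotic, and one finite-$N$ effect deserves emphasis.
In the rarefied model the non-activated generations form a standard-Moran
background whose merger rate is $O(N^{-2})$ — asymptotically negligible
against the activated rate $\asymp N^{-\gamma}$, but at moderate $N$ and
$\gamma$ near 2 it has not died away: for a pattern of $b$ lineages the
background binary-merger rate is $\binom{b}{2}2/(N)_2$ against an
activated multi-merger rate $\approx \lambda_N N^{-\gamma}$, a ratio
$\propto N^{\gamma - 2}$ that decays slowly. At $N = 80$, $\gamma = 1.5$,
$\psi = 0.5$, $n = 6$ the two rates are nearly equal, so about half of
all first mergers are plain binary events and the finite-$N$ jump chain
is visibly distant from the Dirac(0.5) limit — the corresponding
acceptance check documents exactly this. The package's own convergence
demonstration therefore uses $\gamma = 1.2$ at $N = 1000$, where the
background fraction is a few percent and the $\chi^2$ test accepts the
correct limit while soundly rejecting a Kingman null at the same sample
size.

What passing these tests shows — and what it does not. The simulated
data are generated by the package's own discrete models: ideal Cannings
populations with non-overlapping generations, a single multiplying parent
(Moran variants), deterministic size profiles, neutrality, and no
population structure. Agreement with the limit coalescents verifies the
mathematical construction and its implementation; it says nothing about
whether any *real* population follows these models, and none of the
machinery here infers $\rho$, $\gamma$ or $\alpha$ from data.

## Numerical conventions

* Offspring pmfs are computed in log space and normalized at the end
  (stable for $N \ge 10^3$); point-mass integrands honour $0^0 = 1$.
* Falling factorials accumulate in double precision (values such as
  $(200)_5 \approx 3\times10^{11}$ overflow integers).
* Backward indexing: $r = 0$ is the sampling generation, $t = r\,c_N$.
* Rounding: floor in the exponential recursion, banker's rounding for
  generic profiles, clamping floor $\max(2, n)$ with a warning; horizon
  exhaustion yields an *open* genealogy exported as a forest.
* Degenerate declines ($U_\mathrm{eff} \le 1$) are legal: such a
  generation simply has no multiplier and no multi-merger.
* Rarefaction feasibility ($N^{-\gamma}\lambda_N \le 1$) is checked on
  construction; infeasible sizes report the minimal admissible $N$, and
  the asymptotic regime condition ($E((U'_N)_2)/(N-1)$ bounded away from
  0) is probed heuristically on a quadrupled size and reported as a
  warning only, since no finite check can decide an asymptotic statement.
  At a fixed simulated $N$ no subsequence logic is needed or implemented.
* Newick text is written directly from the recorded merger events
  (multifurcations native); `ape` is the parser for round trips and
  `phylo` conversion.

## Limitations

Haploid models only, one multiplying parent per generation, deterministic
size profiles of order $N$; no simultaneous-multiple-merger (Ξ) limits,
no sequence simulation beyond mutation counts and positions, no
likelihoods, no inference. The growth-allocation schemes implemented are
the three named above; other allocations that would still yield a
modified Moran model exist but are not enumerated.
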