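---
title: "Institutional incentives in the collective-risk dilemma: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Institutional incentives in the collective-risk dilemma: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crdincentives)
```

## The model

The collective-risk dilemma is an N-player threshold public goods game.
A population of `Z` individuals holds two strategies, cooperate (C) and
defect (D). Groups of `N` are assembled by sampling without
replacement, so group compositions are hypergeometric. Each cooperator
contributes a fraction `c` of her endowment `B`; if fewer than `M`
cooperators are present, every group member loses her remaining
endowment with probability `r`. The game is a coordination problem
wrapped in a social dilemma: contributing is individually costly, but
too little contribution exposes everyone to the risk.

An institution can top up or dock payoffs from a fixed per-group budget
`N * delta`: a fraction `w` rewards the cooperators present (split
equally, scaled by efficiency `a`), the rest sanctions the defectors
(scaled by `b`). Two modelling points matter:

* **The budget is fixed per group, not per head.** The per-recipient
  share `a w N delta / j` (or `b (1-w) N delta / (N-j)`) diverges as the
  recipients become scarce. No cap is applied: this divergence is what
  makes sanctions so severe near full cooperation that a new
  equilibrium appears there.
* **The weight `w` is resolved from the population state `k`, not from
  the group's own composition.** The institution observes the aggregate
  level of cooperation and sets one policy for all groups; a
  state-dependent schedule switches from `w = 1` to `w = 0` at a
  cooperator fraction `s`. Group-composition-conditioned incentives are
  out of scope.

Strategy revision is pairwise social learning with exploration: a focal
individual either adopts the opposing strategy (probability `mu`) or
imitates a uniformly drawn member of the population with the Fermi
probability `[1 + exp(-beta (f_rm - f_focal))]^{-1}`. Fitness is the
expected single-round payoff over the hypergeometric distribution of
co-players (the focal individual is excluded from the sampling pool; a
focal cooperator's group therefore contains `j + 1` cooperators). The
cooperator count `k` is then a birth-death Markov chain with
transition probabilities

```
T±(k) = (k/Z) ((Z-k)/Z) [1 + exp(∓ beta (f_C(k) - f_D(k)))]^{-1}
T_mu±(k) = (1 - mu) T±(k) + mu (Z∓k···)/Z
```

(the exploration terms are `mu (Z-k)/Z` upward and `mu k/Z` downward).
The fitness of an absent strategy is undefined and never evaluated: the
`k (Z-k)` prefactor short-circuits the monomorphic states.

## Parameters

| name | meaning | default | units |
|------|---------|---------|-------|
| `Z`  | population size | 50 | individuals |
| `N`  | group size | 10 | individuals |
| `M`  | success threshold | 5 (3 for the low-threshold sweeps) | cooperators |
| `B`  | endowment | 1 | payoff |
| `c`  | cost fraction | 0.1 | — |
| `r`  | risk of collective loss | 0.5 | probability |
| `delta` | per-capita incentive budget | 0.025 (0–0.02 in budget sweeps) | payoff |
| `a`, `b` | reward / punishment efficiency | 1 | — |
| `beta` | selection intensity | 5 | 1/payoff |
| `mu` | exploration rate | 0.01 | probability |

These defaults are the study conditions under which all headline
curves are computed; `beta = 5` is strong selection (payoff differences
of order `cB = 0.1` already bias imitation noticeably), and
`mu = 0.01` is small enough to leave the selection structure intact
while making the chain ergodic.

## Numerical choices

* **Stationary distribution.** For a birth-death chain the stationary
  law has the closed product form
  `p_k ∝ prod_{i=1..k} T_mu+(i-1)/T_mu-(i)`. At `beta = 5` these
  ratios span hundreds of orders of magnitude, so the product is
  accumulated as a cumulative sum of logs and exponentiated after
  subtracting the maximum. The eigen-decomposition of the full
  tridiagonal transition matrix is kept only as a test oracle (the two
  agree to `1e-10`; detailed balance holds to `1e-12`).
* **Hypergeometric terms** are delegated to `dhyper`/`phyper`, which
  work on log-gamma internally and implicitly realise the convention
  `choose(n, r) = 0` outside the support — no case analysis is needed
  at the boundaries of the composition sums.
* **Fermi probabilities** are evaluated with `plogis`, which saturates
  to 0/1 for large `|beta * Δf|` instead of overflowing.
* **Equilibria** are reported as bracketing state pairs where the
  imitation-only gradient `G(k) = T+(k) - T-(k)` changes sign between
  adjacent interior states: + to − is a stable (coexistence) point,
  − to + an unstable (coordination) barrier. The gradient is defined
  from the mutation-free transitions — exploration is a device for
  ergodicity, not part of the selection pressure — but the
  `mutation = TRUE` variant of `gradient_of_selection()` is exposed for
  comparison; at `mu = 0.01` the two are visually indistinguishable
  away from the boundary states.

## Group achievement

`a_G(k)` is the probability that a group of `N` drawn from the whole
population (no focal exclusion — this is a census over groups, not an
individual's expectation) contains at least `M` cooperators, and
`eta_G = sum_k p_k a_G(k)` is its stationary average. *Success* here
means **reaching the threshold**, not merely escaping the risk. The
alternative reading — counting sub-threshold groups that happen not to
lose their endowment as successes, `a_G + (1 - a_G)(1 - r)` — is
available via `group_success_prob(..., risk_survival = TRUE)` but is
not the default: under it `eta_G` would tend to 1 as `r → 0` even with
no cooperation at all, which contradicts the near-zero achievement of
the unincentivized low-risk regime. The threshold reading makes
`eta_G` a genuine measure of collective target attainment.

## The optimal switching point

The defector's fitness advantage `f_D(k) - f_C(k)` is linear in the
reward weight `w`, so the advantage-minimising weight at every state is
a boundary value (bang-bang): full reward where a hypergeometrically
weighted bracket — `a/(j+1)` against a sanction term scaled by `b` —
is positive, full punishment where it is negative. The bracket
decreases in `k`, which the package asserts at run time (a warning is
raised if a parameter corner ever violated it) rather than assuming it
silently.

Its root defines the switching point `s*`. One subtlety: for `a = b`
and even `Z` the objective vanishes *exactly* on a lattice state
(`k = Z/2`), and the first strictly negative state is `Z/2 + 1`.
`optimal_switching_point()` therefore treats objective values within
`tol = 1e-9` of zero as the root itself and reports that state's
fraction — `s* = 0.5` for `Z = 50`, `N = 10`, `a = b = 1` — while also
returning `k_switch`, the first state at which sanctioning strictly
lowers the defector advantage. `s*` depends only on `Z`, `N` and
`a/b`: the threshold `M`, risk `r`, cost `c` and budget `delta` cancel
from the bracket, which the test suite verifies by sweeping them.

The runtime switching policy applies `w = 1` for `k/Z < s` and `w = 0`
at or above `s`, so the endpoint policies `s = 0` and `s = 1` reproduce
pure punishment and pure reward bit-for-bit (checked on every
`sweep_switch()` call).

## The agent-based simulator

`simulate()` realises the process event by event — draw a focal
individual, explore or imitate, update one strategy — rather than
sampling the analytic transition matrix, so its long-run occupancy is
an independent check on the closed-form stationary distribution. Two
design choices:

* **Exploration adopts the opposing strategy.** With two strategies,
  "a uniformly random *other* point of the strategy space" is the
  opposing strategy; this makes the event-level transition
  probabilities equal `T_mu±` exactly, which the tests confirm by
  comparing one-step move frequencies out of every well-visited state
  against `T_mu±` at three binomial standard errors. (Drawing uniformly
  from *both* strategies would halve the effective exploration rate.)
* **The role model is drawn from the whole population**, so a focal
  individual can draw herself (a no-op). This matches the `k/Z`
  prefactors of the transition rates.

Per-state fitnesses are precomputed once; all stochastic structure is
sampled. What the simulator emulates is exactly the well-mixed
imitation process of the analytic chain — it is an internal
consistency oracle, not a model of empirical behavioural data. Passing
its checks says the closed-form chain and the stochastic process agree;
it says nothing about how real decision-makers deviate from Fermi
imitation, about heterogeneous wealth or perception of risk, or about
structured interaction networks, none of which are modelled.

At the baseline (`Z = 50`, `M = 5`, `r = 0.5`, `delta = 0`) the
stationary law is bimodal with a coordination barrier between the
modes, and barrier crossings are rare, so the occupancy split between
the modes converges slowly. The suite compares `10^6` events (after
`10^5` burn-in) against the analytic law at a fixed seed with a 0.02
total-variation bound; at this budget the estimate still carries
Monte-Carlo error of order `10^-2`, and substantially tighter
agreement requires order-of-magnitude longer trajectories.

## Problem sizes in the test suite

Exhaustive-enumeration oracles (every co-player set, every group) are
run at `Z ≤ 12`, `N ≤ 6`; eigenvector and detailed-balance checks at
the full `Z = 50`; figure-level sweeps on 11–21-point risk grids at the
study parameters; the agent-based comparison at `1.1 × 10^6` events.
The whole suite completes in well under a minute.

## Limitations

* Well-mixed population, two pure strategies, one game — no structure,
  no conditional or mixed strategies, no repeated interaction.
* The institution's budget is exogenous; who funds it and whether
  contributing to it is itself a dilemma are not modelled.
* The switching policy observes `k` perfectly and instantaneously.
* The strictly-decreasing, single-root property of the switching
  objective is checked numerically per call, not proven for every
  parameter corner.
* The infinite-population replicator limit is out of scope; all
  quantities are finite-`Z` objects.
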