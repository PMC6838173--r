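# crdincentives

Finite-population evolutionary dynamics of the **collective-risk
dilemma** (CRD) under institutional reward and punishment.

In a CRD, groups of `N` players are sampled from a population of `Z`
cooperators (C) and defectors (D). Cooperators contribute a fraction `c`
of their endowment `B`; if a group gathers fewer than `M` cooperators,
every member loses her remaining endowment with probability `r` (the
risk). Single-round payoffs are

    Π_D(j) = B [ θ(j − M) + (1 − r)(1 − θ(j − M)) ]
    Π_C(j) = Π_D(j) − cB

with `j` cooperators in the group and `θ` the Heaviside step
(`θ(0) = 1`). An institution holds a fixed budget `Nδ` per group and
spends a fraction `w` on rewarding the cooperators present and `1 − w`
on sanctioning the defectors, with efficiencies `a` and `b`:

    Π_D^P(j) = Π_D(j) − b(1 − w)Nδ / (N − j)
    Π_C^R(j) = Π_C(j) + a w Nδ / j

Strategies spread by social learning: a focal individual imitates a
random role model with the Fermi probability
`[1 + exp(−β Δf)]^{−1}` and explores with rate `μ`, where fitness `f` is
the hypergeometric expectation of the payoff over group compositions.
The number of cooperators `k` is then a birth–death Markov chain whose
gradient of selection `G(k) = T⁺(k) − T⁻(k)`, stationary distribution
`p̄_k`, and average group achievement `η_G = Σ_k p̄_k a_G(k)` the
package computes exactly. Because the fitness advantage of defectors is
linear in `w`, the advantage-minimising incentive schedule is bang-bang:
pure reward while the cooperator fraction `k/Z` is below a switching
point `s*`, pure punishment above it; `s*` is located from the sign
change of a single hypergeometric sum and depends only on `Z`, `N` and
the efficiency ratio `a/b`.

## Worked example

```r
library(crdincentives)

m <- crd(Z = 50, N = 10, M = 5, B = 1, c = 0.1, r = 0.5,
         delta = 0, beta = 5, mu = 0.01)
m
#> Collective-risk dilemma, finite-population dynamics
#>   Z = 50, N = 10, M = 5, B = 1, c = 0.1, r = 0.5
#>   policy: pure reward (w = 1), delta = 0, a = 1, b = 1
#>   beta = 5, mu = 0.01
#>   average group achievement eta_G = 0.0162
#>   interior equilibria: 2 (unstable, stable)
```

Without incentives and at moderate risk, only 1.6% of groups reach the
target in the long run: the dynamics has a coordination barrier
(unstable equilibrium between `k = 18` and `19`) that the population
rarely crosses, and a coexistence attractor (`k = 26`–`27`) it rarely
enjoys. The optimal incentive schedule:

```r
optimal_switching_point(crd_params(Z = 50, N = 10), a = 1, b = 1)$s
#> [1] 0.5
```

With equally efficient reward and punishment, switch from rewarding to
sanctioning once half the population cooperates. Applying the budget
`δ = 0.025` on the low-threshold game (`M = 3`) across risks:

```r
tab <- sweep_risk(seq(0, 1, 0.5), crd_params(Z = 50, N = 10, M = 3),
                  delta = 0.025, s = 0.5)
reshape(tab, idvar = "r", timevar = "policy", direction = "wide")
#>     r eta_G.none eta_G.reward eta_G.punishment eta_G.switching
#> 1 0.0 0.01981907    0.5073025       0.04620127       0.5565805
#> 2 0.5 0.45129231    0.8997871       0.89625595       0.9514204
#> 3 1.0 0.88900342    0.9524457       0.98135324       0.9842648
```

Any incentive lifts group achievement above the no-policy baseline;
rewards dominate sanctions at low risk, and the switching policy beats
both everywhere. `simulate(m, nsim = 1e6, seed = 1)` runs the
agent-based counterpart of the analytic chain, and `plot(m)` draws the
gradient of selection and stationary distribution.

A thin command-line front end is installed with the package
(`exec/crd`), e.g.
`crd optimal-switch --Z 50 --N 10 --a 1 --b 1` or
`crd sweep-risk --M 3 --delta 0.025 --out achievement.csv`.

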