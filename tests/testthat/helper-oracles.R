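# Brute-force oracles, deliberately independent of the package's
# closed-form code paths: they enumerate individuals and groups
# explicitly and only work at small Z.

# Expected payoff of a focal individual by enumerating every set of
# N - 1 co-players drawn from the other Z - 1 individuals.
oracle_fitness <- function(k, params, policy, which) {
  Z <- params$Z; N <- params$N
  others <- c(rep(1L, if (which == "C") k - 1L else k),
              rep(0L, if (which == "C") Z - k else Z - 1L - k))
  sets <- utils::combn(Z - 1L, N - 1L)
  w <- policy$weight(k, Z)
  pays <- apply(sets, 2L, function(idx) {
    j_others <- sum(others[idx])
    if (which == "C") {
      j <- j_others + 1L
      base <- if (j >= params$M) params$B else params$B * (1 - params$r)
      base - params$c * params$B + policy$a * w * N * policy$delta / j
    } else {
      j <- j_others
      base <- if (j >= params$M) params$B else params$B * (1 - params$r)
      base - policy$b * (1 - w) * N * policy$delta / (N - j)
    }
  })
  mean(pays)
}

# Fraction of all size-N groups (census over the whole population) that
# contain at least M cooperators.
oracle_group_success <- function(k, params) {
  Z <- params$Z; N <- params$N
  strat <- c(rep(1L, k), rep(0L, Z - k))
  sets <- utils::combn(Z, N)
  mean(apply(sets, 2L, function(idx) sum(strat[idx]) >= params$M))
}

# Stationary distribution as the leading left eigenvector of the full
# (Z+1) x (Z+1) tridiagonal transition matrix.
oracle_stationary_eigen <- function(params, policy, dyn) {
  Z <- params$Z
  tp <- transition_probs(0:Z, params, policy, dyn, mutation = TRUE)
  P <- diag(1 - tp$T_plus - tp$T_minus)
  for (k in 0:(Z - 1L)) P[k + 1L, k + 2L] <- tp$T_plus[k + 1L]
  for (k in 1:Z) P[k + 1L, k] <- tp$T_minus[k + 1L]
  e <- eigen(t(P))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

fig2_baseline <- function() {
  list(params = crd_params(Z = 50, N = 10, M = 5, B = 1, c = 0.1, r = 0.5),
       dyn = dynamics_params(beta = 5, mu = 0.01))
}
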