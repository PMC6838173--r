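#' Structural parameters of the collective-risk dilemma
#'
#' Bundles the constants that define the game: a population of `Z`
#' individuals from which groups of `N` players are sampled without
#' replacement; each group succeeds if it contains at least `M`
#' cooperators, and otherwise every member loses her remaining endowment
#' `B` with probability `r`. Cooperators pay a fraction `c` of the
#' endowment towards the collective target; defectors pay nothing.
#'
#' @param Z Population size (positive integer).
#' @param N Group size, `0 < N <= Z`.
#' @param M Success threshold, number of cooperators a group needs,
#'   `0 < M <= N`.
#' @param B Initial endowment, in payoff units (`B > 0`).
#' @param c Cost of cooperation as a fraction of the endowment,
#'   `0 <= c <= 1`.
#' @param r Risk: probability that a group missing the threshold loses
#'   its remaining endowment, `0 <= r <= 1`.
#'
#' @return An object of class `"crd_params"`: a named list with the six
#'   validated fields.
#' @examples
#' crd_params(Z = 50, N = 10, M = 5)
#' @export
crd_params <- function(Z = 50L, N = 10L, M = 5L, B = 1, c = 0.1, r = 0.5) {
  Z <- as.integer(Z); N <- as.integer(N); M <- as.integer(M)
  stopifnot(length(Z) == 1L, length(N) == 1L, length(M) == 1L,
            length(B) == 1L, length(c) == 1L, length(r) == 1L)
  if (Z < 1L) stop("Z must be a positive integer")
  if (N < 1L || N > Z) stop("group size N must satisfy 0 < N <= Z")
  if (M < 1L || M > N) stop("threshold M must satisfy 0 < M <= N")
  if (!is.finite(B) || B <= 0) stop("endowment B must be positive")
  if (!is.finite(c) || c < 0 || c > 1) stop("cost fraction c must lie in [0, 1]")
  if (!is.finite(r) || r < 0 || r > 1) stop("risk r must lie in [0, 1]")
  structure(list(Z = Z, N = N, M = M, B = B, c = c, r = r),
            class = "crd_params")
}

#' @export
print.crd_params <- function(x, ...) {
  cat("Collective-risk dilemma parameters\n")
  cat(sprintf("  population Z = %d, group size N = %d, threshold M = %d\n",
              x$Z, x$N, x$M))
  cat(sprintf("  endowment B = %g, cost fraction c = %g, risk r = %g\n",
              x$B, x$c, x$r))
  invisible(x)
}

#' Institutional incentive policy
#'
#' An institution holds a fixed budget `N * delta` per group, of which a
#' fraction `w` is spent rewarding the cooperators present (divided
#' equally among them, scaled by efficiency `a`) and the remaining
#' `1 - w` sanctioning the defectors (scaled by efficiency `b`). The
#' weight may be a constant, or switch with the population state: pure
#' reward (`w = 1`) while the fraction of cooperators `k/Z` is below the
#' switching point `s`, pure punishment (`w = 0`) from `k/Z >= s` on.
#' The weight is resolved from the population state, not from the
#' composition of an individual group.
#'
#' @param delta Per-capita incentive budget (payoff units, `>= 0`).
#' @param a Reward efficiency (dimensionless, `>= 0`).
#' @param b Punishment efficiency (dimensionless, `>= 0`).
#' @param w Constant reward weight in `[0, 1]`. Ignored when `s` is
#'   given.
#' @param s Optional switching point, a fraction of cooperators in
#'   `[0, 1]`; when supplied the weight rule is the reward-then-punish
#'   switch described above.
#'
#' @return An object of class `"incentive_policy"` with fields `delta`,
#'   `a`, `b`, `s` (or `NULL`) and `weight`, a function mapping the
#'   state `k` and population size `Z` to the reward fraction.
#' @examples
#' incentive_policy(delta = 0.025)              # pure reward (w = 1)
#' incentive_policy(delta = 0.025, w = 0)       # pure punishment
#' incentive_policy(delta = 0.025, s = 0.5)     # reward below 50%, then punish
#' @export
incentive_policy <- function(delta = 0, a = 1, b = 1, w = 1, s = NULL) {
  stopifnot(length(delta) == 1L, is.finite(delta))
  if (delta < 0) stop("budget delta must be non-negative")
  if (!is.finite(a) || a < 0) stop("reward efficiency a must be >= 0")
  if (!is.finite(b) || b < 0) stop("punishment efficiency b must be >= 0")
  if (is.null(s)) {
    if (!is.finite(w) || w < 0 || w > 1) stop("weight w must lie in [0, 1]")
    force(w)
    weight <- function(k, Z) rep_len(w, length(k))
    label <- if (w == 1) "pure reward (w = 1)" else if (w == 0)
      "pure punishment (w = 0)" else sprintf("constant w = %g", w)
  } else {
    if (!is.finite(s) || s < 0 || s > 1) stop("switching point s must lie in [0, 1]")
    force(s)
    weight <- function(k, Z) as.numeric(k / Z < s)
    w <- NULL
    label <- sprintf("switching at k/Z = %g (reward below, punish at or above)", s)
  }
  structure(list(delta = delta, a = a, b = b, w = w, s = s,
                 weight = weight, label = label),
            class = "incentive_policy")
}

#' @export
print.incentive_policy <- function(x, ...) {
  cat("Incentive policy:", x$label, "\n")
  cat(sprintf("  per-capita budget delta = %g, efficiencies a = %g, b = %g\n",
              x$delta, x$a, x$b))
  invisible(x)
}

#' Social-learning dynamics parameters
#'
#' @param beta Intensity of selection of the Fermi imitation rule
#'   (inverse payoff units, `>= 0`); `beta = 0` is neutral drift.
#' @param mu Exploration (mutation) rate: per-event probability that the
#'   focal individual adopts the opposing strategy instead of imitating,
#'   in `[0, 1]`. A positive `mu` makes the chain ergodic.
#'
#' @return An object of class `"crd_dynamics"`.
#' @examples
#' dynamics_params(beta = 5, mu = 0.01)
#' @export
dynamics_params <- function(beta = 5, mu = 0.01) {
  if (!is.finite(beta) || beta < 0) stop("selection intensity beta must be >= 0")
  if (!is.finite(mu) || mu < 0 || mu > 1) stop("mutation rate mu must lie in [0, 1]")
  structure(list(beta = beta, mu = mu), class = "crd_dynamics")
}

#' @export
print.crd_dynamics <- function(x, ...) {
  cat(sprintf("Dynamics: selection intensity beta = %g, exploration rate mu = %g\n",
              x$beta, x$mu))
  invisible(x)
}

as_crd_params <- function(x) {
  if (inherits(x, "crd_params")) x else do.call(crd_params, as.list(x))
}
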