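#' Heaviside step function
#'
#' The threshold indicator used in the collective-risk payoffs, with the
#' convention `heaviside(0) = 1`: a group that gathers exactly the
#' required number of cooperators succeeds.
#'
#' @param x Numeric vector of finite values.
#' @return Integer vector of 0/1, `1` where `x >= 0`.
#' @examples
#' heaviside(c(-1, 0, 3))
#' @export
heaviside <- function(x) {
  if (!all(is.finite(x))) stop("heaviside requires finite arguments")
  as.integer(x >= 0)
}

#' Single-round payoffs in the collective-risk dilemma
#'
#' In a group of `N` players with `j` cooperators, every player keeps
#' the endowment `B` if the group reaches the threshold `M`; otherwise
#' all keep only the expected fraction `1 - r` of it. Cooperators
#' additionally pay the contribution `c * B`. `payoff_defector_base()`
#' and `payoff_cooperator_base()` give these baseline payoffs;
#' `payoff_defector_incentivized()` and
#' `payoff_cooperator_incentivized()` add the institutional incentive: a
#' group budget `N * delta` of which a fraction `w` is split equally
#' among the `j` cooperators as a reward (scaled by efficiency `a`) and
#' `1 - w` among the `N - j` defectors as a sanction (scaled by `b`).
#' The budget is fixed per group and divided among whoever is present,
#' so the per-head share grows without bound as `j` approaches `0` or
#' `N` — this divergence is deliberate and drives the emergence of a
#' near-full-cooperation equilibrium under strong sanctioning.
#'
#' @param j Number of cooperators in the group (vectorised). A defector's
#'   group satisfies `0 <= j <= N - 1` for the incentivized payoff (at
#'   least the focal defector is present); a cooperator's group requires
#'   `j >= 1`.
#' @param params A [crd_params()] object.
#' @param policy An [incentive_policy()] object supplying `delta`, `a`, `b`.
#' @param w Reward fraction in `[0, 1]` already resolved from the
#'   population state (see [incentive_policy()]).
#' @return Numeric vector of payoffs.
#' @examples
#' p <- crd_params(Z = 50, N = 10, M = 5, B = 1, c = 0.1, r = 0.5)
#' payoff_defector_base(4:5, p)
#' payoff_cooperator_base(4:5, p)
#' pol <- incentive_policy(delta = 0.02, a = 1, b = 1)
#' payoff_defector_incentivized(5, p, pol, w = 0)
#' @export
payoff_defector_base <- function(j, params) {
  params <- as_crd_params(params)
  if (any(j < 0 | j > params$N)) stop("cooperator count j out of range [0, N]")
  met <- heaviside(j - params$M)
  params$B * (met + (1 - params$r) * (1 - met))
}

#' @rdname payoff_defector_base
#' @export
payoff_cooperator_base <- function(j, params) {
  params <- as_crd_params(params)
  if (any(j < 1)) stop("a cooperator's group contains at least herself (j >= 1)")
  payoff_defector_base(j, params) - params$c * params$B
}

#' @rdname payoff_defector_base
#' @export
payoff_defector_incentivized <- function(j, params, policy, w) {
  params <- as_crd_params(params)
  if (any(j > params$N - 1L)) stop("a defector's group has at most N - 1 cooperators")
  payoff_defector_base(j, params) -
    policy$b * (1 - w) * params$N * policy$delta / (params$N - j)
}

#' @rdname payoff_defector_base
#' @export
payoff_cooperator_incentivized <- function(j, params, policy, w) {
  params <- as_crd_params(params)
  if (any(j < 1)) stop("a cooperator's group contains at least herself (j >= 1)")
  payoff_cooperator_base(j, params) +
    policy$a * w * params$N * policy$delta / j
}
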