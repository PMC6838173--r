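#' Probability that a randomly formed group succeeds
#'
#' With `k` cooperators among `Z` individuals, a group of `N` sampled
#' without replacement from the whole population contains at least `M`
#' cooperators with hypergeometric tail probability; that is the group
#' success probability `a_G(k)`. Unlike fitness sampling, no focal
#' individual is excluded: this is a census over all groups the
#' population can form. Success means reaching the contribution
#' threshold; optionally, `risk_survival = TRUE` also counts
#' sub-threshold groups that escape the risk, giving
#' `a_G + (1 - a_G)(1 - r)`.
#'
#' @param k Population state(s), `0 <= k <= Z` (vectorised).
#' @param params A [crd_params()] object.
#' @param risk_survival Count sub-threshold groups that keep their
#'   endowment (survive the risk) as successes. Default `FALSE`:
#'   success is reaching the threshold.
#' @return Numeric vector of probabilities, non-decreasing in `k`.
#' @examples
#' p <- crd_params(Z = 10, N = 5, M = 2)
#' group_success_prob(0:10, p)
#' @export
group_success_prob <- function(k, params, risk_survival = FALSE) {
  params <- as_crd_params(params)
  if (any(k < 0L | k > params$Z)) stop("k must lie in [0, Z]")
  a <- stats::phyper(params$M - 1L, k, params$Z - k, params$N,
                     lower.tail = FALSE)
  if (risk_survival) a <- a + (1 - a) * (1 - params$r)
  a
}

#' Average group achievement
#'
#' The headline cooperation metric: the stationary-weighted mean of the
#' per-state group success probability,
#' `eta_G = sum_k p_k a_G(k)` — the long-run fraction of groups that
#' reach the collective target.
#'
#' @param p_bar Stationary distribution over `k = 0..Z` (sums to 1).
#' @param a_G Per-state group success probabilities, same length.
#' @return A single probability in `[0, 1]`.
#' @examples
#' p <- crd_params(Z = 20, N = 5, M = 3)
#' pbar <- stationary_distribution(p, incentive_policy(), dynamics_params())
#' group_achievement(pbar, group_success_prob(0:20, p))
#' @export
group_achievement <- function(p_bar, a_G) {
  if (length(p_bar) != length(a_G))
    stop("p_bar and a_G must have the same length (Z + 1)")
  if (abs(sum(p_bar) - 1) > 1e-8)
    stop("p_bar must be a normalized probability vector")
  sum(p_bar * a_G)
}
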