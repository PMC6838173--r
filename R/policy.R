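#' Defector-advantage objective for the reward/punishment split
#'
#' Because the incentivized fitness difference `f_D - f_C` is linear in
#' the reward weight `w`, choosing the weight that minimises the
#' defector's advantage at a state `k` reduces to the sign of a single
#' hypergeometric sum: over group compositions `j` (cooperators among a
#' cooperator's co-players),
#' \deqn{\sum_j \frac{\binom{k-1}{j}\binom{Z-k}{N-1-j}}{\binom{Z-1}{N-1}}
#'   \left[\frac{a}{j+1} - \frac{b}{N-j}\,\frac{k}{k-j}\,
#'   \frac{Z-k-N+1+j}{Z-k}\right].}
#' A positive value means a marginal unit of budget lowers the
#' defector's advantage more when spent on rewards; negative, on
#' sanctions. The sum decreases in `k` and has a single root, so the
#' advantage-minimising policy is bang-bang: pure reward below the root,
#' pure punishment above it. Terms outside the hypergeometric support
#' (where the weight is zero) are dropped, which also keeps the
#' `k - j` factor well defined.
#'
#' @param k Population state(s), `1 <= k <= Z - 1` (both strategies
#'   present; vectorised).
#' @param params A [crd_params()] object (only `Z` and `N` enter).
#' @param a,b Reward and punishment efficiencies (`>= 0`, not both 0).
#' @return Numeric vector: the value of the objective at each `k`.
#' @examples
#' p <- crd_params(Z = 50, N = 10)
#' sign(switching_objective(c(10, 40), p))
#' @export
switching_objective <- function(k, params, a = 1, b = 1) {
  params <- as_crd_params(params)
  Z <- params$Z; N <- params$N
  if (any(k < 1L | k > Z - 1L))
    stop("objective is defined for interior states 1 <= k <= Z - 1")
  if (a < 0 || b < 0) stop("efficiencies must be non-negative")
  j <- 0:(N - 1L)
  vapply(k, function(ki) {
    wgt <- stats::dhyper(j, ki - 1L, Z - ki, N - 1L)
    on <- wgt > 0
    term <- a / (j[on] + 1) -
      (b / (N - j[on])) * (ki / (ki - j[on])) *
      ((Z - ki - N + 1 + j[on]) / (Z - ki))
    sum(wgt[on] * term)
  }, numeric(1))
}

#' Optimal reward-to-punishment switching point
#'
#' Locates the root of [switching_objective()] over the interior states:
#' the fraction of cooperators `s* = k/Z` at which the
#' advantage-minimising policy flips from pure reward to pure
#' punishment. The objective is checked to be decreasing in `k` (it is
#' claimed, not proven, to have a single root; a violation raises a
#' warning rather than being silently accepted). States where the
#' objective vanishes to within `tol` are treated as the root itself, so
#' an exact crossing on a lattice state (as happens for `a = b` with
#' even `Z`) is reported at that state. If the objective is already
#' negative at `k = 1` the smallest admissible switching point `1/Z` is
#' returned (always punish); if it never turns negative, `s* = 1`
#' (always reward).
#'
#' @inheritParams switching_objective
#' @param tol Numerical tolerance for treating an objective value as
#'   zero.
#' @return A list with `s` (the switching fraction `s*`), `k_switch`
#'   (the smallest state at which punishment applies) and `objective`
#'   (the objective values over `k = 1..Z-1`).
#' @examples
#' optimal_switching_point(crd_params(Z = 50, N = 10), a = 1, b = 1)$s
#' @export
optimal_switching_point <- function(params, a = 1, b = 1, tol = 1e-9) {
  params <- as_crd_params(params)
  if (a == 0 && b == 0)
    stop("a = b = 0 leaves the objective identically zero")
  Z <- params$Z
  ks <- 1:(Z - 1L)
  obj <- switching_objective(ks, params, a = a, b = b)
  if (any(diff(obj) > tol))
    warning("switching objective is not monotonically decreasing in k")
  below <- which(obj < tol)
  if (length(below) == 0L) {
    s <- 1; k_switch <- Z  # never switch: reward throughout
  } else {
    k_root <- ks[below[1L]]
    s <- k_root / Z
    # punishment applies from the first strictly negative state on
    neg <- which(obj < -tol)
    k_switch <- if (length(neg)) ks[neg[1L]] else Z
  }
  list(s = s, k_switch = as.integer(k_switch), objective = obj)
}

#' Advantage-minimising weight at a single state
#'
#' The objective is linear in `w`, so its optimum over `[0, 1]` sits at
#' a boundary: full reward where the objective is non-negative, full
#' punishment where it is negative (bang-bang control).
#'
#' @inheritParams switching_objective
#' @return Vector of 0/1 weights, one per state in `k`.
#' @examples
#' p <- crd_params(Z = 50, N = 10)
#' optimal_w_per_state(c(10, 25, 40), p)
#' @export
optimal_w_per_state <- function(k, params, a = 1, b = 1) {
  as.numeric(switching_objective(k, params, a = a, b = b) >= 0)
}
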