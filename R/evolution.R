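#' Probability of a group composition around a focal individual
#'
#' Groups are assembled by sampling `N - 1` co-players without
#' replacement from the `Z - 1` other members of the population, so the
#' number of cooperators among the co-players is hypergeometric. A focal
#' cooperator leaves `k - 1` cooperators available; a focal defector
#' leaves `k`. Compositions outside the hypergeometric support have
#' probability zero.
#'
#' @param j Number of cooperators among the `N - 1` co-players
#'   (vectorised, `0 <= j <= N - 1`).
#' @param k Number of cooperators in the population, `0 <= k <= Z`.
#' @param focal `"C"` or `"D"`, the strategy of the focal individual.
#' @param params A [crd_params()] object.
#' @return Numeric vector of probabilities.
#' @examples
#' p <- crd_params(Z = 6, N = 3, M = 2)
#' group_composition_prob(0:2, k = 3, focal = "C", p)  # sums to 1
#' @export
group_composition_prob <- function(j, k, focal = c("C", "D"), params) {
  params <- as_crd_params(params)
  focal <- match.arg(focal)
  Z <- params$Z; N <- params$N
  if (any(j < 0 | j > N - 1L)) stop("j must lie in [0, N - 1]")
  if (k < 0L || k > Z) stop("k must lie in [0, Z]")
  if (focal == "C" && k < 1L) stop("no cooperator present at k = 0")
  if (focal == "D" && k > Z - 1L) stop("no defector present at k = Z")
  avail <- if (focal == "C") k - 1L else k
  stats::dhyper(j, avail, Z - 1L - avail, N - 1L)
}

#' Expected payoff (fitness) of a strategy at a population state
#'
#' The fitness of a cooperator (defector) with `k` cooperators in the
#' population is the expectation of her single-round incentivized payoff
#' over the hypergeometric distribution of group compositions. The
#' reward fraction `w` is resolved from the population state via the
#' policy's weight rule before payoffs are evaluated.
#'
#' @inheritParams group_composition_prob
#' @param k Population state(s), vectorised.
#' @param policy An [incentive_policy()] object.
#' @param which `"C"` or `"D"`: which strategy's fitness to evaluate.
#'   Requesting the fitness of an absent strategy (`"C"` at `k = 0`,
#'   `"D"` at `k = Z`) is an error.
#' @return Numeric vector of fitnesses, one per element of `k`.
#' @examples
#' p <- crd_params(Z = 50, N = 10, M = 5)
#' fitness(1, p, incentive_policy(), which = "C")  # lone cooperator
#' @export
fitness <- function(k, params, policy = incentive_policy(), which = c("C", "D")) {
  params <- as_crd_params(params)
  which <- match.arg(which)
  Z <- params$Z; N <- params$N
  if (any(k < 0L | k > Z)) stop("k must lie in [0, Z]")
  if (which == "C" && any(k < 1L)) stop("fitness of an absent strategy (C at k = 0)")
  if (which == "D" && any(k > Z - 1L)) stop("fitness of an absent strategy (D at k = Z)")
  j <- 0:(N - 1L)
  w_k <- policy$weight(k, Z)
  vapply(seq_along(k), function(i) {
    ki <- k[i]
    if (which == "C") {
      probs <- stats::dhyper(j, ki - 1L, Z - ki, N - 1L)
      pay <- payoff_cooperator_incentivized(j + 1L, params, policy, w_k[i])
    } else {
      probs <- stats::dhyper(j, ki, Z - 1L - ki, N - 1L)
      pay <- payoff_defector_incentivized(j, params, policy, w_k[i])
    }
    sum(probs * pay)
  }, numeric(1))
}

#' Fermi imitation probability
#'
#' Probability that a focal individual adopts the strategy of a role
#' model, a logistic function of the fitness difference with slope set
#' by the intensity of selection. Saturates to 0/1 for large
#' `|beta * (f_rm - f_focal)|` without overflow.
#'
#' @param f_role_model,f_focal Fitness of the role model and of the
#'   focal individual (vectorised).
#' @param dyn A [dynamics_params()] object (only `beta` is used).
#' @return Numeric vector of probabilities.
#' @examples
#' imitation_prob(1, 1, dynamics_params(beta = 5))   # 0.5
#' @export
imitation_prob <- function(f_role_model, f_focal, dyn = dynamics_params()) {
  stats::plogis(dyn$beta * (f_role_model - f_focal))
}

#' Birth-death transition probabilities of the cooperator count
#'
#' At each elementary event a focal individual is drawn uniformly; with
#' probability `mu` she adopts the opposing strategy (exploration), and
#' otherwise imitates a uniformly drawn member of the population with
#' the Fermi probability. The cooperator count `k` then increases or
#' decreases by one with probabilities
#' `T^+(k) = (k/Z)((Z-k)/Z) / (1 + exp(-beta (f_C - f_D)))` and
#' `T^-(k)` with the opposite sign in the exponent; the exploration
#' terms add `mu (Z-k)/Z` and `mu k/Z` respectively. The `k (Z - k)`
#' prefactor vanishes at the monomorphic states, so fitnesses of absent
#' strategies are never evaluated.
#'
#' @inheritParams fitness
#' @param dyn A [dynamics_params()] object.
#' @param mutation If `TRUE`, return the exploration-augmented
#'   probabilities `T_mu^±`; otherwise the imitation-only `T^±`.
#' @return A data frame with columns `k`, `T_plus`, `T_minus`.
#' @examples
#' p <- crd_params(Z = 20, N = 5, M = 3)
#' transition_probs(0:20, p, incentive_policy(), dynamics_params())
#' @export
transition_probs <- function(k, params, policy = incentive_policy(),
                             dyn = dynamics_params(), mutation = FALSE) {
  params <- as_crd_params(params)
  Z <- params$Z
  if (any(k < 0L | k > Z)) stop("k must lie in [0, Z]")
  interior <- k > 0L & k < Z
  df <- numeric(length(k))  # f_C - f_D, only needed where both exist
  if (any(interior)) {
    ki <- k[interior]
    df[interior] <- fitness(ki, params, policy, "C") -
      fitness(ki, params, policy, "D")
  }
  pref <- (k / Z) * ((Z - k) / Z)
  T_plus <- pref * stats::plogis(dyn$beta * df)
  T_minus <- pref * stats::plogis(-dyn$beta * df)
  if (mutation) {
    T_plus <- (1 - dyn$mu) * T_plus + dyn$mu * (Z - k) / Z
    T_minus <- (1 - dyn$mu) * T_minus + dyn$mu * k / Z
  }
  data.frame(k = k, T_plus = T_plus, T_minus = T_minus)
}

#' Gradient of selection
#'
#' The per-state difference `G(k) = T^+(k) - T^-(k)` between the
#' probabilities of gaining and losing one cooperator: its sign gives
#' the most likely direction of evolution, and sign changes across
#' adjacent states are the finite-population analogues of fixed points.
#' By default the imitation-only transitions are used; set
#' `mutation = TRUE` for the exploration-augmented variant.
#'
#' @inheritParams transition_probs
#' @return Numeric vector `G(k)` for `k = 0..Z`.
#' @examples
#' p <- crd_params(Z = 50, N = 10, M = 5)
#' G <- gradient_of_selection(p, incentive_policy(), dynamics_params(beta = 5))
#' find_equilibria(G)
#' @export
gradient_of_selection <- function(params, policy = incentive_policy(),
                                  dyn = dynamics_params(), mutation = FALSE) {
  params <- as_crd_params(params)
  tp <- transition_probs(0:params$Z, params, policy, dyn, mutation = mutation)
  tp$T_plus - tp$T_minus
}

#' Stationary distribution of the cooperator count
#'
#' With a positive exploration rate the birth-death chain is ergodic and
#' its unique stationary distribution has the closed form
#' `p_k` proportional to the product over `i = 1..k` of
#' `T_mu^+(i-1) / T_mu^-(i)`. The product is accumulated in log space
#' and normalised, which stays well conditioned at strong selection
#' (`beta >= 5`) where the ratios span many orders of magnitude.
#'
#' @inheritParams transition_probs
#' @return Numeric vector of probabilities over `k = 0..Z`, summing to 1.
#' @examples
#' p <- crd_params(Z = 50, N = 10, M = 5)
#' pbar <- stationary_distribution(p, incentive_policy(), dynamics_params())
#' sum(pbar)
#' @export
stationary_distribution <- function(params, policy = incentive_policy(),
                                    dyn = dynamics_params()) {
  params <- as_crd_params(params)
  if (dyn$mu <= 0)
    stop("stationary distribution requires mu > 0 (the chain is absorbing otherwise)")
  Z <- params$Z
  tp <- transition_probs(0:Z, params, policy, dyn, mutation = TRUE)
  # log p_k - log p_0 = sum_{i=1..k} log T+(i-1) - log T-(i)
  logratio <- log(tp$T_plus[1:Z]) - log(tp$T_minus[2:(Z + 1L)])
  logp <- c(0, cumsum(logratio))
  p <- exp(logp - max(logp))
  p / sum(p)
}

#' Finite-population equilibria from a gradient of selection
#'
#' Scans adjacent interior states for sign changes of `G`. A change from
#' positive to negative marks a stable (coexistence) equilibrium that
#' attracts the cooperator fraction; negative to positive marks an
#' unstable (coordination) equilibrium acting as a barrier. Locations
#' are reported as the bracketing state pair.
#'
#' @param G Numeric gradient vector over `k = 0..Z` (length `Z + 1`).
#' @return A data frame with columns `k_lower`, `k_upper`, `type`
#'   (`"stable"` or `"unstable"`); zero rows when the interior gradient
#'   never changes sign.
#' @examples
#' find_equilibria(c(0, 1, 1, -1, 0))  # one stable crossing on Z = 4
#' @export
find_equilibria <- function(G) {
  Z <- length(G) - 1L
  if (Z < 2L) stop("gradient must cover at least states 0..2")
  ks <- 1:(Z - 1L)
  g <- G[ks + 1L]  # interior values G(1)..G(Z-1)
  out <- data.frame(k_lower = integer(0), k_upper = integer(0),
                    type = character(0), stringsAsFactors = FALSE)
  if (Z < 3L) return(out)
  for (i in seq_len(length(ks) - 1L)) {
    if (g[i] > 0 && g[i + 1L] < 0) {
      out <- rbind(out, data.frame(k_lower = ks[i], k_upper = ks[i + 1L],
                                   type = "stable", stringsAsFactors = FALSE))
    } else if (g[i] < 0 && g[i + 1L] > 0) {
      out <- rbind(out, data.frame(k_lower = ks[i], k_upper = ks[i + 1L],
                                   type = "unstable", stringsAsFactors = FALSE))
    }
  }
  out
}
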