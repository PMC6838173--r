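#' Agent-based simulation of the social-learning process
#'
#' Stochastic counterpart of the analytic chain in [crd()], built from
#' the elementary event rather than the closed-form transition rates: a
#' focal individual is drawn uniformly from the population; with
#' probability `mu` she explores, adopting the opposing strategy;
#' otherwise she draws a role model uniformly from the whole population
#' (drawing herself changes nothing) and imitates with the Fermi
#' probability of the fitness difference. The cooperator count after
#' each event is recorded. Per-state fitnesses are precomputed once;
#' everything else is sampled, so the long-run occupancy of the
#' trajectory is an independent check on the closed-form stationary
#' distribution.
#'
#' @param object A [crd()] model.
#' @param nsim Number of elementary update events.
#' @param seed Optional integer seed, recorded in the result.
#' @param burn_in Number of leading events that
#'   [empirical_distribution()] discards (`0 <= burn_in < nsim`).
#' @param k0 Initial number of cooperators; defaults to `Z / 2`
#'   (rounded).
#' @param ... Unused.
#' @return An object of class `"crd_sim"`: list with `states` (integer
#'   vector of `k` after each event), `k0`, `burn_in`, `seed`, `Z` and
#'   `steps`.
#' @examples
#' m <- crd(Z = 20, N = 5, M = 3)
#' sim <- simulate(m, nsim = 2000, seed = 1, burn_in = 500)
#' head(empirical_distribution(sim))
#' @export
simulate.crd <- function(object, nsim = 1e5, seed = NULL, burn_in = 0,
                         k0 = NULL, ...) {
  stopifnot(nsim >= 1, burn_in >= 0, burn_in < nsim)
  if (!is.null(seed)) set.seed(seed)
  Z <- object$params$Z
  mu <- object$dyn$mu
  beta <- object$dyn$beta
  if (is.null(k0)) k0 <- as.integer(round(Z / 2))
  if (k0 < 0L || k0 > Z) stop("k0 must lie in [0, Z]")

  f_C <- object$profile$f_C  # NA at k = 0, never read there
  f_D <- object$profile$f_D  # NA at k = Z
  # imitation acceptance probabilities per interior state, one per direction
  p_up <- stats::plogis(beta * (f_C - f_D))    # D imitates C
  p_dn <- stats::plogis(-beta * (f_C - f_D))   # C imitates D

  states <- integer(nsim)
  u_focal <- stats::runif(nsim)
  u_mut <- stats::runif(nsim)
  u_rm <- stats::runif(nsim)
  u_acc <- stats::runif(nsim)

  k <- as.integer(k0)
  for (t in seq_len(nsim)) {
    focal_C <- u_focal[t] * Z < k
    if (u_mut[t] < mu) {
      k <- if (focal_C) k - 1L else k + 1L
    } else {
      rm_C <- u_rm[t] * Z < k
      if (rm_C != focal_C) {
        if (rm_C) {                       # focal defector meets cooperator
          if (u_acc[t] < p_up[k + 1L]) k <- k + 1L
        } else {                          # focal cooperator meets defector
          if (u_acc[t] < p_dn[k + 1L]) k <- k - 1L
        }
      }
    }
    states[t] <- k
  }

  structure(list(states = states, k0 = as.integer(k0),
                 burn_in = as.integer(burn_in),
                 seed = seed, Z = Z, steps = as.integer(nsim)),
            class = "crd_sim")
}

#' @export
print.crd_sim <- function(x, ...) {
  kept <- x$steps - x$burn_in
  cat(sprintf("Agent-based trajectory: %d events (%d after burn-in), Z = %d\n",
              x$steps, kept, x$Z))
  cat(sprintf("  start k0 = %d, seed = %s, mean k/Z after burn-in = %.3f\n",
              x$k0, if (is.null(x$seed)) "unset" else x$seed,
              mean(x$states[(x$burn_in + 1L):x$steps]) / x$Z))
  invisible(x)
}

#' Occupancy histogram of a simulated trajectory
#'
#' Normalised time the trajectory spends in each population state after
#' the burn-in prefix is discarded.
#'
#' @param sim A `"crd_sim"` object from [simulate.crd()].
#' @return Numeric vector over `k = 0..Z`, summing to 1.
#' @export
empirical_distribution <- function(sim) {
  stopifnot(inherits(sim, "crd_sim"))
  kept <- sim$states[(sim$burn_in + 1L):sim$steps]
  if (length(kept) == 0L) stop("no states left after burn-in")
  tabulate(kept + 1L, nbins = sim$Z + 1L) / length(kept)
}

#' Total-variation distance between two distributions
#'
#' @param p,q Probability vectors of equal length.
#' @return `sum(abs(p - q)) / 2`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(p - q)) / 2
}
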