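#' Evolutionary model of the collective-risk dilemma
#'
#' Builds the full birth-death description of the social-learning
#' dynamics for one parameter set: per-state fitnesses of cooperators
#' and defectors under hypergeometric group sampling, transition
#' probabilities with and without exploration, the gradient of
#' selection and its interior equilibria, the stationary distribution,
#' the per-state group success probability and the average group
#' achievement `eta_G`.
#'
#' Parameters may be given flat (the usual call) or as pre-built
#' [crd_params()], [incentive_policy()] and [dynamics_params()] objects,
#' which take precedence over the corresponding flat arguments.
#'
#' @param Z,N,M,B,c,r Game constants, see [crd_params()].
#' @param delta,a,b,w,s Incentive policy, see [incentive_policy()]:
#'   per-capita budget, efficiencies, constant reward weight, or a
#'   switching point `s` (reward below `k/Z = s`, punishment at or
#'   above).
#' @param beta,mu Selection intensity and exploration rate, see
#'   [dynamics_params()].
#' @param params,policy,dyn Optional pre-built parameter objects.
#' @param risk_survival Passed to [group_success_prob()].
#'
#' @return An object of class `"crd"`: a list with the parameter
#'   objects, `profile` (a data frame over `k = 0..Z` with columns `k`,
#'   `k_over_Z`, `f_C`, `f_D`, `T_plus`, `T_minus`, `T_mu_plus`,
#'   `T_mu_minus`, `G`, `p_bar`, `a_G`; fitnesses of absent strategies
#'   are `NA`), `equilibria` (see [find_equilibria()]) and `eta_G`.
#'
#' @examples
#' m <- crd(Z = 50, N = 10, M = 5, r = 0.5, delta = 0.02, w = 0)
#' m
#' summary(m)
#' @seealso [simulate.crd()] for the agent-based counterpart,
#'   [sweep_risk()] and friends for parameter sweeps.
#' @export
crd <- function(Z = 50, N = 10, M = 5, B = 1, c = 0.1, r = 0.5,
                delta = 0, a = 1, b = 1, w = 1, s = NULL,
                beta = 5, mu = 0.01,
                params = NULL, policy = NULL, dyn = NULL,
                risk_survival = FALSE) {
  if (is.null(params)) params <- crd_params(Z, N, M, B, c, r)
  if (is.null(policy)) policy <- incentive_policy(delta, a, b, w, s)
  if (is.null(dyn)) dyn <- dynamics_params(beta, mu)
  Z <- params$Z
  k <- 0:Z

  f_C <- c(NA_real_, fitness(1:Z, params, policy, "C"))
  f_D <- c(fitness(0:(Z - 1L), params, policy, "D"), NA_real_)

  dfit <- ifelse(k == 0L | k == Z, 0, f_C - f_D)
  pref <- (k / Z) * ((Z - k) / Z)
  T_plus <- pref * stats::plogis(dyn$beta * dfit)
  T_minus <- pref * stats::plogis(-dyn$beta * dfit)
  T_mu_plus <- (1 - dyn$mu) * T_plus + dyn$mu * (Z - k) / Z
  T_mu_minus <- (1 - dyn$mu) * T_minus + dyn$mu * k / Z
  G <- T_plus - T_minus

  p_bar <- if (dyn$mu > 0) {
    logratio <- log(T_mu_plus[1:Z]) - log(T_mu_minus[2:(Z + 1L)])
    logp <- c(0, cumsum(logratio))
    p <- exp(logp - max(logp))
    p / sum(p)
  } else rep(NA_real_, Z + 1L)

  a_G <- group_success_prob(k, params, risk_survival = risk_survival)
  eta_G <- if (dyn$mu > 0) sum(p_bar * a_G) else NA_real_

  profile <- data.frame(k = k, k_over_Z = k / Z, f_C = f_C, f_D = f_D,
                        T_plus = T_plus, T_minus = T_minus,
                        T_mu_plus = T_mu_plus, T_mu_minus = T_mu_minus,
                        G = G, p_bar = p_bar, a_G = a_G)

  structure(list(params = params, policy = policy, dyn = dyn,
                 profile = profile,
                 equilibria = find_equilibria(G),
                 eta_G = eta_G,
                 risk_survival = risk_survival),
            class = "crd")
}

#' @export
print.crd <- function(x, ...) {
  p <- x$params
  cat("Collective-risk dilemma, finite-population dynamics\n")
  cat(sprintf("  Z = %d, N = %d, M = %d, B = %g, c = %g, r = %g\n",
              p$Z, p$N, p$M, p$B, p$c, p$r))
  cat(sprintf("  policy: %s, delta = %g, a = %g, b = %g\n",
              x$policy$label, x$policy$delta, x$policy$a, x$policy$b))
  cat(sprintf("  beta = %g, mu = %g\n", x$dyn$beta, x$dyn$mu))
  if (!is.na(x$eta_G))
    cat(sprintf("  average group achievement eta_G = %.4f\n", x$eta_G))
  neq <- nrow(x$equilibria)
  cat(sprintf("  interior equilibria: %d%s\n", neq,
              if (neq) paste0(" (", paste(x$equilibria$type, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' @export
summary.crd <- function(object, ...) {
  pr <- object$profile
  out <- list(model = object,
              eta_G = object$eta_G,
              equilibria = object$equilibria,
              mean_coop = if (!is.na(object$eta_G))
                sum(pr$p_bar * pr$k_over_Z) else NA_real_,
              mode_k = if (!is.na(object$eta_G))
                pr$k[which.max(pr$p_bar)] else NA_integer_)
  class(out) <- "summary.crd"
  out
}

#' @export
print.summary.crd <- function(x, ...) {
  print(x$model)
  if (!is.na(x$eta_G)) {
    cat(sprintf("  stationary mean fraction of cooperators: %.4f\n", x$mean_coop))
    cat(sprintf("  most visited state: k = %d\n", x$mode_k))
  }
  if (nrow(x$equilibria)) {
    cat("  equilibria (bracketing states):\n")
    print(x$equilibria, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.crd <- function(object, ...) {
  p <- object$params; pol <- object$policy; d <- object$dyn
  c(Z = p$Z, N = p$N, M = p$M, B = p$B, c = p$c, r = p$r,
    delta = pol$delta, a = pol$a, b = pol$b,
    w = if (is.null(pol$w)) NA_real_ else pol$w,
    s = if (is.null(pol$s)) NA_real_ else pol$s,
    beta = d$beta, mu = d$mu)
}

#' @export
as.data.frame.crd <- function(x, ...) x$profile

#' Plot gradient of selection and stationary distribution
#'
#' Two stacked base-graphics panels in the layout used throughout this
#' literature: the gradient of selection `G(k)` (top, with its zero
#' line) and the stationary distribution (bottom), both against the
#' fraction of cooperators `k/Z`.
#'
#' @param x A [crd()] object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.crd <- function(x, ...) {
  pr <- x$profile
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(pr$k_over_Z, pr$G, type = "l", xlab = "", col = "steelblue",
                 ylab = "gradient of selection G(k)", ...)
  graphics::abline(h = 0, lty = 3)
  if (nrow(x$equilibria))
    graphics::points((x$equilibria$k_lower + 0.5) / x$params$Z,
                     rep(0, nrow(x$equilibria)),
                     pch = ifelse(x$equilibria$type == "stable", 19, 1))
  graphics::plot(pr$k_over_Z, pr$p_bar, type = "h", col = "grey40",
                 xlab = "fraction of cooperators k/Z",
                 ylab = "stationary probability")
  invisible(x)
}

#' Export a chain profile as CSV
#'
#' Writes the per-state profile of a [crd()] model (fitnesses,
#' transition probabilities, gradient, stationary distribution) to a
#' CSV file.
#'
#' @param x A [crd()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  stopifnot(inherits(x, "crd"))
  utils::write.csv(x$profile, path, row.names = FALSE)
  invisible(path)
}
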