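#' Parameter sweeps over the figure grids
#'
#' Drivers that regenerate the model's headline curves as tidy tables.
#' `sweep_risk()` computes the average group achievement `eta_G` across
#' a risk grid for four policies: no incentives, pure reward, pure
#' punishment, and the reward-then-punish switch at `s`.
#' `sweep_switch()` sweeps the switching point itself (its endpoints
#' `s = 0` and `s = 1` are checked to reproduce the pure policies
#' exactly). `sweep_delta()` returns the full chain profile (gradient
#' and stationary distribution) across a budget grid for pure reward
#' and pure punishment. `sweep_ab()` maps the efficiency ratio `a/b`
#' to the optimal switching point `s*`.
#'
#' @param risks Numeric grid of risk values in `[0, 1]`.
#' @param params A [crd_params()] object; its `r` field is overridden
#'   by the grid in `sweep_risk()`.
#' @param delta Per-capita incentive budget for the incentivized
#'   policies.
#' @param a,b Reward and punishment efficiencies.
#' @param s Switching point used for the combined policy in
#'   `sweep_risk()`.
#' @param dyn A [dynamics_params()] object.
#' @return `sweep_risk()`: a data frame with columns `r`, `policy`,
#'   `eta_G`.
#' @examples
#' p <- crd_params(Z = 50, N = 10, M = 3)
#' head(sweep_risk(seq(0, 1, 0.25), p, delta = 0.025))
#' @export
sweep_risk <- function(risks = seq(0, 1, length.out = 21),
                       params = crd_params(), delta = 0.025,
                       a = 1, b = 1, s = 0.5,
                       dyn = dynamics_params()) {
  check_grid(risks, 0, 1)
  policies <- list(
    none = incentive_policy(delta = 0, a = a, b = b, w = 1),
    reward = incentive_policy(delta = delta, a = a, b = b, w = 1),
    punishment = incentive_policy(delta = delta, a = a, b = b, w = 0),
    switching = incentive_policy(delta = delta, a = a, b = b, s = s)
  )
  out <- expand.grid(r = risks, policy = names(policies),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$eta_G <- mapply(function(r, pol) {
    p <- crd_params(params$Z, params$N, params$M, params$B, params$c, r)
    crd(params = p, policy = policies[[pol]], dyn = dyn)$eta_G
  }, out$r, out$policy)
  out
}

#' @rdname sweep_risk
#' @param s_grid Grid of switching points in `[0, 1]`.
#' @return `sweep_switch()`: a data frame with columns `s`, `r`,
#'   `eta_G`.
#' @export
sweep_switch <- function(s_grid = seq(0, 1, length.out = 21),
                         risks = 0.5,
                         params = crd_params(M = 3), delta = 0.025,
                         a = 1, b = 1, dyn = dynamics_params()) {
  check_grid(s_grid, 0, 1)
  check_grid(risks, 0, 1)
  out <- expand.grid(s = s_grid, r = risks,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$eta_G <- mapply(function(s, r) {
    p <- crd_params(params$Z, params$N, params$M, params$B, params$c, r)
    crd(params = p,
        policy = incentive_policy(delta = delta, a = a, b = b, s = s),
        dyn = dyn)$eta_G
  }, out$s, out$r)
  # endpoint consistency: s = 0 is pure punishment, s = 1 pure reward
  for (r in risks) {
    for (ep in intersect(c(0, 1), s_grid)) {
      pure <- crd(params = crd_params(params$Z, params$N, params$M,
                                      params$B, params$c, r),
                  policy = incentive_policy(delta = delta, a = a, b = b,
                                            w = ep),
                  dyn = dyn)$eta_G
      got <- out$eta_G[out$s == ep & out$r == r]
      if (!identical(got, pure))
        stop(sprintf("endpoint check failed: s = %g at r = %g does not match the pure policy", ep, r))
    }
  }
  out
}

#' @rdname sweep_risk
#' @param deltas Grid of per-capita budgets (`>= 0`).
#' @return `sweep_delta()`: a long data frame: columns `delta`, `policy`
#'   (`"reward"`/`"punishment"`), then the [crd()] profile columns.
#' @export
sweep_delta <- function(deltas = c(0, 0.005, 0.01, 0.02),
                        params = crd_params(), a = 1, b = 1,
                        dyn = dynamics_params()) {
  check_grid(deltas, 0, Inf)
  rows <- list()
  for (d in deltas) {
    for (pol in c("reward", "punishment")) {
      m <- crd(params = params,
               policy = incentive_policy(delta = d, a = a, b = b,
                                         w = if (pol == "reward") 1 else 0),
               dyn = dyn)
      rows[[length(rows) + 1L]] <-
        cbind(delta = d, policy = pol, m$profile,
              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @rdname sweep_risk
#' @param ratios Grid of positive efficiency ratios `a/b`.
#' @return `sweep_ab()`: a data frame with columns `ab_ratio` and
#'   `s_star`.
#' @export
sweep_ab <- function(ratios = exp(seq(log(0.05), log(20), length.out = 25)),
                     params = crd_params()) {
  check_grid(ratios, 0, Inf, open_lower = TRUE)
  data.frame(ab_ratio = ratios,
             s_star = vapply(ratios, function(ab)
               optimal_switching_point(params, a = ab, b = 1)$s,
               numeric(1)))
}

check_grid <- function(x, lo, hi, open_lower = FALSE) {
  if (!length(x) || !all(is.finite(x)))
    stop("grid must be a non-empty finite numeric vector")
  if (is.unsorted(x)) stop("grid must be sorted increasingly")
  bad <- if (open_lower) any(x <= lo) else any(x < lo)
  if (bad || any(x > hi)) stop("grid values outside the legal range")
  invisible(x)
}

#' Write a sweep table with a reproducibility manifest
#'
#' Writes the table as CSV and, alongside it, a JSON manifest recording
#' every parameter needed to regenerate it (plus package version and
#' seed, when given). Re-running the sweep with the manifest's
#' parameters reproduces the CSV exactly for the analytic sweeps.
#'
#' @param x A data frame from one of the sweep drivers.
#' @param path Output CSV path; the manifest is written next to it with
#'   suffix `_manifest.json`.
#' @param parameters Named list of the parameters that produced `x`.
#' @param seed Optional seed to record (stochastic outputs).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path, parameters = list(), seed = NULL) {
  utils::write.csv(x, path, row.names = FALSE)
  manifest <- list(
    parameters = parameters,
    seed = seed,
    package = "crdincentives",
    version = as.character(utils::packageVersion("crdincentives")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest,
                       sub("\\.csv$", "_manifest.json", path),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
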