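test_that("switching objective signs follow the surviving incentive term", {
  p <- crd_params(Z = 30, N = 6, M = 3)
  ks <- 1:29
  expect_true(all(switching_objective(ks, p, a = 1, b = 0) > 0))
  expect_true(all(switching_objective(ks, p, a = 0, b = 1) < 0))
  expect_error(switching_objective(0, p), "interior")
  expect_error(switching_objective(30, p), "interior")
})

test_that("the objective decreases in k for every tested parameter set", {
  for (p in list(crd_params(Z = 50, N = 10), crd_params(Z = 25, N = 4, M = 2),
                 crd_params(Z = 60, N = 15), crd_params(Z = 12, N = 11, M = 2)))
    for (ab in c(0.2, 1, 5)) {
      obj <- switching_objective(1:(p$Z - 1), p, a = ab, b = 1)
      expect_true(all(diff(obj) < 0))
    }
})

test_that("equal efficiencies put the optimal switch at half the population", {
  sw <- optimal_switching_point(crd_params(Z = 50, N = 10), a = 1, b = 1)
  expect_equal(sw$s, 0.5)
  # the exact crossing sits on a lattice state; sanctioning starts just above
  expect_identical(sw$k_switch, 26L)
})

test_that("degenerate efficiencies give the always-reward / always-punish limits", {
  p <- crd_params(Z = 50, N = 10)
  expect_equal(optimal_switching_point(p, a = 1, b = 0)$s, 1)
  expect_equal(optimal_switching_point(p, a = 0, b = 1)$s, 1 / 50)
  expect_error(optimal_switching_point(p, a = 0, b = 0), "identically zero")
})

test_that("the switch point is scale-invariant in (a, b) and insensitive to M and r", {
  p <- crd_params(Z = 50, N = 10)
  for (ab in c(0.3, 1, 2.5)) {
    base <- optimal_switching_point(p, a = ab, b = 1)$s
    expect_equal(optimal_switching_point(p, a = 7 * ab, b = 7)$s, base)
    expect_equal(optimal_switching_point(p, a = ab / 100, b = 1 / 100)$s, base)
  }
  # M and r enter neither the weights nor the bracket
  ref <- optimal_switching_point(crd_params(Z = 50, N = 10, M = 5, r = 0.5))$s
  for (M in 1:10) for (r in c(0, 0.5, 1))
    expect_equal(optimal_switching_point(crd_params(Z = 50, N = 10, M = M, r = r))$s,
                 ref)
})

test_that("s* is non-decreasing in the efficiency ratio and saturates at the extremes", {
  p <- crd_params(Z = 50, N = 10)
  tab <- sweep_ab(c(0.001, 0.05, 0.2, 1, 5, 20, 1000), p)
  expect_true(all(diff(tab$s_star) >= 0))
  expect_equal(tab$s_star[1], 1 / 50)   # punishment vastly more efficient
  expect_equal(tab$s_star[nrow(tab)], 1)
})

test_that("no interior weight beats both pure policies (bang-bang control)", {
  p <- crd_params(Z = 30, N = 8, M = 4, r = 0.6)
  pol0 <- incentive_policy(delta = 0.03, a = 0.8, b = 1.1)
  wgrid <- seq(0, 1, 0.1)
  for (k in c(1, 5, 10, 15, 20, 25, 29)) {
    adv <- vapply(wgrid, function(w) {
      pol <- incentive_policy(delta = 0.03, a = 0.8, b = 1.1, w = w)
      fitness(k, p, pol, "D") - fitness(k, p, pol, "C")
    }, numeric(1))
    expect_lte(min(adv[c(1, length(wgrid))]), min(adv) + 1e-12)
    best_w <- optimal_w_per_state(k, p, a = 0.8, b = 1.1)
    expect_equal(adv[wgrid == best_w], min(adv), tolerance = 1e-12)
  }
})

test_that("the optimal switch dominates both pure policies across the risk grid", {
  p <- crd_params(Z = 50, N = 10, M = 3)
  s_star <- optimal_switching_point(p, a = 1, b = 1)$s
  tab <- sweep_risk(seq(0, 1, length.out = 11), p, delta = 0.025, s = s_star)
  wide <- reshape(tab, idvar = "r", timevar = "policy", direction = "wide")
  expect_true(all(wide$eta_G.switching >=
                    pmax(wide$eta_G.reward, wide$eta_G.punishment) - 1e-9))
})
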