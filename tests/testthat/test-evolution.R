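test_that("group composition probabilities are the focal-excluding hypergeometric", {
  p <- crd_params(Z = 6, N = 3, M = 2)
  # exhaustive: focal C at k = 3 leaves 2 C and 3 D among 5; pairs with one C
  expect_equal(group_composition_prob(1, k = 3, focal = "C", p), 6 / 10)
  for (k in 0:6) for (focal in c("C", "D")) {
    if ((focal == "C" && k == 0) || (focal == "D" && k == 6)) next
    expect_equal(sum(group_composition_prob(0:2, k, focal, p)), 1)
  }
  # no cooperators to sample: point mass at j = 0
  expect_equal(group_composition_prob(0:2, k = 0, focal = "D", p), c(1, 0, 0))
  expect_error(group_composition_prob(0, k = 0, focal = "C", p), "no cooperator")
  expect_error(group_composition_prob(0, k = 6, focal = "D", p), "no defector")
})

test_that("fitness matches exhaustive enumeration of every co-player set", {
  cases <- list(
    list(p = crd_params(Z = 8, N = 4, M = 2, B = 1, c = 0.1, r = 0.5),
         pol = incentive_policy(delta = 0.03, a = 1, b = 1, w = 0.5)),
    list(p = crd_params(Z = 10, N = 5, M = 3, B = 2, c = 0.4, r = 0.8),
         pol = incentive_policy(delta = 0.05, a = 1.5, b = 0.7, w = 0)),
    list(p = crd_params(Z = 9, N = 5, M = 5, B = 1, c = 0, r = 1),
         pol = incentive_policy(delta = 0.02, a = 0.5, b = 2, s = 0.5))
  )
  for (cs in cases) {
    Z <- cs$p$Z
    for (k in 1:(Z - 1L)) {
      expect_equal(fitness(k, cs$p, cs$pol, "C"),
                   oracle_fitness(k, cs$p, cs$pol, "C"), tolerance = 1e-12)
      expect_equal(fitness(k, cs$p, cs$pol, "D"),
                   oracle_fitness(k, cs$p, cs$pol, "D"), tolerance = 1e-12)
    }
  }
})

test_that("fitness edge values follow from the game structure", {
  # without risk or incentives the cost is the whole difference
  p0 <- crd_params(Z = 20, N = 6, M = 3, B = 1, c = 0.1, r = 0)
  none <- incentive_policy(delta = 0)
  for (k in c(1, 7, 19))
    expect_equal(fitness(k, p0, none, "D") - fitness(k, p0, none, "C"), 0.1)
  # a lone cooperator never reaches M = 5
  p1 <- crd_params(Z = 50, N = 10, M = 5, B = 1, c = 0.1, r = 0.5)
  expect_equal(fitness(1, p1, none, "C"), 0.4)
  expect_error(fitness(0, p1, none, "C"), "absent")
  expect_error(fitness(50, p1, none, "D"), "absent")
})

test_that("higher budgets never hurt cooperators under reward nor help defectors under punishment", {
  p <- crd_params(Z = 30, N = 8, M = 4)
  dyns <- dynamics_params()
  deltas <- c(0, 0.01, 0.02, 0.05)
  fC <- sapply(deltas, function(d)
    fitness(1:29, p, incentive_policy(delta = d, w = 1), "C"))
  fD <- sapply(deltas, function(d)
    fitness(1:29, p, incentive_policy(delta = d, w = 0), "D"))
  expect_true(all(diff(t(fC)) >= 0))   # f_C non-decreasing in delta
  expect_true(all(diff(t(fD)) <= 0))   # f_D non-increasing in delta
})

test_that("imitation follows the Fermi rule and saturates without overflow", {
  d5 <- dynamics_params(beta = 5)
  expect_equal(imitation_prob(1, 1, d5), 0.5)
  expect_equal(imitation_prob(3, -1, dynamics_params(beta = 0)), 0.5)
  expect_true(all(diff(imitation_prob(seq(-2, 2, 0.5), 0, d5)) > 0))
  expect_equal(imitation_prob(1e6, 0, dynamics_params(beta = 1e4)), 1)
  expect_equal(imitation_prob(-1e6, 0, dynamics_params(beta = 1e4)), 0)
})

test_that("transition probabilities behave at boundaries, neutrality, and under exploration", {
  p <- crd_params(Z = 20, N = 5, M = 3)
  pol <- incentive_policy(delta = 0.02, w = 0)
  dyn <- dynamics_params(beta = 5, mu = 0.01)
  tp <- transition_probs(0:20, p, pol, dyn, mutation = FALSE)
  expect_equal(tp$T_plus[c(1, 21)], c(0, 0))
  expect_equal(tp$T_minus[c(1, 21)], c(0, 0))
  expect_true(all(tp$T_plus >= 0 & tp$T_minus >= 0))
  expect_true(all(tp$T_plus + tp$T_minus <= 1))
  tpm <- transition_probs(0:20, p, pol, dyn, mutation = TRUE)
  expect_equal(tpm$T_plus[1], dyn$mu)
  expect_equal(tpm$T_minus[1], 0)
  expect_equal(tpm$T_minus[21], dyn$mu)
  expect_true(all(tpm$T_plus[1:20] > 0) && all(tpm$T_minus[2:21] > 0))
  # neutral drift: Fermi term is exactly one half
  tp0 <- transition_probs(0:20, p, pol, dynamics_params(beta = 0), mutation = FALSE)
  k <- 0:20
  expect_equal(tp0$T_plus, (k / 20) * ((20 - k) / 20) / 2)
  expect_equal(tp0$T_minus, tp0$T_plus)
})

test_that("the closed-form stationary distribution matches the eigenvector of the chain", {
  cases <- list(
    list(p = crd_params(Z = 30, N = 6, M = 3), pol = incentive_policy(delta = 0),
         dyn = dynamics_params(beta = 5, mu = 0.01)),
    list(p = crd_params(Z = 25, N = 8, M = 6, r = 0.9),
         pol = incentive_policy(delta = 0.03, w = 0),
         dyn = dynamics_params(beta = 8, mu = 0.005)),
    list(p = crd_params(Z = 40, N = 10, M = 3, r = 0.2),
         pol = incentive_policy(delta = 0.025, s = 0.5),
         dyn = dynamics_params(beta = 2, mu = 0.05))
  )
  for (cs in cases) {
    pbar <- stationary_distribution(cs$p, cs$pol, cs$dyn)
    expect_equal(sum(pbar), 1, tolerance = 1e-12)
    expect_lt(max(abs(pbar - oracle_stationary_eigen(cs$p, cs$pol, cs$dyn))), 1e-10)
    # reversibility of the birth-death chain
    tp <- transition_probs(0:cs$p$Z, cs$p, cs$pol, cs$dyn, mutation = TRUE)
    Z <- cs$p$Z
    expect_lt(max(abs(pbar[1:Z] * tp$T_plus[1:Z] -
                        pbar[2:(Z + 1)] * tp$T_minus[2:(Z + 1)])), 1e-12)
  }
  expect_error(stationary_distribution(cases[[1]]$p, cases[[1]]$pol,
                                       dynamics_params(beta = 5, mu = 0)),
               "mu > 0")
})

test_that("full exploration collapses the chain to the Ehrenfest urn", {
  p <- crd_params(Z = 30, N = 6, M = 3)
  pbar <- stationary_distribution(p, incentive_policy(delta = 0.02, w = 0),
                                  dynamics_params(beta = 5, mu = 1))
  expect_lt(max(abs(pbar - dbinom(0:30, 30, 0.5))), 1e-10)
})

test_that("with composition-independent payoffs the stationary law is symmetric in C and D", {
  # c = 0, delta = 0, r = 0: every individual earns B in every group
  p <- crd_params(Z = 30, N = 6, M = 3, c = 0, r = 0)
  pbar <- stationary_distribution(p, incentive_policy(delta = 0),
                                  dynamics_params(beta = 5, mu = 0.01))
  expect_lt(max(abs(pbar - rev(pbar))), 1e-12)
})

test_that("gradient sign structure follows the dilemma", {
  # cost dominates without risk: cooperation always declines
  G0 <- gradient_of_selection(crd_params(Z = 20, N = 5, M = 3, r = 0),
                              incentive_policy(delta = 0),
                              dynamics_params(beta = 5))
  expect_equal(G0[c(1, 21)], c(0, 0))
  expect_true(all(G0[2:20] < 0))
  # risk creates a coordination barrier and a coexistence attractor
  b <- fig2_baseline()
  G <- gradient_of_selection(b$params, incentive_policy(delta = 0), b$dyn)
  eq <- find_equilibria(G)
  expect_identical(eq$type, c("unstable", "stable"))
})

test_that("find_equilibria classifies sign changes between adjacent states", {
  expect_identical(nrow(find_equilibria(c(0, -1, -2, -1, 0))), 0L)
  eq <- find_equilibria(c(0, 1, 1, -1, 0))
  expect_identical(eq$k_lower, 2L)
  expect_identical(eq$k_upper, 3L)
  expect_identical(eq$type, "stable")
  eq2 <- find_equilibria(c(0, -1, 1, -1, 0))
  expect_identical(eq2$type, c("unstable", "stable"))
})
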