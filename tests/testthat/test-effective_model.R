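test_that("the passive equilibrium balances junction tensions under the length constraint", {
  expect_equal(eff_equilibrium(eff_params()), c(l1 = 1, l2 = 1))
  eq <- eff_equilibrium(eff_params(Lambda1 = 0.1, Lambda2 = 0.2))
  expect_equal(eq[["l1"]], 1 + 2 * 0.1 / 3, tolerance = 1e-12)  # long center
  expect_equal(eq[["l1"]] + 2 * eq[["l2"]], 3, tolerance = 1e-12)
  eq2 <- eff_equilibrium(eff_params(Lambda1 = 0.4, Lambda2 = 0.1))
  expect_lt(eq2[["l1"]], 1)                                     # short center
  expect_gt(eq2[["l2"]], 1)
})

test_that("the propagation threshold has its closed form, limits and monotonicity", {
  expect_equal(tau_p(1, 0.1), log(2) / 10, tolerance = 1e-12)
  expect_equal(tau_p(1, 0), 0)
  expect_equal(tau_p(2, 0), 0)
  expect_identical(tau_p(1, 0.2), Inf)   # eps_on at Gamma0/(3+2*Gamma0)
  expect_identical(tau_p(1, 0.25), Inf)
  expect_error(tau_p(-1, 0.1))
  expect_error(tau_p(1, -0.1))
  eps <- seq(0.01, 0.15, by = 0.01)
  expect_true(all(diff(tau_p(1, eps)) > 0))          # increasing in eps_on
  g <- seq(0.5, 2, by = 0.1)
  expect_true(all(diff(vapply(g, tau_p, 1, eps_on = 0.1)) < 0))  # decreasing in Gamma0
})

test_that("reactivation coefficients match their closed form and vanish at zero threshold", {
  ab0 <- reactivation_coefficients(1, 0)
  expect_equal(ab0$A, 0)
  expect_equal(ab0$B, 0)
  ab <- reactivation_coefficients(1, 0.1)
  # with Gamma0 = 1, eps_on = 0.1: exp(10 tau_p) = 2 exactly, so B = 0.4,
  # and A = (1/2)(1 - 2^(-4/5)) 2^(3/5) since 8 tau_p = (4/5) ln 2
  expect_equal(ab$B, 0.4, tolerance = 1e-12)
  expect_equal(ab$A, 0.5 * (1 - 2^(-0.8)) * 2^0.6, tolerance = 1e-12)
  expect_error(reactivation_coefficients(1, 0.25), "infinite")
  eps <- seq(0.01, 0.19, by = 0.01)
  Avals <- vapply(eps, function(e) reactivation_coefficients(1, e)$A, 1)
  Bvals <- vapply(eps, function(e) reactivation_coefficients(1, e)$B, 1)
  expect_true(all(diff(Avals) > 0))
  expect_true(all(diff(Bvals) > 0))
})

test_that("the reactivation window sits just above the propagation threshold", {
  rr <- reactivation_range(1, 0.1)
  tp <- tau_p(1, 0.1)
  expect_lt(tp, rr[["tau1"]])
  expect_lt(rr[["tau1"]], rr[["tau2"]])
  expect_equal(round(rr[["tau1"]] - tp, 3), 0.003)
  expect_null(reactivation_range(1, 0.05))   # below the eps_on window
  expect_null(reactivation_range(1, 0.25))   # no propagation at all
  expect_null(reactivation_range(1, 0))      # A = B = 0
})

test_that("simulated outcomes fall into the three regimes", {
  p <- eff_params()  # Gamma0 = 1, eps_on = 0.1
  expect_equal(simulate_effective(p, tau = 0.05, kL = 0, record = FALSE)$label,
               "no_propagation")
  expect_equal(simulate_effective(p, tau = 0.09, kL = 0, record = FALSE)$label,
               "reactivation")
  expect_equal(simulate_effective(p, tau = 0.2, kL = 0, record = FALSE)$label,
               "pulse")
  expect_equal(simulate_effective(p, tau = 0.09, kL = 5, record = FALSE)$label,
               "no_propagation")
  expect_equal(simulate_effective(p, tau = 1, kL = 5, record = FALSE)$label,
               "no_propagation")
})

test_that("the simulated trajectory conserves the fixed-boundary constraint", {
  out <- simulate_effective(eff_params(Lambda1 = 0.1, Lambda2 = 0.2),
                            tau = 0.1, kL = 0.3)
  tr <- out$trajectory
  expect_true(all(abs(tr$l1 + 2 * tr$l2 - 3) < 1e-9))
  expect_true(all(c("eps1", "eps2", "state1", "state2") %in% names(tr)))
})

test_that("numeric bisection of the model recovers the analytic threshold", {
  for (G0 in c(1, 2)) for (e in c(0.05, 0.1)) {
    p <- eff_params(Gamma0 = G0, eps_on = e)
    tpn <- eff_critical_tau(p, kL = 0, what = "propagation")
    expect_lt(abs(tpn - tau_p(G0, e)), 2 * p$dt)
  }
})

test_that("the phase diagram contains the three phases in the expected layout", {
  p <- eff_params()
  g <- effective_phase_diagram(p, tau_grid = c(0.05, 0.09, 0.2),
                               kL_grid = c(0, 5))
  expect_setequal(unique(g$label), c("no_propagation", "reactivation", "pulse"))
  # reactivation is confined to small tau and small kL
  expect_equal(g$label[g$tau == 0.09 & g$kL == 0], "reactivation")
  expect_true(all(g$label[g$kL == 5] == "no_propagation"))
})
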