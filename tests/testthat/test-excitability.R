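test_that("junction strain is the relative extension past the rest length", {
  tis <- hex_small()
  j <- 3L
  l <- junction_geometry(tis, j)$length
  expect_equal(junction_strain(tis, j), 0)
  tis$l0[j] <- l / 1.1
  expect_equal(junction_strain(tis, j), 0.1, tolerance = 1e-12)
  tis$l0[j] <- l / 0.9
  expect_equal(junction_strain(tis, j), -0.1, tolerance = 1e-12)
  tis$l0[j] <- 0
  expect_error(junction_strain(tis, j), "rest length")
})

test_that("state transitions follow the three-state rules simultaneously", {
  tis <- hex_small()
  ep <- excit_params(eps_on = 0.1, tau_act = 0.3, tau_ref = 0.2, Gamma0 = 0.5)
  dt <- 0.01
  # junction 1: active, timer about to expire -> refractory with full timer
  tis$state[1L] <- 1L; tis$timer[1L] <- dt; tis$gamma[1L] <- ep$Gamma0
  # junction 2: refractory, timer about to expire, strained -> inactive only
  tis$state[2L] <- 2L; tis$timer[2L] <- dt
  tis$l0[2L] <- junction_geometry(tis, 2L)$length / 1.5
  # junction 3: inactive at threshold strain (inclusive) -> active
  tis$l0[3L] <- junction_geometry(tis, 3L)$length / (1 + ep$eps_on)
  # junction 4: inactive just below threshold -> stays inactive
  tis$l0[4L] <- junction_geometry(tis, 4L)$length / (1 + ep$eps_on - 0.001)
  out <- update_states(tis, ep, dt)
  expect_equal(out$state[1L], 2L)
  expect_equal(out$timer[1L], ep$tau_ref)
  expect_equal(out$gamma[1L], 0)
  expect_equal(out$state[2L], 0L)  # refractory cannot re-activate in the same step
  expect_equal(out$state[3L], 1L)
  expect_equal(out$timer[3L], ep$tau_act)
  expect_equal(out$gamma[3L], ep$Gamma0)
  expect_equal(out$state[4L], 0L)
  # the freshly inactive strained junction may activate on the next step
  out2 <- update_states(out, ep, dt)
  expect_equal(out2$state[2L], 1L)
})

test_that("a seeded junction is active for tau_act then refractory for tau_ref", {
  mp <- mech_params(kL = 0)
  ep <- excit_params(eps_on = 0.1, tau_act = 0.3, tau_ref = 0.2, Gamma0 = 0.5)
  tis <- seed_activation(hex_small(), "single", 1L, ep)
  states <- integer(70L)
  for (s in seq_along(states)) {
    tis <- step_tissue(tis, mp, ep)
    states[s] <- tis$state[1L]
  }
  n_act <- which(states != 1L)[1L] - 1L
  expect_lt(abs(n_act * mp$dt - ep$tau_act), mp$dt * 1.5)
  after <- states[(n_act + 1L):length(states)]
  n_ref <- which(after != 2L)[1L] - 1L
  expect_lt(abs(n_ref * mp$dt - ep$tau_ref), mp$dt * 1.5)
  expect_equal(after[n_ref + 1L], 0L)
})

test_that("state fractions always sum to one during a run", {
  mp <- mech_params(kL = 0.5)
  ep <- excit_params(tau_act = 1, tau_ref = 1)
  tis <- seed_activation(hex_small(), "single", NULL, ep)
  rec <- run_simulation(tis, mp, ep, t_end = 3)
  expect_equal(rec$f_inactive + rec$f_active + rec$f_refractory,
               rep(1, length(rec$times)))
})

test_that("seeding modes activate the requested junctions", {
  tis <- hex_small()
  ep <- excit_params(tau_act = 2, tau_ref = 1)
  s1 <- seed_activation(tis, "single", NULL, ep)
  expect_equal(sum(s1$state == 1L), 1L)
  expect_equal(state_fractions(s1)[["active"]], 1 / length(tis$ja))
  expect_equal(s1$timer[s1$state == 1L], ep$tau_act)
  expect_error(seed_activation(tis, "single", 99999L, ep), "nonexistent")
  expect_error(seed_activation(s1, "single", 1L, ep), "inactive tissue")

  # a row: the zigzag of non-vertical junctions in one horizontal band
  mids <- excitissue:::junction_midpoints(tis)
  d <- excitissue:::junction_vectors(tis)
  nonvert <- which(abs(d[, 1L]) > 0.2 * sqrt(d[, 1L]^2 + d[, 2L]^2))
  y0 <- mids[nonvert[1L], 2L]
  sr <- seed_activation(tis, "row", list(y = y0), ep)
  nrow_act <- sum(sr$state == 1L)
  expect_gte(nrow_act, 3L)
  expect_true(all(sr$state[setdiff(seq_along(tis$ja), which(sr$state == 1L))] == 0L))

  srr <- seed_activation(tis, "row_plus_refractory", list(y = y0), ep)
  expect_equal(sum(srr$state == 1L), nrow_act)
  expect_gt(sum(srr$state == 2L), 0L)
  expect_equal(srr$timer[srr$state == 2L][1L], ep$tau_ref)
  # refractory layer lies below the active row
  ref_y <- mids[srr$state == 2L, 2L]
  act_y <- mids[srr$state == 1L, 2L]
  rel <- excitissue:::band_rel_y(ref_y, tis$box, ref = mean(act_y))
  expect_true(all(rel < 0))
})

test_that("with a zero threshold any positively strained junction activates", {
  tis <- hex_small()
  tis$l0 <- tis$l0 * 0.999           # uniform small positive strain
  ep <- excit_params(eps_on = 0, tau_act = 1, tau_ref = 1)
  out <- update_states(tis, ep, 0.01)
  expect_true(all(out$state == 1L))
})
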