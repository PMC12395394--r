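test_that("energy matches its definition and the tension term scales with length", {
  tis <- hex_small()
  expect_lt(total_energy(tis, mech_params(Lambda = 0)), 1e-12)
  ltot <- sum(excitissue:::junction_lengths(tis))
  e0 <- total_energy(tis, mech_params(Lambda = 0))
  e1 <- total_energy(tis, mech_params(Lambda = 0.1))
  expect_equal(e1 - e0, 0.1 * ltot, tolerance = 1e-12)
})

test_that("forces are minus the energy gradient (numeric check) and sum to zero", {
  tis <- jitter_tissue(hex_small(), 0.02)
  mp <- mech_params()
  F <- net_vertex_forces(tis, mp)
  expect_lt(max(abs(colSums(F))), 1e-9)  # translation invariance
  h <- 1e-6
  for (v in c(1L, 7L, 23L)) {
    for (dim in 1:2) {
      tp <- tis; tp$pos[v, dim] <- tp$pos[v, dim] + h
      tm <- tis; tm$pos[v, dim] <- tm$pos[v, dim] - h
      g <- (total_energy(tp, mp) - total_energy(tm, mp)) / (2 * h)
      expect_equal(F[v, dim], -g, tolerance = 1e-5)
    }
  }
})

test_that("an active junction pulls its endpoints together with force Gamma * l", {
  tis <- hex_small()
  mp <- mech_params()
  passive <- net_vertex_forces(tis, mp)
  j <- 4L
  tis$gamma[j] <- 0.7
  act <- net_vertex_forces(tis, mp) - passive
  g <- junction_geometry(tis, j)
  ia <- tis$ja[j]; ib <- tis$jb[j]
  expect_equal(act[ia, ], 0.7 * g$vector, tolerance = 1e-12)
  expect_equal(act[ib, ], -0.7 * g$vector, tolerance = 1e-12)
  expect_equal(sqrt(sum(act[ia, ]^2)), 0.7 * g$length, tolerance = 1e-12)
  others <- setdiff(seq_len(nrow(tis$pos)), c(ia, ib))
  expect_lt(max(abs(act[others, ])), 1e-12)
})

test_that("stepping from equilibrium leaves the tissue unchanged", {
  tis <- hex_small()
  out <- step_tissue(tis, mech_params(), steps = 5L)
  expect_lt(max_vertex_displacement(out, tis), 1e-8)
})

test_that("passive dynamics is a gradient flow: energy is non-increasing", {
  tis <- jitter_tissue(hex_small(), 0.02)
  mp <- mech_params(kL = 0)
  en <- numeric(60L)
  for (i in seq_along(en)) {
    tis <- step_tissue(tis, mp)
    en[i] <- total_energy(tis, mp)
  }
  expect_true(all(diff(en) <= 1e-12))
})

test_that("rest lengths relax exponentially toward the current length", {
  tis <- hex_small()
  mp <- mech_params(kL = 1)
  j <- 2L
  l <- junction_geometry(tis, j)$length
  tis$l0[j] <- 1.5 * l
  gap0 <- tis$l0[j] - l
  out <- step_tissue(tis, mp, steps = as.integer(1 / mp$dt))  # elapsed time 1/kL
  gap1 <- out$l0[j] - junction_geometry(out, j)$length
  expect_equal(gap1 / gap0, exp(-1), tolerance = 0.01)
})

test_that("a T1 swap rewires topology correctly and conserves the Euler characteristic", {
  tis <- hex_small()
  mp <- mech_params()
  j <- 11L
  ia <- tis$ja[j]; ib <- tis$jb[j]
  shared <- intersect(which(vapply(tis$cells, function(lp) ia %in% lp, TRUE)),
                      which(vapply(tis$cells, function(lp) ib %in% lp, TRUE)))
  sides_before <- cell_sides(tis)
  # collapse the junction below the T1 threshold by hand
  g <- junction_geometry(tis, j)
  mid <- tis$pos[ia, ] + g$vector / 2
  u <- g$vector / g$length
  tis$pos[ia, ] <- mid - 0.002 * u
  tis$pos[ib, ] <- mid + 0.002 * u
  out <- t1_transitions(tis, mp)

  expect_equal(out$stats$t1_count, 1L)
  expect_equal(out$l0[j], 1.5 * mp$lT1)
  expect_equal(junction_geometry(out, j)$length, 1.5 * mp$lT1, tolerance = 1e-12)
  expect_equal(out$state[j], 0L)
  expect_equal(out$gamma[j], 0)
  expect_equal(nrow(out$pos), nrow(tis$pos))
  expect_equal(length(out$ja), length(tis$ja))
  expect_equal(length(out$cells), length(tis$cells))
  expect_true(validate_tissue(out)$ok)
  sides_after <- cell_sides(out)
  expect_equal(sort(sides_after[shared]), sort(sides_before[shared] - 1L))
  expect_equal(sum(sides_after), sum(sides_before))
  # swapped edge is now perpendicular to its old direction
  expect_lt(abs(sum(junction_geometry(out, j)$vector * u)), 1e-12)

  # no junction below threshold: no-op
  out2 <- t1_transitions(out, mp)
  expect_identical(out2$stats$t1_count, 1L)
  expect_identical(out2$pos, out$pos)
})

test_that("equilibration restores a perturbed lattice and is idempotent", {
  ref <- hex_small()
  tis <- equilibrate(jitter_tissue(ref, 0.01), mech_params())
  expect_lt(max(abs(net_vertex_forces(tis, mech_params()))), 1e-6)
  # gradient flow conserves the centroid, so the lattice is recovered up to
  # the uniform translation contributed by the jitter's mean
  d <- excitissue:::min_image(tis$pos - ref$pos, ref$box)
  d <- sweep(d, 2L, colMeans(d))
  expect_lt(max(sqrt(d[, 1L]^2 + d[, 2L]^2)), 1e-4)
  tis2 <- equilibrate(tis, mech_params())
  expect_identical(tis2$pos, tis$pos)
  expect_equal(junction_strain(tis2), rep(0, length(tis2$ja)))
})

test_that("halving the time step does not change the tracked strain appreciably", {
  run_strain <- function(dt) {
    mp <- mech_params(kL = 0.7, dt = dt)
    ep <- excit_params(tau_act = 0.8, tau_ref = 0.8)
    tis <- seed_activation(hex_small(), "single", 1L, ep)
    tis <- step_tissue(tis, mp, ep, steps = as.integer(3 / dt))
    total_strain(tis)
  }
  expect_equal(run_strain(0.01), run_strain(0.005), tolerance = 0.05)
})
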