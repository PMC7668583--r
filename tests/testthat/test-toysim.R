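test_that("energy terms vanish at their minima", {
  # two bonded beads at the rest length: zero bond energy, zero force
  two <- structure_model(matrix(c(0, 0, 0, 0.38, 0, 0), 2, 3, byrow = TRUE))
  ff <- bead_forcefield(angle_k = 0, ev_eps = 0)
  e <- toy_energy(two, ff)
  expect_equal(as.numeric(e), 0, tolerance = 1e-12)
  expect_equal(max(abs(attr(e, "forces"))), 0, tolerance = 1e-9)
  # a restraint-only system with the pair at r0 scores k/2
  pair <- structure_model(matrix(c(0, 0, 0, 1.6, 0, 0), 2, 3, byrow = TRUE),
                          res_id = c(1L, 6L))
  ff_r <- bead_forcefield(bond_k = 0, angle_k = 0, ev_eps = 0,
                          restraints = tibble::tibble(i = 1L, j = 2L))
  # note: restraint indices address bead positions (rows)
  e_r <- toy_energy(pair, ff_r)
  expect_equal(as.numeric(e_r), 10 / 2, tolerance = 1e-9)
})

test_that("analytic forces match central finite differences", {
  target <- make_folded_fixture(14, "helix_loop_helix", seed = 2)
  rs <- build_scenario(target, tpr = 1, n_cp = 5, seed = 1)
  ff <- bead_forcefield(ref = target, restraints = rs)
  m <- make_unfolded_fixture(14, seed = 3)
  e <- toy_energy(m, ff)
  F <- attr(e, "forces")
  co <- as.matrix(m[, c("x", "y", "z")])
  h <- 1e-6
  for (i in seq_len(nrow(co))) {
    for (d in 1:3) {
      cp <- co; cp[i, d] <- cp[i, d] + h
      cm <- co; cm[i, d] <- cm[i, d] - h
      num <- -(as.numeric(toy_energy(structure_model(cp), ff)) -
                 as.numeric(toy_energy(structure_model(cm), ff))) / (2 * h)
      expect_lt(abs(num - F[i, d]), 1e-4)
    }
  }
})

test_that("zero forces and zero friction give ballistic drift", {
  free <- bead_forcefield(bond_k = 0, angle_k = 0, ev_eps = 0)
  m <- structure_model(matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE))
  v0 <- matrix(c(0.1, 0, 0, -0.2, 0.05, 0), 2, 3, byrow = TRUE)
  out <- langevin_run(m, free, temperature = 300, n_steps = 100, dt = 0.01,
                      friction = 0, velocities = v0)
  expect_equal(as.matrix(out$model[, c("x", "y", "z")]),
               as.matrix(m[, c("x", "y", "z")]) + v0 * 1,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("deterministic dynamics conserves energy", {
  m <- make_folded_fixture(10, "helix", seed = 1)
  ff <- bead_forcefield(ref = m)
  # perturb slightly so there is motion, then integrate without noise
  set.seed(1)
  m2 <- structure_model(as.matrix(m[, 3:5]) + rnorm(30, sd = 0.01),
                        res_id = m$res_id)
  out <- langevin_run(m2, ff, temperature = 0, n_steps = 1e5, dt = 0.01,
                      friction = 0, velocities = matrix(0, 10, 3),
                      sample_interval = 10)
  etot <- out$sampled_energy + out$sampled_kinetic
  # secular drift per 1e4 steps, from window means so the bounded
  # shadow-energy oscillation of the splitting integrator averages out
  first <- mean(etot[1:1000])
  last <- mean(etot[9001:10000])
  expect_lt(abs(last - first) / 9, 1e-3)
  # and the oscillation itself stays small relative to the total energy
  expect_lt(stats::sd(etot) / mean(etot), 1e-3)
})

test_that("thermostatted kinetic energy satisfies equipartition", {
  # bonded dimer in a heat bath: mean KE per dof -> kB T / 2 within 5%
  two <- structure_model(matrix(c(0, 0, 0, 0.38, 0, 0), 2, 3, byrow = TRUE))
  ff <- bead_forcefield(angle_k = 0, ev_eps = 0)
  kB <- 0.008314462618
  out <- langevin_run(two, ff, temperature = 300, n_steps = 2e5, dt = 0.01,
                      friction = 2, mass = 110, sample_interval = 20,
                      seed = 123)
  ke_per_dof <- mean(out$sampled_kinetic) / 6
  expect_equal(ke_per_dof, kB * 300 / 2, tolerance = 0.05)
})

test_that("langevin runs are reproducible given a seed", {
  m <- make_unfolded_fixture(12, seed = 1)
  ff <- bead_forcefield()
  a <- langevin_run(m, ff, 300, 500, seed = 77)
  b <- langevin_run(m, ff, 300, 500, seed = 77)
  c <- langevin_run(m, ff, 300, 500, seed = 78)
  expect_identical(as.data.frame(a$model), as.data.frame(b$model))
  expect_false(identical(as.data.frame(a$model), as.data.frame(c$model)))
})

test_that("integrator reports divergence with advice", {
  m <- structure_model(matrix(c(0, 0, 0, 0.38, 0, 0), 2, 3, byrow = TRUE))
  ff <- bead_forcefield(bond_k = 1e9, angle_k = 0, ev_eps = 0)
  expect_error(
    langevin_run(m, ff, 300, 1000, dt = 0.1, seed = 1),
    "dt")
})

test_that("REMD without a complete exchange block is plain parallel MD", {
  start <- make_unfolded_fixture(10, seed = 1)
  ff <- bead_forcefield()
  lad <- build_ladder(ladder_params(300, 0.05, 3))
  run <- run_remd(start, ff, lad, n_steps = 400, exchange_interval = 1000,
                  sample_interval = 200, seed = 1)
  expect_equal(nrow(run$exchanges), 0)
  expect_equal(length(unique(run$frames$slot)), 3)
})

test_that("REMD exchange decisions replay exactly from logged energies", {
  start <- make_unfolded_fixture(12, seed = 2)
  target <- make_folded_fixture(12, "helix_loop_helix", seed = 1)
  ff <- bead_forcefield(ref = target)
  lad <- build_ladder(ladder_params(300, 0.08, 4))
  run <- run_remd(start, ff, lad, n_steps = 1e4, exchange_interval = 500,
                  sample_interval = 500, seed = 5)
  ex <- run$exchanges
  expect_gt(nrow(ex), 0)
  kB <- 0.008314462618
  t_lo <- lad$temperature[ex$slot_lo + 1]
  t_hi <- lad$temperature[ex$slot_hi + 1]
  delta <- (1 / (kB * t_hi) - 1 / (kB * t_lo)) * (ex$e_lo - ex$e_hi)
  expect_equal(ex$delta, delta, tolerance = 1e-10)
  expect_equal(ex$probability, pmin(1, exp(-delta)), tolerance = 1e-10)
  expect_identical(ex$accepted, ex$rng_draw < ex$probability)
})

test_that("identical temperatures accept every exchange", {
  start <- make_unfolded_fixture(10, seed = 3)
  ff <- bead_forcefield()
  lad <- tibble::tibble(replica = 0:2, temperature = rep(300, 3))
  run <- run_remd(start, ff, lad, n_steps = 2000, exchange_interval = 500,
                  sample_interval = 500, seed = 2)
  expect_true(all(run$exchanges$probability == 1))
  expect_true(all(run$exchanges$accepted))
})

test_that("REMD acceptance statistics agree with the Metropolis average", {
  # identical force field and modest ladder: realized acceptance within 3
  # sigma of the mean Metropolis probability of the attempted swaps
  start <- make_unfolded_fixture(10, seed = 4)
  ff <- bead_forcefield()
  lad <- build_ladder(ladder_params(300, 0.06, 4))
  run <- run_remd(start, ff, lad, n_steps = 3e4, exchange_interval = 300,
                  sample_interval = 0, seed = 9)
  ex <- run$exchanges
  p_bar <- mean(ex$probability)
  se <- sqrt(sum(ex$probability * (1 - ex$probability))) / nrow(ex)
  expect_lt(abs(mean(ex$accepted) - p_bar), max(3 * se, 1e-12))
})

test_that("REMD runs are reproducible and tidiers summarise them", {
  start <- make_unfolded_fixture(10, seed = 5)
  ff <- bead_forcefield()
  lad <- build_ladder(ladder_params(300, 0.06, 3))
  a <- run_remd(start, ff, lad, 2000, exchange_interval = 500,
                sample_interval = 500, seed = 31)
  b <- run_remd(start, ff, lad, 2000, exchange_interval = 500,
                sample_interval = 500, seed = 31)
  expect_identical(a$frames, b$frames)
  expect_identical(a$exchanges$accepted, b$exchanges$accepted)
  g <- glance(a)
  expect_equal(g$n_attempts, nrow(a$exchanges))
  expect_identical(tidy(a), tibble::as_tibble(a$exchanges))
  st <- exchange_statistics(a)
  expect_equal(sum(st$attempts), nrow(a$exchanges))
  tr <- slot_trajectory(a, 0)
  expect_s3_class(tr, "trajectory_ensemble")
  expect_equal(length(unique(tr$frame)), 4)
})
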