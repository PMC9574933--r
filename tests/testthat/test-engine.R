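# Pairwise forces, integrator and boundary conditions.

test_that("conservative force is linear, capped and cutoff-limited", {
  expect_equal(conservative_force(c(1.2, 0, 0), 25, 1.2), c(0, 0, 0))
  expect_equal(conservative_force(c(0.6, 0, 0), 25, 1.2),
               c(25 * 0.5, 0, 0))  # r = R/2 gives a/2
  f0 <- conservative_force(c(1e-15, 0, 0), 25, 1.2, seed = 2)
  expect_equal(sqrt(sum(f0^2)), 25)  # maximum repulsion at contact
  f <- conservative_force(c(0.3, 0.4, 0), 40, 1)
  expect_equal(f / sqrt(sum(f^2)), c(0.6, 0.8, 0))  # repulsive along r_ij
})

test_that("thermostat pair forces follow the weight functions", {
  z <- c(0, 0, 0)
  out <- pair_thermostat_forces(c(1.5, 0, 0), c(1, 0, 0), 4.5, 3, 1, 0.01,
                                0.7)
  expect_equal(out$dissipative, z)
  expect_equal(out$random, z)
  # perpendicular relative velocity: no dissipation
  out2 <- pair_thermostat_forces(c(0.5, 0, 0), c(0, 1, 0), 4.5, 3, 1, 0.01,
                                 0.7)
  expect_equal(out2$dissipative, z)
  expect_equal(out2$random, 3 * 0.5 * 0.7 / sqrt(0.01) * c(1, 0, 0))
  # omega^D = (omega^R)^2
  out3 <- pair_thermostat_forces(c(0.5, 0, 0), c(1, 0, 0), 4.5, 3, 1, 0.01,
                                 0)
  expect_equal(out3$dissipative, -4.5 * 0.25 * 1 * c(1, 0, 0))
  expect_error(pair_thermostat_forces(c(0.5, 0, 0), c(1, 0, 0), 4.5, 3, 1,
                                      -1, 0), "dt")
  # engine random force has zero mean over the keyed stream
  sys <- dpd_system(positions = rbind(c(1, 1, 1), c(1.5, 1, 1)),
                    species = c("W", "W"), box_edge = 5)
  m <- colMeans(t(vapply(1:4000, function(s) {
    compute_forces(sys, ff_default, seed = 1, step = s,
                   breakdown = TRUE)$random[1, ]
  }, numeric(3))))
  w <- 0.5; se <- 3 * w / sqrt(0.01) / sqrt(4000)
  expect_true(all(abs(m) < 4 * se))
})

test_that("bond forces derive from the harmonic potential", {
  out <- bond_force(c(0.45, 0, 0), 0.45, 150)
  expect_equal(out$force_i, c(0, 0, 0))
  # finite-difference check of -dU/dr and antisymmetry
  U <- function(r) 150 / 2 * (r - 0.45)^2
  for (r in c(0.3, 0.45, 0.6, 0.9)) {
    f <- bond_force(c(r, 0, 0), 0.45, 150)
    num <- -(U(r + 1e-6) - U(r - 1e-6)) / 2e-6
    expect_equal(f$force_i[1], num, tolerance = 1e-6)
    expect_equal(f$force_i, -f$force_j)
  }
  # energy symmetric about l0
  expect_equal(U(0.45 + 0.1), U(0.45 - 0.1))
})

test_that("angle forces match numeric gradients and carry no net force", {
  # straight chain at theta0 = 180: all forces vanish
  out <- angle_force(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 180, 5)
  expect_equal(out$force_i, c(0, 0, 0))
  expect_equal(out$theta, 180)
  # bent configuration: analytic forces equal numerical gradient of U
  pi_ <- c(0.1, 0.9, 0); pj <- c(1, 0, 0); pk <- c(2, 0.2, 0.3)
  Uof <- function(pi_, pj, pk, th0 = 150) {
    a <- pi_ - pj; b <- pk - pj
    th <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    5 / 2 * (th - th0 * pi / 180)^2
  }
  out <- angle_force(pi_, pj, pk, 150, 5)
  for (comp in 1:3) {
    e <- rep(0, 3); e[comp] <- 1e-7
    expect_equal(out$force_i[comp],
                 -(Uof(pi_ + e, pj, pk) - Uof(pi_ - e, pj, pk)) / 2e-7,
                 tolerance = 1e-5)
    expect_equal(out$force_j[comp],
                 -(Uof(pi_, pj + e, pk) - Uof(pi_, pj - e, pk)) / 2e-7,
                 tolerance = 1e-5)
  }
  expect_equal(out$force_i + out$force_j + out$force_k, c(0, 0, 0))
  # net torque about the central bead vanishes
  tq <- cross3(pi_ - pj, out$force_i) + cross3(pk - pj,
                                                           out$force_k)
  expect_equal(tq, c(0, 0, 0), tolerance = 1e-12)
})

test_that("smeared electrostatics: closed form, Ewald vs direct sum", {
  g <- ff_default$electrostatics$coupling
  # finite and attractive at near contact for opposite charges
  e01 <- slater_pair_energy(0.1, 1, -1, g)
  expect_true(is.finite(e01) && e01 < 0)
  expect_equal(slater_pair_energy(1e-15, 1, -1, g),
               -g * 0.929 / (4 * pi))
  # approaches point Coulomb at 5 r_C within 1%
  expect_equal(slater_pair_energy(5, 1, 1, g), g / (4 * pi * 5),
               tolerance = 0.01)
  # Ewald vs direct lattice sum (tinfoil boundary) on a small neutral box
  set.seed(4)
  L <- 10; n <- 12
  sys <- dpd_system(positions = matrix(runif(3 * n, 0, L), ncol = 3),
                    species = rep(c("Na", "ES"), n / 2),
                    charge = rep(c(1, -1), n / 2), box_edge = L)
  ew <- electrostatic_forces(sys, ff_default)
  ds <- direct_sum_electrostatics(sys, ff_default, n_images = 8)
  expect_equal(ew$energy, ds$energy, tolerance = 2e-3)
  expect_lt(max(abs(ew$force - ds$force)) / max(abs(ds$force)), 5e-3)
  expect_equal(colSums(ew$force), c(0, 0, 0), tolerance = 1e-10)
  # non-neutral systems are rejected
  bad <- dpd_system(positions = matrix(runif(9, 0, 5), ncol = 3),
                    species = rep("Na", 3), charge = rep(1, 3),
                    box_edge = 5)
  expect_error(electrostatic_forces(bad, ff_default), "neutral")
})

test_that("pairwise antisymmetry and cell/brute equivalence", {
  sys <- random_water_box(200, 5, seed = 7)
  # random mixed species to exercise per-pair cutoffs
  set.seed(8)
  sys$species <- sample(ff_default$species[c(1, 2, 3, 4)], 200,
                        replace = TRUE)
  fc <- compute_forces(sys, ff_default, seed = 2, step = 5,
                       method = "cell", breakdown = TRUE)
  fb <- compute_forces(sys, ff_default, seed = 2, step = 5,
                       method = "brute", breakdown = TRUE)
  expect_lt(max(abs(fc$force - fb$force)), 1e-12)
  # Newton's third law: conservative + thermostat forces sum to zero
  for (part in c("conservative", "dissipative", "random")) {
    expect_equal(colSums(fc[[part]]), c(0, 0, 0), tolerance = 1e-10)
  }
  # explicit two-bead antisymmetry on random samples
  set.seed(9)
  for (k in 1:25) {
    p <- matrix(runif(6, 0, 3), 2, 3, byrow = TRUE)
    two <- dpd_system(positions = p, velocities = matrix(rnorm(6), 2),
                      species = sample(ff_default$species[1:3], 2,
                                       replace = TRUE), box_edge = 4)
    f <- compute_forces(two, ff_default, seed = k, step = 1)$force
    expect_equal(f[1, ], -f[2, ], tolerance = 1e-14)
  }
})

test_that("integration conserves momentum and is restartable bitwise", {
  sys <- random_water_box(375, 5, seed = 3)
  tr <- run_dpd(sys, ff_default, n_steps = 50, seed = 5)
  expect_equal(total_momentum(tr$system), c(0, 0, 0), tolerance = 50 * 1e-10)
  # free streaming: zero forces move beads by v dt
  ff0 <- ff_default
  ff0$repulsion[] <- 0
  ff0$thermostat$sigma <- 0
  ff0$thermostat$gamma <- 0
  ff0$electrostatics$enabled <- FALSE
  one <- dpd_system(positions = rbind(c(1, 1, 1), c(3, 3, 3)),
                    velocities = rbind(c(0.5, 0, 0), c(0, -0.25, 0)),
                    species = c("W", "W"), box_edge = 5)
  tr1 <- run_dpd(one, ff0, n_steps = 100, seed = 1)
  expect_equal(tr1$system$positions[1, 1], 1 + 0.5 * 1, tolerance = 1e-12)
  expect_equal(tr1$system$positions[2, 2], 3 - 0.25 * 1, tolerance = 1e-12)
  # snapshot count: stride 10 over 100 steps yields 11 frames with t = 0
  tr2 <- run_dpd(sys, ff_default, n_steps = 100, seed = 5,
                 snapshot_stride = 10)
  expect_length(tr2$frames, 11)
  expect_equal(tr2$frames[[1]]$time, 0)
  # checkpoint restart reproduces the uninterrupted run bitwise
  trA <- run_dpd(sys, ff_default, n_steps = 60, seed = 5)
  trB <- run_dpd(trA$system, ff_default, n_steps = 60, seed = 5,
                 step0 = trA$step, restart_force = trA$force)
  trF <- run_dpd(sys, ff_default, n_steps = 120, seed = 5)
  expect_identical(trB$system$positions, trF$system$positions)
  expect_identical(trB$system$velocities, trF$system$velocities)
})

test_that("breaking the fluctuation-dissipation link biases the temperature", {
  sys <- random_water_box(375, 5, seed = 13)
  ff_bad <- ff_default
  ff_bad$thermostat$gamma <- 2  # sigma = 3 kept: sigma^2 != 2 gamma kT
  tr <- run_dpd(sys, ff_bad, n_steps = 1500, seed = 7,
                temperature_stride = 10)
  t_bad <- mean(tail(tr$temperature, 75))
  # equipartition target for the broken pair is sigma^2/(2 gamma) = 2.25
  expect_gt(t_bad, 1.5)
  tr_ok <- run_dpd(sys, ff_default, n_steps = 1500, seed = 7,
                   temperature_stride = 10)
  expect_lt(abs(mean(tail(tr_ok$temperature, 75)) - 1), 0.05)
})

test_that("ideal-fluid velocities relax to a Maxwellian", {
  ff0 <- ff_default
  ff0$repulsion[] <- 0
  ff0$electrostatics$enabled <- FALSE
  set.seed(21)
  # start far from equilibrium: bimodal velocities
  n <- 500
  sys <- dpd_system(positions = matrix(runif(3 * n, 0, 6), ncol = 3),
                    velocities = bimodal_v(3 * n),
                    species = rep("W", n), box_edge = 6)
  tr <- run_dpd(sys, ff0, n_steps = 800, seed = 3, snapshot_stride = 100)
  pooled <- unlist(lapply(tr$frames[5:9], function(fr) fr$velocities))
  # shape test at the realized kinetic temperature (the small integrator
  # temperature bias is asserted separately by the thermostat check)
  ks <- stats::ks.test(pooled, "pnorm", mean = 0,
                       sd = sqrt(mean(pooled^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("Lees-Edwards boundaries wrap the offset and reduce to PBC", {
  sys <- random_water_box(50, 5, seed = 2)
  # zero rate: identical to a periodic wrap
  s0 <- apply_lees_edwards(sys, 0, 0.01)
  expect_equal(s0$positions, wrap_positions(sys$positions, 5))
  expect_equal(s0$shear_offset, 0)
  # offset accumulates modulo L
  s1 <- sys
  for (k in 1:7) s1 <- apply_lees_edwards(s1, 20, 0.05)
  expect_equal(s1$shear_offset, (7 * 20 * 5 * 0.05) %% 5)
  expect_true(s1$shear_offset >= 0 && s1$shear_offset < 5)
  # crossing the sheared boundary shifts x and corrects vx
  one <- dpd_system(positions = rbind(c(2, 2, 4.99)),
                    velocities = rbind(c(0, 0, 1)),
                    species = "W", box_edge = 5)
  one$positions[1, 3] <- 5.2  # pretend it just left the box
  out <- apply_lees_edwards(one, 0.1, 0.2)
  expect_lt(out$positions[1, 3], 5)
  expect_equal(out$velocities[1, 1], -0.1 * 5)
})
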