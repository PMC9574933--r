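# Unit mapping, conversions and force-field loading.

test_that("unit map reproduces the water-matched length and time scales", {
  um <- build_unit_map(298.15, 997, 2, 3)
  expect_equal(um$length_scale * 1e10, 5.65, tolerance = 0.002)
  expect_equal(um$mass_scale, 5.98e-26, tolerance = 0.002)
  expect_equal(um$energy_scale, 4.11e-21, tolerance = 0.002)
  # tau = r_C sqrt(m / kT)
  expect_equal(um$time_scale,
               um$length_scale * sqrt(um$mass_scale / um$energy_scale))
  # cube-root dependence on the water density
  um8 <- build_unit_map(298.15, 997 * 8, 2, 3)
  expect_equal(um8$length_scale, um$length_scale / 2)
  expect_error(build_unit_map(-1, 997, 2, 3), "temperature_kelvin")
  expect_error(build_unit_map(298, -5, 2, 3), "water_mass_density")
})

test_that("conversion round-trips and known worked values", {
  um <- build_unit_map()
  set.seed(1)
  for (k in 1:20) {
    dims <- sample(-2:2, 4, replace = TRUE)
    v <- runif(1, 0.1, 100)
    back <- convert_units(convert_units(v, dims, "to_si", um),
                          dims, "to_reduced", um)
    expect_equal(back, v, tolerance = 1e-12)
  }
  # the n = 0 hexagonal spacing in real units
  expect_equal(convert_units(7.52, c(length = 1), "to_si", um) * 1e9,
               4.25, tolerance = 0.002)
  # friction coefficient mass/time
  expect_equal(convert_units(4.5, c(mass = 1, time = -1), "to_si", um),
               1.25e-13, tolerance = 0.002)
  expect_identical(convert_units(0, c(energy = 1), "to_si", um), 0)
  expect_error(convert_units(1, c(banana = 1), "to_si", um), "banana")
})

test_that("fluctuation-dissipation link between sigma and gamma", {
  expect_equal(gamma_from_sigma(3, 1), 4.5)
  expect_equal(gamma_from_sigma(0, 1), 0)
  expect_equal(gamma_from_sigma(2, 2), 1)
  expect_error(gamma_from_sigma(3, 0), "positive")
  # identity on positive reals
  for (g in c(0.1, 1, 4.5, 20)) {
    expect_equal(gamma_from_sigma(sigma_from_gamma(g, 1.3), 1.3), g)
  }
})

test_that("bond-length rule is symmetric, monotone and rejects gaps", {
  rule <- ff_default$bond_rule
  for (p in list(c(2, 2), c(2, 3), c(3, 4), c(1, 4))) {
    expect_equal(bond_length(p[1], p[2], rule),
                 bond_length(p[2], p[1], rule))
  }
  # monotone non-decreasing in the total heavy-atom count
  tot <- 2:8
  l <- vapply(tot, function(s) bond_length(1, s - 1, rule), numeric(1))
  expect_true(all(diff(l) >= 0))
  expect_error(bond_length(0, 2, rule), ">= 1")
  tab_rule <- list(type = "pair_table", table = list(`2-2` = 0.45))
  expect_equal(bond_length(2, 2, tab_rule), 0.45)
  expect_error(bond_length(2, 3, tab_rule), "2-3")
})

test_that("force-field loading validates structural invariants", {
  expect_s3_class(ff_default, "dpd_force_field")
  expect_identical(unname(ff_default$cutoff["W", "W"]), 1)
  expect_true(isSymmetric(ff_default$repulsion))
  cfg <- jsonlite::fromJSON(default_force_field_path())
  bad <- cfg
  bad$repulsion[1, 2] <- bad$repulsion[1, 2] + 1
  expect_error(load_force_field(bad), "not symmetric.*CT|CT.*not symmetric")
  bad2 <- cfg
  bad2$thermostat$gamma <- 4
  expect_error(load_force_field(bad2), "fluctuation-dissipation")
  bad3 <- cfg
  bad3$cutoff[1, 1] <- 0.9
  expect_error(load_force_field(bad3), "water-water cutoff")
})

test_that("electrostatic coupling and bead volumes follow the unit map", {
  g <- electro_coupling(um_default, 78.3)
  expect_equal(g, dpd_constants$e^2 /
                 (um_default$energy_scale * dpd_constants$eps0 * 78.3 *
                    um_default$length_scale))
  expect_equal(bead_volume(1, "half_cutoff"), 4 / 3 * pi / 8)
  expect_equal(bead_volume(1, "cutoff"), 4 / 3 * pi)
})
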