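# Molecule construction, polydispersity sampling and box composition.

test_that("SLEnS chains carry the requested ethoxylation", {
  t0 <- build_slens(0, ff_default)
  t3 <- build_slens(3, ff_default)
  expect_equal(length(t3$bead_sequence) - length(t0$bead_sequence), 3)
  expect_equal(sum(t3$bead_sequence == "EO"), 3)
  expect_equal(sum(t0$bead_sequence == "EO"), 0)
  expect_equal(unname(t0$net_charge), -1)
  # bonds connect adjacent beads with rule-derived rest lengths
  t2 <- build_slens(2, ff_default)
  nb <- length(t2$bead_sequence)
  expect_equal(t2$bonds$from, seq_len(nb - 1))
  expect_equal(t2$bonds$to, 2:nb)
  heavy <- ff_default$heavy_atoms[t2$bead_sequence]
  expect_equal(t2$bonds$l0,
               unname(bond_length(heavy[-nb], heavy[-1],
                                  ff_default$bond_rule)))
  # every interior bead sits in exactly one angle triple
  expect_equal(nrow(t2$angles), nb - 2)
  expect_equal(t2$angles$j, 2:(nb - 1))
  expect_error(build_slens(-1), "non-negative")
})

test_that("ethoxylation sampling is deterministic and hits its mean", {
  pm <- sample_ethoxylation(list(support = 1, weights = 1), 100, seed = 3)
  expect_equal(unname(pm), 100)
  aes <- aes_distribution()
  expect_equal(aes$mean, 0.76, tolerance = 1e-12)
  expect_equal(sum(aes$weights), 1)
  c1 <- sample_ethoxylation(aes, 5000, seed = 11)
  c2 <- sample_ethoxylation(aes, 5000, seed = 11)
  expect_identical(c1, c2)
  # binomial standard error bound on a large draw
  half <- list(support = 0:1, weights = c(0.5, 0.5))
  cc <- sample_ethoxylation(half, 1e6, seed = 5)
  expect_equal(sum(0:1 * cc) / 1e6, 0.5, tolerance = 0.01)
  expect_error(sample_ethoxylation(list(support = 0:1, weights = c(1, 1)),
                                   10), "sum to 1")
  # exchangeability: permuting support with weights permutes the counts
  d1 <- list(support = c(0, 3), weights = c(0.7, 0.3))
  d2 <- list(support = c(3, 0), weights = c(0.3, 0.7))
  s1 <- sample_ethoxylation(d1, 1000, seed = 9)
  s2 <- sample_ethoxylation(d2, 1000, seed = 9)
  expect_equal(unname(s1[c("0", "3")]), unname(s2[c("0", "3")]))
})

test_that("compositions balance mass, charge and bead count", {
  topo <- build_slens(0, ff_default)
  c0 <- composition_from_weight_percent(10, 0, topo, force_field = ff_default)
  expect_equal(c0$water_count, round(3 * 10^3))
  expect_equal(sum(c0$molecule_counts), 0)
  for (L in c(10, 20)) {
    for (wt in c(7, 30, 55, 80)) {
      cp <- composition_from_weight_percent(L, wt, topo,
                                            force_field = ff_default)
      expect_equal(cp$total_charge, 0)
      nb <- length(topo$bead_sequence)
      expect_equal(sum(cp$molecule_counts) * (nb + 1) + cp$water_count,
                   round(3 * L^3))
      expect_lt(abs(cp$weight_percent_realized - wt), 0.5)
      # independent mass-balance recomputation from the returned counts
      m <- sum(cp$molecule_counts)
      mass_s <- m * molecule_molar_mass(topo, ff_default)
      mass_w <- (cp$water_count + cp$sodium_count) *
        ff_default$molar_masses[["W"]]
      expect_equal(100 * mass_s / (mass_s + mass_w),
                   cp$weight_percent_realized)
    }
  }
  expect_error(composition_from_weight_percent(10, 100, topo),
               "weight_percent")
})

test_that("random initial configurations are reproducible and thermalized", {
  topo <- build_slens(1, ff_default)
  comp <- composition_from_weight_percent(8, 20, topo,
                                          force_field = ff_default)
  s1 <- random_initial_configuration(comp, seed = 4)
  s2 <- random_initial_configuration(comp, seed = 4)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$velocities, s2$velocities)
  expect_equal(total_momentum(s1), c(0, 0, 0), tolerance = 1e-10)
  # mean KE per dof = 1/2 within 3 standard errors (chi-squared bound)
  n <- nrow(s1$positions)
  ke_dof <- sum(s1$velocities^2) / (3 * n)
  se <- sqrt(2 / (3 * n))
  expect_lt(abs(ke_dof - 1), 3 * se)
  # bonded neighbours start at their rest length
  b1 <- s1$bonds[1, ]
  d <- min_image_disp(s1$positions[b1$j, ] - s1$positions[b1$i, ],
                      s1$box_edge)
  expect_equal(sqrt(sum(d^2)), b1$l0, tolerance = 1e-9)
})
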