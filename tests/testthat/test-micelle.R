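# Micelle identification, aggregation statistics and shape.

test_that("tail-contact clustering recovers planted micelles", {
  sys <- make_micelle_field(c(30, 30), L = 20, target_rg = 2, seed = 5)
  ms <- find_micelles(sys)
  expect_equal(sort(ms$sizes), c(30, 30))
  expect_equal(sum(ms$sizes), 60)
  # a lone molecule forms its own cluster of size 1
  sys1 <- make_micelle_field(c(1), L = 10, target_rg = 0.7, seed = 2)
  ms1 <- find_micelles(sys1)
  expect_equal(ms1$sizes, 1)
  # empty system: empty set, not an error
  w <- dpd_system(positions = matrix(runif(30, 0, 5), ncol = 3),
                  species = rep("W", 10), box_edge = 5)
  expect_length(find_micelles(w)$sizes, 0)
})

test_that("clustering matches a brute-force union-find oracle", {
  # dense random field of small molecules so clusters are nontrivial
  set.seed(14)
  L <- 8
  nmol <- 50
  pos <- NULL; mols <- integer(0); specs <- character(0)
  for (m in seq_len(nmol)) {
    base <- runif(3, 0, L)
    xyz <- matrix(base, 3, 3, byrow = TRUE) +
      matrix(rnorm(9, sd = 0.3), 3, 3)
    pos <- rbind(pos, xyz)
    mols <- c(mols, rep(m, 3))
    specs <- c(specs, "CT", "CM", "ES")
  }
  sys <- dpd_system(positions = pos, species = specs, molecule = mols,
                    box_edge = L)
  ms <- find_micelles(sys, cutoff = 1.0)
  oracle <- oracle_clusters(sys, cutoff = 1.0)
  expect_same_partition(unname(ms$assignment), oracle)
  expect_equal(sum(ms$sizes), nmol)
})

test_that("clustering is invariant under global translation and wrap", {
  sys <- make_micelle_field(c(12, 20, 7), L = 18, target_rg = 1.5, seed = 8)
  ms0 <- find_micelles(sys)
  sys2 <- sys
  sys2$positions <- wrap_positions(
    sweep(sys2$positions, 2, c(7.3, -4.1, 11.9), `+`), sys2$box_edge)
  ms2 <- find_micelles(sys2)
  expect_equal(sort(ms0$sizes), sort(ms2$sizes))
  expect_same_partition(unname(ms0$assignment), unname(ms2$assignment))
})

test_that("aggregation series tracks micelle counts over frames", {
  sys <- make_micelle_field(c(30, 30), L = 20, target_rg = 2, seed = 5)
  ser <- aggregation_series(list(sys, sys, sys))
  expect_equal(ser$n_agg, rep(30, 3))
  # merging two micelles doubles the mean at the merge frame
  merged <- make_micelle_field(c(60), L = 20, target_rg = 2.5, seed = 5)
  ser2 <- aggregation_series(list(sys, merged))
  expect_equal(ser2$n_agg, c(30, 60))
  # molecule-weighted mean is never below the micelle-weighted mean
  mixed <- make_micelle_field(c(10, 50), L = 20, target_rg = 1.8, seed = 6)
  a <- aggregation_series(list(mixed), weighting = "micelle")$n_agg
  b <- aggregation_series(list(mixed), weighting = "molecule")$n_agg
  expect_gt(b, a)
})

test_that("block-average equilibration detection", {
  tt <- seq(0, 49900, by = 100)
  # constant series: first block
  res <- equilibration_point(data.frame(time = tt, n_agg = rep(40, 500)),
                             5000)
  expect_equal(res$block, 1)
  # monotone ramp with no plateau
  res2 <- equilibration_point(data.frame(time = tt, n_agg = tt / 100), 5000)
  expect_identical(res2, "not equilibrated")
  expect_error(equilibration_point(data.frame(time = 1:10, n_agg = 1:10),
                                   5000), "3 blocks")
  # ramp-then-plateau with unit noise: detected within one block in >= 95%
  # of seeded replicates
  hits <- 0
  for (r in 1:200) {
    set.seed(r)
    mu <- ifelse(tt < 15000, 20 + 30 * tt / 15000, 50)
    res3 <- equilibration_point(
      data.frame(time = tt, n_agg = mu + rnorm(length(tt))), 5000)
    if (is.list(res3) && abs(res3$block - 4) <= 1) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("radius of gyration: exact small cases and the sphere moment", {
  expect_equal(as.numeric(radius_of_gyration(rbind(c(1, 2, 3)))), 0)
  expect_equal(as.numeric(radius_of_gyration(rbind(c(0, 0, 0),
                                                   c(2, 0, 0)))), 1)
  # 1e4 uniform points in a sphere of radius R: R_G -> sqrt(3/5) R
  set.seed(3)
  R <- 2
  u <- matrix(rnorm(3e4), ncol = 3)
  pts <- u / sqrt(rowSums(u^2)) * R * runif(1e4)^(1 / 3)
  expect_equal(as.numeric(radius_of_gyration(pts)), sqrt(3 / 5) * R,
               tolerance = 0.01)
  # consistency through the sphere-radius map
  expect_equal(sphere_radius(as.numeric(radius_of_gyration(pts))), R,
               tolerance = 0.01)
  expect_equal(sphere_radius(0), 0)
  expect_equal(sphere_radius(sqrt(3 / 5)), 1)
  # unwrapping: a cluster split across the boundary
  split <- rbind(c(0.2, 1, 1), c(9.8, 1, 1))
  expect_equal(as.numeric(radius_of_gyration(split, box_edge = 10)), 0.2)
  # percolating cluster flagged
  line <- cbind(seq(0, 9.5, by = 0.5), 1, 1)
  expect_warning(radius_of_gyration(line, box_edge = 10), "percolat")
})

test_that("sphericity profile locates the most-spherical size", {
  # exactly flat profile: minimum undefined
  flat <- structure(list(sizes = rep(seq(20, 80, by = 5), each = 4),
                         r_gyration = (0.02 *
                             rep(seq(20, 80, by = 5), each = 4))^(1 / 3)),
                    class = "micelle_set")
  pf <- sphericity_profile(flat)
  expect_false(pf$minimum_defined)
  # parabolic profile with a minimum at N = 55
  Ns <- rep(seq(30, 80, by = 5), each = 6)
  y <- 0.02 + 1e-5 * (Ns - 55)^2
  par <- structure(list(sizes = Ns, r_gyration = (y * Ns)^(1 / 3)),
                   class = "micelle_set")
  pp <- sphericity_profile(par)
  expect_true(pp$minimum_defined)
  expect_lt(abs(pp$N_star - 55), 5)
  expect_equal(pp$R_G_star, (0.02 * 55)^(1 / 3), tolerance = 0.02)
  # a single populated bin cannot define a minimum
  one <- structure(list(sizes = rep(40, 5), r_gyration = rep(1.2, 5)),
                   class = "micelle_set")
  expect_false(sphericity_profile(one)$minimum_defined)
  expect_equal(pp$bins$bin[2] - pp$bins$bin[1], 5)
})

test_that("composition mixing statistic is calibrated on multinomial nulls", {
  set.seed(42)
  w <- c(0.5, 0.3, 0.2)
  comp <- lapply(1:200, function(i) {
    as.table(stats::setNames(stats::rmultinom(1, 50, w)[, 1], 0:2))
  })
  msl <- structure(list(composition = comp, sizes = rep(50, 200)),
                   class = "micelle_set")
  mix <- composition_mixing(msl, list(support = 0:2, weights = w), seed = 7)
  frac <- mean(mix$null_quantile > 0.95)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.12)
  # a micelle made entirely of the rarest species is an extreme outlier
  comp2 <- c(comp[1:20],
             list(as.table(stats::setNames(c(0, 0, 30), 0:2))))
  msl2 <- structure(list(composition = comp2,
                         sizes = c(rep(50, 20), 30)),
                    class = "micelle_set")
  mix2 <- composition_mixing(msl2, list(support = 0:2, weights = w),
                             seed = 7)
  expect_gt(tail(mix2$null_quantile, 1), 0.999)
  # size-1 micelles still get a defined quantile
  comp3 <- c(comp[1:5], list(as.table(stats::setNames(c(1, 0, 0), 0:2))))
  msl3 <- structure(list(composition = comp3, sizes = c(rep(50, 5), 1)),
                    class = "micelle_set")
  mix3 <- composition_mixing(msl3, list(support = 0:2, weights = w),
                             seed = 7)
  expect_true(all(is.finite(mix3$null_quantile)))
  # monodisperse input is rejected
  mono <- structure(list(composition = lapply(1:4, function(i) {
    as.table(stats::setNames(5, "0"))
  }), sizes = rep(5, 4)), class = "micelle_set")
  expect_error(composition_mixing(mono), "monodisperse")
})
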