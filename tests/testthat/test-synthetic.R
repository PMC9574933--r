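# Ground-truth fixture generators.

test_that("micelle fields honour their ground truth and are reproducible", {
  s1 <- make_micelle_field(c(30, 50), L = 20, target_rg = 2, seed = 3)
  s2 <- make_micelle_field(c(30, 50), L = 20, target_rg = 2, seed = 3)
  expect_identical(s1$positions, s2$positions)
  ms <- find_micelles(s1)
  expect_equal(sort(ms$sizes), c(30, 50))
  # measured core R_G within 2% of the target on a large micelle
  # (finite-N moment: the sampling error shrinks as 1/sqrt(beads))
  big <- make_micelle_field(300, L = 20, target_rg = 2, seed = 4)
  msb <- find_micelles(big)
  expect_equal(unname(msb$r_gyration), 2, tolerance = 0.02)
  # infeasible packing is rejected
  expect_error(make_micelle_field(rep(40, 30), L = 10, target_rg = 2),
               "packing infeasible")
})

test_that("fixtures at reduced density 3 are charge neutral and complete", {
  mf <- make_micelle_field(c(20, 25), L = 12, target_rg = 1.6, seed = 4,
                           fill_water = TRUE)
  expect_equal(nrow(mf$positions), round(3 * 12^3))
  expect_equal(sum(mf$charge), 0)
  lam <- make_lamellar(L = 16, kappa_vec = c(4, 0, 0), seed = 5)
  expect_equal(nrow(lam$positions), round(3 * 16^3))
  expect_equal(sum(lam$charge), 0)
  hx <- make_hexagonal(L = 20, a = c(10, 0), b = c(0, 10), seed = 6,
                       axial_spacing = 1, mols_per_station = 4)
  expect_equal(nrow(hx$positions), round(3 * 20^3))
  expect_equal(sum(hx$charge), 0)
})

test_that("lamellar fixtures satisfy the layer commensuration they claim", {
  lam <- make_lamellar(L = 40, kappa_vec = c(4, 1, 0), seed = 8)
  gt <- attr(lam, "ground_truth")
  expect_equal(gt$d, 40 / sqrt(17))
  expect_equal(gt$kappa, 4)
  # measured d equals a member of the allowed catalog
  m <- measure_lamellar(lam)
  cat40 <- allowed_d_spacings(40, 5, 15)
  expect_lt(min(abs(cat40$d - m$d)), 1e-6)
  # bridged variant reports its defect
  lamb <- make_lamellar(L = 16, kappa_vec = c(4, 0, 0), bridge = TRUE,
                        seed = 9)
  expect_true(attr(lamb, "ground_truth")$bridged)
})

test_that("hexagonal fixtures reject bad lattices and recover under noise", {
  # non-tiling vectors are refused
  expect_error(make_hexagonal(L = 40, a = c(9, 0), b = c(4, 8),
                              density = 0), "tile")
  # rod overlap is refused
  expect_error(make_hexagonal(L = 40, a = c(4, 0), b = c(0, 4),
                              density = 0), "overlap")
  # lattice vectors recovered within 2% at noise 0.2
  hx <- make_hexagonal(L = 40, a = c(10, 0), b = c(4, 8), density = 0,
                       seed = 7, noise_sigma = 0.2)
  fit <- measure_hexagonal(hx)
  truth <- attr(hx, "ground_truth")
  expect_equal(sort(fit$lengths), sort(truth$lengths), tolerance = 0.02)
  # orientation class: axis-aligned lattice vector of a commensurate cell
  expect_equal(fit$orientation, "parallel")
})
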