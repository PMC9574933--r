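# Lamellar and hexagonal periodicity analysis and spacing catalogs.

test_that("nematic director from molecular orientations", {
  # molecules all along z (sign-mixed: nematic, not polar)
  set.seed(6)
  n <- 40
  base <- matrix(runif(3 * n, 2, 18), ncol = 3)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  pos <- NULL; mols <- integer(0); specs <- character(0)
  for (m in seq_len(n)) {
    head <- base[m, ] + c(0, 0, sgn[m] * 1.5)
    pos <- rbind(pos, base[m, ], head)
    mols <- c(mols, m, m)
    specs <- c(specs, "CT", "ES")
  }
  sys <- dpd_system(positions = pos, species = specs, molecule = mols,
                    box_edge = 20)
  d <- lamellar_director(sys)
  expect_equal(abs(d[3]), 1, tolerance = 1e-9)
  # isotropic orientations: no director
  set.seed(7)
  pos2 <- NULL; mols2 <- integer(0); specs2 <- character(0)
  for (m in 1:200) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    b <- runif(3, 2, 18)
    pos2 <- rbind(pos2, b, b + 1.5 * u)
    mols2 <- c(mols2, m, m)
    specs2 <- c(specs2, "CT", "ES")
  }
  sys2 <- dpd_system(positions = pos2, species = specs2, molecule = mols2,
                     box_edge = 20)
  expect_null(lamellar_director(sys2, degeneracy_tol = 0.3))
  expect_error(lamellar_director(sys, degeneracy_tol = 0.01,
                                 head_species = "none"), "10 molecules")
})

test_that("layer counting by commensurate density waves", {
  lam5 <- make_lamellar(L = 20, kappa_vec = c(5, 0, 0), seed = 3)
  dir5 <- lamellar_director(lam5)
  lc <- layer_count(lam5, dir5)
  expect_equal(lc$kappa, 5)
  # tilted 8-layer stack: kappa_vec (8, 2, 0)
  lam8 <- make_lamellar(L = 40, kappa_vec = c(8, 2, 0), seed = 4)
  m8 <- measure_lamellar(lam8)
  expect_equal(m8$kappa, 8)
  expect_equal(m8$d, 40 / sqrt(68), tolerance = 1e-9)
  # uniform random positions: rejected as non-lamellar
  set.seed(5)
  posr <- NULL; molsr <- integer(0); specsr <- character(0)
  for (m in 1:150) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    b <- runif(3, 0, 20)
    posr <- rbind(posr, b, b + 1.5 * u)
    molsr <- c(molsr, m, m)
    specsr <- c(specsr, "CT", "ES")
  }
  rnd <- dpd_system(positions = posr, species = specsr, molecule = molsr,
                    box_edge = 20)
  expect_error(measure_lamellar(rnd))
})

test_that("d-spacing closed form and generator round trips", {
  expect_equal(d_spacing(40, 0, 5), 8)
  expect_equal(d_spacing(40, 60, 2), 10)
  expect_error(d_spacing(40, 95, 2))
  # pipeline recovers a tilted generating spacing within 1%
  lam <- make_lamellar(L = 40, kappa_vec = c(4, 1, 0), seed = 8,
                       noise_sigma = 0.1)
  truth <- attr(lam, "ground_truth")
  m <- measure_lamellar(lam)
  expect_equal(m$d, truth$d, tolerance = 0.01)
  expect_equal(m$theta, truth$theta, tolerance = 0.5)
})

test_that("allowed d-spacing catalog matches the closed form and an oracle", {
  cat40 <- allowed_d_spacings(40, 5, 41)
  expect_true(10 %in% signif(cat40$d, 3))          # kappa = (4,0,0)
  expect_true(signif(40 / sqrt(17), 3) %in% signif(cat40$d, 3))
  # strictly decreasing with increasing |kappa|^2
  expect_true(all(diff(cat40$d) < 0))
  # every entry reproduces its spacing from its integers
  expect_equal(cat40$d,
               40 / sqrt(cat40$kx^2 + cat40$ky^2 + cat40$kz^2))
  # brute-force oracle over a bounded integer cube
  oracle <- sort(unique(signif(
    40 / sqrt(rowSums(as.matrix(
      expand.grid(0:12, 0:12, 0:12)[-1, ])^2)), 3)))
  oracle <- oracle[oracle > 5 & oracle < 41]
  expect_equal(sort(signif(cat40$d, 3)), oracle)
  expect_equal(nrow(allowed_d_spacings(40, 50, 60)), 0)
})

test_that("rod detection and lattice fitting on hexagonal fixtures", {
  hx <- make_hexagonal(L = 40, a = c(10, 0), b = c(4, 8), density = 0,
                       seed = 2)
  truth <- attr(hx, "ground_truth")
  rods <- detect_rods(hx)
  expect_equal(rods$axis, 1)
  expect_equal(nrow(rods$centers), 20)
  # centres match the generators within 0.1 (after matching)
  dmin <- apply(rods$centers, 1, function(ct) {
    min(sqrt(rowSums(min_image_disp(
      truth$centers - matrix(ct, nrow(truth$centers), 2, byrow = TRUE),
      40)^2)))
  })
  expect_lt(max(dmin), 0.1)
  fit <- fit_hexagonal_lattice(rods$centers, 40)
  expect_equal(fit$r_s, (10 + sqrt(80) + 10) / 3, tolerance = 0.002)
  expect_true(fit$commensurate)
  expect_true(fit$hexagonal)
  expect_equal(fit$orientation, "parallel")
  # lamellar input is rejected
  lam <- make_lamellar(L = 20, kappa_vec = c(4, 0, 0), seed = 3)
  expect_error(detect_rods(lam), "not hexagonal")
})

test_that("lattice fit is robust to noise and invariant to relabeling", {
  hx <- make_hexagonal(L = 40, a = c(10, 0), b = c(4, 8), density = 0,
                       seed = 4, noise_sigma = 0.2)
  fit <- measure_hexagonal(hx)
  expect_equal(fit$r_s, 9.6481, tolerance = 0.02)   # within 2% under noise
  # perfect lattice given directly: r_S = s exactly
  s <- 5
  ctr <- as.matrix(expand.grid(0:3, 0:3))
  perfect <- cbind(ctr[, 1] * s + ctr[, 2] * s / 2,
                   ctr[, 2] * s * sqrt(3) / 2)
  fitp <- fit_hexagonal_lattice(perfect, 40)
  expect_equal(fitp$lengths, rep(s, 3), tolerance = 1e-6)
  expect_equal(fitp$r_s, s, tolerance = 1e-6)
  # relabeling and rigid translation leave the fit unchanged
  hxc <- detect_rods(hx)$centers
  set.seed(11)
  perm <- sample(nrow(hxc))
  shift <- wrap_positions(hxc[perm, ] + matrix(c(3.7, -8.1), nrow(hxc), 2,
                                               byrow = TRUE), 40)
  fit2 <- fit_hexagonal_lattice(shift, 40)
  expect_equal(sort(fit2$lengths), sort(fit$lengths), tolerance = 1e-9)
})

test_that("hexagonal spacing catalog: membership, count, oracle equality", {
  cat40 <- allowed_r_s(40, 1.5, 7.5, 11)
  expect_true(9.65 %in% signif(cat40$r_s, 3))
  expect_true(7.52 %in% signif(cat40$r_s, 3))
  expect_equal(nrow(cat40), 10)
  # every entry's reduced basis reproduces its three lengths
  for (k in seq_len(nrow(cat40))) {
    a <- c(cat40$ax[k], cat40$ay[k]); b <- c(cat40$bx[k], cat40$by[k])
    lens <- sort(c(sqrt(sum(a^2)), sqrt(sum(b^2)),
                   min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))))
    expect_equal(lens, c(cat40$l1[k], cat40$l2[k], cat40$l3[k]),
                 tolerance = 1e-9)
  }
  # exact agreement with the bounded brute-force enumeration
  expect_equal(signif(cat40$r_s, 3),
               allowed_r_s_bruteforce(40, 1.5, 7.5, 11, bound = 8))
})

test_that("phase classification distinguishes the three structures", {
  mf <- make_micelle_field(c(30, 40), L = 20, target_rg = 2, seed = 5)
  expect_equal(classify_phase(mf)$label, "micellar")
  hx <- make_hexagonal(L = 40, a = c(10, 0), b = c(4, 8), density = 0,
                       seed = 2)
  pc <- classify_phase(hx)
  expect_equal(pc$label, "hexagonal")
  expect_equal(pc$hexagonal$r_s, 9.648, tolerance = 0.01)
  # bridges in 10% of frames: imperfect lamellar
  frames <- lapply(1:10, function(i) {
    make_lamellar(L = 20, kappa_vec = c(4, 0, 0), bridge = (i == 1),
                  seed = 100 + i)
  })
  pcb <- classify_phase(frames)
  expect_equal(pcb$label, "lamellar-imperfect")
  expect_equal(pcb$evidence$bridge_rate, 0.1)
  pcp <- classify_phase(frames[2:6])
  expect_equal(pcp$label, "lamellar-perfect")
})

test_that("volume model fit recovers the layer thickness", {
  set.seed(10)
  ratio <- c(1.3, 1.7, 2.2, 2.9, 3.6)
  d_obs <- 6 * ratio
  fit <- fit_d_model(d_obs, ratio)
  expect_equal(fit$d_s, 6, tolerance = 1e-10)
  expect_equal(fit$residuals, rep(0, 5), tolerance = 1e-10)
  # with noise the estimate stays within a hundredth
  fitn <- fit_d_model(d_obs + rnorm(5, sd = 0.005), ratio)
  expect_equal(fitn$d_s, 6, tolerance = 0.01)
  # all-surfactant limit: ratio 1 means d = d_s
  expect_equal(fit_d_model(c(6, 6, 6), c(1, 1, 1))$d_s, 6)
  expect_error(fit_d_model(c(1, 2), c(1, 2)), "3 concentrations")
  # the ratio is scale invariant in the bead volumes
  topo <- build_slens(0, ff_default)
  comp <- composition_from_weight_percent(10, 50, topo,
                                          force_field = ff_default)
  r1 <- composition_volume_ratio(comp, ff_default)
  ff2 <- ff_default
  ff2$cutoff <- ff_default$cutoff * 2^(1 / 3) # doubles every bead volume
  expect_equal(composition_volume_ratio(comp, ff2), r1, tolerance = 1e-12)
})

test_that("ethoxylation interpolation coordinate", {
  expect_equal(interpolate_ethoxylation(7.52, 9.65, 7.52), 0)
  expect_equal(interpolate_ethoxylation(7.52, 9.65, 9.65), 1)
  expect_equal(interpolate_ethoxylation(7.52, 9.65, (7.52 + 9.65) / 2),
               0.5)
  expect_error(interpolate_ethoxylation(8, 8, 8.5), "undefined")
})
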