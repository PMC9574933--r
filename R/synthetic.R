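# Idealized particle configurations with known ground truth: geometric
# scaffolds that let every analysis stage be validated without long
# simulations. Not thermodynamically realistic.

#' Synthetic field of spherical micelles
#'
#' Places micelles of prescribed aggregation numbers at mutually separated
#' centres. Tail beads are sampled uniformly within a sphere of radius
#' \eqn{\sqrt{5/3}\,R_G} (so the measured core radius of gyration matches
#' the target up to finite-N fluctuation), ethoxy and head beads sit on the
#' shell along each molecule's outward direction, and one counterion
#' floats just outside. Optionally fills the remainder of the box with
#' water to reduced density 3.
#'
#' @param sizes integer vector: aggregation number of each micelle.
#' @param L box edge.
#' @param target_rg target core radius of gyration (scalar or per micelle).
#' @param n_ethoxy ethoxylation per molecule: scalar, or a list of
#'   per-micelle vectors.
#' @param noise_sigma isotropic Gaussian jitter applied to every bead.
#' @param seed RNG seed.
#' @param cutoff clustering cutoff the field must respect (micelle shells
#'   are separated by more than this).
#' @param fill_water fill with water beads to reduced density 3.
#' @param force_field force field (species, charges).
#' @return a [dpd_system()]; attribute `ground_truth` holds sizes, centres
#'   and the target radius.
#' @export
make_micelle_field <- function(sizes, L, target_rg = 2, n_ethoxy = 0,
                               noise_sigma = 0, seed = 1L, cutoff = 1.0,
                               fill_water = FALSE,
                               force_field = load_force_field()) {
  stopifnot(all(sizes >= 1), L > 0, noise_sigma >= 0)
  set.seed(seed)
  ff <- force_field
  nm <- length(sizes)
  rg <- rep_len(target_rg, nm)
  rs <- sqrt(5 / 3) * rg
  if (!is.list(n_ethoxy)) {
    n_ethoxy <- lapply(sizes, function(s) rep_len(n_ethoxy, s))
  }
  shell_extra <- vapply(n_ethoxy, function(v) 0.3 * (max(v) + 2), numeric(1))
  reach <- rs + shell_extra + 0.8       # outermost bead radius (counterion)
  # sequential random placement with separation > cutoff between shells
  centers <- matrix(NA_real_, nm, 3)
  for (i in seq_len(nm)) {
    ok <- FALSE
    for (try in seq_len(5000)) {
      cand <- stats::runif(3, 0, L)
      if (i == 1) { ok <- TRUE; break }
      d <- sqrt(rowSums(min_image_disp(
        centers[seq_len(i - 1), , drop = FALSE] -
          matrix(cand, i - 1, 3, byrow = TRUE), L)^2))
      if (all(d > reach[i] + reach[seq_len(i - 1)] + cutoff + 0.2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("packing infeasible: cannot place micelle ", i,
                  " without contact at the requested density",
                  call. = FALSE)
    centers[i, ] <- cand
  }
  mol_block <- ff_molecule(ff)
  tail_len <- length(mol_block$tail)
  pos <- list(); specs <- character(0); mols <- integer(0)
  mol_id <- 0L
  truth_n <- list()
  for (i in seq_len(nm)) {
    nvec <- n_ethoxy[[i]]
    truth_n[[i]] <- nvec
    for (m in seq_len(sizes[i])) {
      mol_id <- mol_id + 1L
      # uniform-in-sphere tail beads
      tp <- matrix(stats::rnorm(3 * tail_len), ncol = 3)
      tp <- tp / sqrt(rowSums(tp^2)) *
        (rs[i] * stats::runif(tail_len)^(1 / 3))
      u <- tp[tail_len, ]
      un <- sqrt(sum(u^2))
      u <- if (un > 1e-9) u / un else c(0, 0, 1)
      n_i <- nvec[m]
      shell <- NULL
      if (n_i > 0) {
        shell <- t(vapply(seq_len(n_i), function(j) {
          u * (rs[i] + 0.3 * j)
        }, numeric(3)))
      }
      head <- u * (rs[i] + 0.3 * (n_i + 1))
      na <- u * (rs[i] + 0.3 * (n_i + 1) + 0.8)
      beads <- rbind(tp, shell, head)
      pos[[length(pos) + 1L]] <- sweep(beads, 2, centers[i, ], `+`)
      pos[[length(pos) + 1L]] <- matrix(centers[i, ] + na, 1, 3)
      specs <- c(specs, mol_block$tail, rep(mol_block$ethoxy, n_i),
                 mol_block$head, mol_block$counterion)
      mols <- c(mols, rep(mol_id, tail_len + n_i + 1), NA_integer_)
    }
  }
  positions <- do.call(rbind, pos)
  specs_v <- specs; mols_v <- mols
  if (fill_water) {
    ntot <- round(3 * L^3)
    nw <- ntot - nrow(positions)
    if (nw > 0) {
      wpos <- matrix(NA_real_, 0, 3)
      while (nrow(wpos) < nw) {
        cand <- matrix(stats::runif(3 * nw * 2, 0, L), ncol = 3)
        dmin <- rep(Inf, nrow(cand))
        for (i in seq_len(nm)) {
          d <- sqrt(rowSums(min_image_disp(
            cand - matrix(centers[i, ], nrow(cand), 3, byrow = TRUE), L)^2))
          dmin <- pmin(dmin, d - reach[i])
        }
        wpos <- rbind(wpos, cand[dmin > 0.3, , drop = FALSE])
      }
      wpos <- wpos[seq_len(nw), , drop = FALSE]
      positions <- rbind(positions, wpos)
      specs_v <- c(specs_v, rep("W", nw))
      mols_v <- c(mols_v, rep(NA_integer_, nw))
    }
  }
  if (noise_sigma > 0) {
    positions <- positions + matrix(stats::rnorm(length(positions),
                                                 sd = noise_sigma),
                                    ncol = 3)
  }
  sys <- dpd_system(positions = positions, species = specs_v,
                    molecule = mols_v, charge = unname(ff$charges[specs_v]),
                    box_edge = L)
  attr(sys, "ground_truth") <- list(kind = "micellar", sizes = sizes,
                                    centers = centers, target_rg = rg,
                                    n_ethoxy = truth_n)
  sys
}

#' Synthetic lamellar stack
#'
#' Builds alternating surfactant bilayers and water slabs whose density
#' wave is the integer wave vector `kappa_vec` (PBC-commensurate by
#' construction): the d-spacing is \eqn{L/|\kappa|} and the layer normal
#' \eqn{\kappa/|\kappa|}. Molecules stand normal to the layers in two
#' leaflets with tails toward the midplane. Optionally carves a water
#' bridge through one bilayer (the "imperfect" defect).
#'
#' @param L box edge.
#' @param kappa_vec integer wave vector, e.g. `c(5, 0, 0)` for five
#'   untilted bilayers along x or `c(4, 2, 0)` for a tilted stack.
#' @param n_ethoxy ethoxylation of the (monodisperse) chains.
#' @param surf_fraction volume fraction of the repeat taken by the
#'   surfactant slab.
#' @param bridge insert a water channel through one bilayer.
#' @param thermal_sigma Gaussian spread applied to the chain beads so the
#'   tails fill the slab like a liquid (in-plane tail connectivity) rather
#'   than standing as isolated rigid lines; does not bias the density wave.
#' @param noise_sigma additional positional jitter on every bead.
#' @param seed RNG seed.
#' @param density reduced bead density.
#' @param force_field force field.
#' @return a [dpd_system()] with `ground_truth` (d, kappa, theta, normal).
#' @export
make_lamellar <- function(L, kappa_vec = c(5, 0, 0), n_ethoxy = 0,
                          surf_fraction = 0.5, bridge = FALSE,
                          thermal_sigma = 0.25, noise_sigma = 0, seed = 1L,
                          density = 3,
                          force_field = load_force_field()) {
  stopifnot(all(kappa_vec == round(kappa_vec)), any(kappa_vec != 0))
  set.seed(seed)
  ff <- force_field
  mol_block <- ff_molecule(ff)
  chain <- c(mol_block$tail, rep(mol_block$ethoxy, n_ethoxy),
             mol_block$head)
  nb <- length(chain)
  kn <- sqrt(sum(kappa_vec^2))
  nhat <- kappa_vec / kn
  d <- L / kn
  ntot <- round(density * L^3)
  n_mol <- 2 * round(surf_fraction * ntot / (2 * (nb + 1)))
  n_anchor <- n_mol / 2
  # uniform anchors projected to the nearest bilayer midplane
  anchors <- matrix(stats::runif(3 * n_anchor, 0, L), ncol = 3)
  phase <- anchors %*% kappa_vec / L          # midplanes at integer phase
  shift <- (phase - round(phase)) * d
  anchors <- anchors - outer(as.vector(shift), nhat)
  spacing <- 0.55 * d * surf_fraction / nb    # bead spacing along normal
  pos <- list(); specs <- character(0); mols <- integer(0)
  mol_id <- 0L
  for (leaf in c(1, -1)) {
    for (a in seq_len(n_anchor)) {
      mol_id <- mol_id + 1L
      off <- (seq_len(nb) - 0.5) * spacing * leaf
      pos[[length(pos) + 1L]] <- matrix(anchors[a, ], nb, 3, byrow = TRUE) +
        outer(off, nhat)
      specs <- c(specs, chain)
      mols <- c(mols, rep(mol_id, nb))
    }
  }
  positions <- do.call(rbind, pos)
  if (thermal_sigma > 0) {
    positions <- positions + matrix(stats::rnorm(length(positions),
                                                 sd = thermal_sigma),
                                    ncol = 3)
  }
  # water + ions in the inter-bilayer region
  n_na <- n_mol
  n_wat <- ntot - n_mol * nb - n_na
  s_half <- surf_fraction * d / 2
  sample_water_region <- function(n_needed) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n_needed) {
      cand <- matrix(stats::runif(3 * n_needed * 2, 0, L), ncol = 3)
      ph <- cand %*% kappa_vec / L
      dist_mid <- abs((ph - round(ph))) * d
      out <- rbind(out, cand[dist_mid > s_half, , drop = FALSE])
    }
    out[seq_len(n_needed), , drop = FALSE]
  }
  wat <- sample_water_region(n_wat)
  nap <- sample_water_region(n_na)
  positions <- rbind(positions, nap, wat)
  specs <- c(specs, rep(mol_block$counterion, n_na), rep("W", n_wat))
  mols <- c(mols, rep(NA_integer_, n_na + n_wat))
  bridged_at <- NULL
  if (bridge) {
    # water channel through one bilayer: beads along the normal at a random
    # in-plane location
    p0 <- anchors[sample.int(n_anchor, 1), ]
    ts <- seq(-s_half - 0.6, s_half + 0.6, by = 0.25)
    ch <- NULL
    for (strand in 1:3) {
      jit <- matrix(stats::rnorm(3 * length(ts), sd = 0.1), ncol = 3)
      ch <- rbind(ch, matrix(p0, length(ts), 3, byrow = TRUE) +
                    outer(ts, nhat) + jit)
    }
    positions <- rbind(positions, ch)
    specs <- c(specs, rep("W", nrow(ch)))
    mols <- c(mols, rep(NA_integer_, nrow(ch)))
    bridged_at <- p0
  }
  if (noise_sigma > 0) {
    positions <- positions + matrix(stats::rnorm(length(positions),
                                                 sd = noise_sigma),
                                    ncol = 3)
  }
  sys <- dpd_system(positions = positions, species = specs, molecule = mols,
                    charge = unname(ff$charges[specs]), box_edge = L)
  axis <- which.max(abs(kappa_vec))
  theta <- acos(abs(kappa_vec[axis]) / kn) * 180 / pi
  attr(sys, "ground_truth") <- list(kind = "lamellar", d = d,
                                    kappa = max(abs(kappa_vec)),
                                    kappa_vec = kappa_vec, theta = theta,
                                    normal = nhat, bridged = bridge,
                                    bridged_at = bridged_at)
  sys
}

#' Synthetic hexagonal rod lattice
#'
#' Rods of surfactant molecules run along a box axis at the points of the
#' two-dimensional lattice generated by `a` and `b` in the transverse
#' plane. The lattice must tile the periodic transverse cell (integer
#' combinations reach (L,0) and (0,L)) unless `allow_incommensurate`.
#' Molecules radiate from each rod axis with tails inward; water and
#' counterions fill the remainder to the requested density.
#'
#' @param L box edge.
#' @param a,b transverse lattice vectors (length-2).
#' @param rod_axis 1, 2 or 3 (x, y, z).
#' @param n_ethoxy ethoxylation of the chains.
#' @param axial_spacing molecule stations along the rod axis.
#' @param mols_per_station molecules radiating per station.
#' @param thermal_sigma Gaussian spread applied to the chain beads (liquid-
#'   like rod interiors).
#' @param noise_sigma additional positional jitter on every bead.
#' @param seed RNG seed.
#' @param density reduced bead density for the water fill (0 = no fill).
#' @param allow_incommensurate skip the tiling check.
#' @param force_field force field.
#' @return a [dpd_system()] with `ground_truth` (a, b, r_s, centres, axis).
#' @export
make_hexagonal <- function(L, a = c(10, 0), b = c(4, 8), rod_axis = 1,
                           n_ethoxy = 0, axial_spacing = 0.5,
                           mols_per_station = 6, thermal_sigma = 0.2,
                           noise_sigma = 0, seed = 1L,
                           density = 3, allow_incommensurate = FALSE,
                           force_field = load_force_field()) {
  set.seed(seed)
  ff <- force_field
  M <- solve(cbind(a, b), diag(2) * L)
  if (!allow_incommensurate && max(abs(M - round(M))) > 1e-6) {
    stop("lattice vectors do not tile the periodic transverse cell; ",
         "set allow_incommensurate = TRUE to override", call. = FALSE)
  }
  lens <- three_lengths(a, b)
  mol_block <- ff_molecule(ff)
  chain <- c(mol_block$tail, rep(mol_block$ethoxy, n_ethoxy),
             mol_block$head)
  nb <- length(chain)
  l0 <- 0.35
  rod_reach <- nb * l0 + 0.3
  if (min(lens) < 2 * rod_reach) {
    stop(sprintf(
      "rod overlap: molecules reach %.2f but nearest rods are %.2f apart",
      rod_reach, min(lens)), call. = FALSE)
  }
  # lattice points in the primary transverse cell
  rng <- -24:24
  pts <- as.matrix(expand.grid(i = rng, j = rng))
  cen <- pts[, 1] %o% a + pts[, 2] %o% b
  cen <- cen %% L
  cen <- unique(round(cen, 6))
  tr <- setdiff(1:3, rod_axis)
  stations <- seq(0, L - axial_spacing / 2, by = axial_spacing)
  pos <- list(); specs <- character(0); mols <- integer(0)
  mol_id <- 0L
  for (r in seq_len(nrow(cen))) {
    for (s in stations) {
      angs <- 2 * pi * (seq_len(mols_per_station) - 1) / mols_per_station +
        stats::runif(1, 0, 2 * pi)
      for (ang in angs) {
        mol_id <- mol_id + 1L
        u2 <- c(cos(ang), sin(ang))
        radii <- (seq_len(nb) - 0.5) * l0
        p <- matrix(0, nb, 3)
        p[, tr[1]] <- cen[r, 1] + radii * u2[1]
        p[, tr[2]] <- cen[r, 2] + radii * u2[2]
        p[, rod_axis] <- s + stats::runif(1, -0.1, 0.1)
        pos[[length(pos) + 1L]] <- p
        specs <- c(specs, chain)
        mols <- c(mols, rep(mol_id, nb))
      }
    }
  }
  positions <- do.call(rbind, pos)
  if (thermal_sigma > 0) {
    positions <- positions + matrix(stats::rnorm(length(positions),
                                                 sd = thermal_sigma),
                                    ncol = 3)
  }
  n_mol <- mol_id
  if (density > 0) {
    ntot <- round(density * L^3)
    n_na <- n_mol
    n_wat <- ntot - n_mol * nb - n_na
    if (n_wat < 0) stop("rod packing exceeds the bead budget at this density",
                        call. = FALSE)
    fill <- matrix(NA_real_, 0, 3)
    while (nrow(fill) < n_wat + n_na) {
      cand <- matrix(stats::runif(3 * (n_wat + n_na), 0, L), ncol = 3)
      d2 <- rep(Inf, nrow(cand))
      for (r in seq_len(nrow(cen))) {
        dd <- min_image_disp(cbind(cand[, tr[1]] - cen[r, 1],
                                   cand[, tr[2]] - cen[r, 2]), L)
        d2 <- pmin(d2, rowSums(dd^2))
      }
      fill <- rbind(fill, cand[d2 > (rod_reach + 0.2)^2, , drop = FALSE])
    }
    fill <- fill[seq_len(n_wat + n_na), , drop = FALSE]
    positions <- rbind(positions, fill)
    specs <- c(specs, rep(mol_block$counterion, n_na), rep("W", n_wat))
    mols <- c(mols, rep(NA_integer_, n_na + n_wat))
  }
  if (noise_sigma > 0) {
    positions <- positions + matrix(stats::rnorm(length(positions),
                                                 sd = noise_sigma),
                                    ncol = 3)
  }
  sys <- dpd_system(positions = positions, species = specs, molecule = mols,
                    charge = unname(ff$charges[specs]), box_edge = L)
  attr(sys, "ground_truth") <- list(kind = "hexagonal", a = a, b = b,
                                    lengths = lens, r_s = mean(lens),
                                    centers = cen, axis = rod_axis)
  sys
}
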