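# Lamellar and hexagonal periodicity analysis, PBC-allowed spacing
# catalogs, phase classification and the concentration-spacing model.

# ------------------------------------------------------------- lamellar ----

#' Nematic director of the surfactant molecules
#'
#' Principal eigenvector of the second-moment (nematic) tensor
#' \eqn{Q = \langle 3 u u^T - I \rangle / 2} of the head-to-tail end-to-end
#' unit vectors; robust to the +-u sign ambiguity. Sign-canonicalized so
#' the largest component is positive.
#'
#' @param system a [dpd_system()] with molecule ids.
#' @param head_species,tail_end_species species of the two chain ends used
#'   for the end-to-end vector.
#' @param degeneracy_tol absolute gap between the two leading eigenvalues
#'   of the nematic tensor below which the orientation is considered
#'   degenerate (no director); isotropic and planar-isotropic orientation
#'   sets both fall below it.
#' @return unit vector (length 3), or `NULL` with a message when the
#'   orientation tensor is degenerate.
#' @export
lamellar_director <- function(system, head_species = "ES",
                              tail_end_species = "CT",
                              degeneracy_tol = 0.05) {
  mol <- system$molecule
  heads <- which(system$species %in% head_species & !is.na(mol))
  tails <- which(system$species %in% tail_end_species & !is.na(mol))
  hm <- mol[heads]; tm <- mol[tails]
  common <- intersect(hm, tm)
  if (length(common) < 10) stop("need at least 10 molecules", call. = FALSE)
  hp <- system$positions[heads[match(common, hm)], , drop = FALSE]
  tp <- system$positions[tails[match(common, tm)], , drop = FALSE]
  u <- min_image_disp(hp - tp, system$box_edge)
  len <- sqrt(rowSums(u^2))
  u <- u[len > 1e-9, , drop = FALSE] / len[len > 1e-9]
  Q <- (3 * crossprod(u) / nrow(u) - diag(3)) / 2
  eig <- eigen(Q, symmetric = TRUE)
  if ((eig$values[1] - eig$values[2]) < degeneracy_tol) {
    return(NULL)
  }
  v <- eig$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Count lamellar layers along the director
#'
#' Identifies the dominant density wave of the surfactant beads among the
#' PBC-commensurate wave vectors \eqn{k = 2\pi \kappa / L} (integer
#' \eqn{\kappa}), restricted to vectors aligned with the director. The
#' layer count is the largest integer component of the winning wave
#' vector — the number of bilayers crossed along the director-matched box
#' axis.
#'
#' @param system a [dpd_system()].
#' @param director unit vector from [lamellar_director()].
#' @param surf_species bead species forming the layers.
#' @param kmax integer search bound per component.
#' @param align_deg angular window (degrees) around the director.
#' @param peak_factor required ratio of peak power to background power.
#' @return list with `kappa` (layer count), `kappa_vec`, `power_ratio`.
#' @export
layer_count <- function(system, director, surf_species = c("CT", "CM", "EO",
                                                           "ES"),
                        kmax = 12, align_deg = 30, peak_factor = 2) {
  if (is.null(director)) stop("no director supplied", call. = FALSE)
  idx <- which(system$species %in% surf_species)
  if (!length(idx)) stop("no surfactant beads", call. = FALSE)
  x <- system$positions[idx, , drop = FALSE]
  # large configurations: a deterministic bead subsample is ample for the
  # dominant density wave
  if (nrow(x) > 8000) {
    x <- x[round(seq(1, nrow(x), length.out = 8000)), , drop = FALSE]
  }
  L <- system$box_edge
  kv <- as.matrix(expand.grid(kx = 0:kmax, ky = -kmax:kmax, kz = -kmax:kmax))
  kv <- kv[rowSums(kv^2) > 0, , drop = FALSE]
  # half-space (k and -k give the same power)
  kv <- kv[kv[, 1] > 0 | (kv[, 1] == 0 & (kv[, 2] > 0 |
             (kv[, 2] == 0 & kv[, 3] > 0))), , drop = FALSE]
  kn <- sqrt(rowSums(kv^2))
  cosang <- abs(as.vector(kv %*% director)) / kn
  aligned <- cosang >= cos(align_deg * pi / 180)
  if (!any(aligned)) stop("no commensurate wave vector near the director",
                          call. = FALSE)
  # evaluate the aligned candidates plus a background sample
  bg_idx <- which(!aligned)
  if (length(bg_idx) > 300) {
    bg_idx <- bg_idx[round(seq(1, length(bg_idx), length.out = 300))]
  }
  p_al <- structure_factor_power(x, kv[aligned, , drop = FALSE], L)
  p_bg <- structure_factor_power(x, kv[bg_idx, , drop = FALSE], L)
  # background = strongest off-director power, so that structureless
  # (Poisson) configurations, whose aligned and off-director extremes are
  # statistically identical, fail the dominance criterion
  bg <- max(p_bg)
  if (!is.finite(bg) || bg <= 0) bg <- stats::median(c(p_al, p_bg))
  best <- which(aligned)[which.max(p_al)]
  ratio <- max(p_al) / bg
  if (ratio < peak_factor) {
    stop("no dominant layer peak: configuration is not lamellar ",
         sprintf("(power ratio %.2f < %g)", ratio, peak_factor),
         call. = FALSE)
  }
  kvec <- kv[best, ]
  list(kappa = max(abs(kvec)), kappa_vec = unname(kvec),
       power_ratio = ratio)
}

structure_factor_power <- function(x, kv, L) {
  kv <- matrix(kv, ncol = 3)
  out <- numeric(nrow(kv))
  # chunked to bound the phase-matrix memory
  chunk <- max(1L, floor(2e6 / nrow(x)))
  for (s in seq(1, nrow(kv), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(kv))
    ph <- x %*% t(kv[s:e, , drop = FALSE]) * (2 * pi / L)
    out[s:e] <- (colSums(cos(ph))^2 + colSums(sin(ph))^2) / nrow(x)
  }
  out
}

#' Lamellar d-spacing from box edge, tilt and layer count
#'
#' The periodic box constrains bilayers to satisfy
#' \eqn{L \cos\theta = \kappa d}, so \eqn{d = L \cos\theta / \kappa}.
#'
#' @param L box edge.
#' @param theta polar angle (degrees) of the director to its matched box
#'   axis, in `[0, 90)`.
#' @param kappa number of bilayers (positive integer).
#' @export
d_spacing <- function(L, theta, kappa) {
  stopifnot(kappa >= 1, kappa == round(kappa), theta >= 0, theta < 90)
  L * cos(theta * pi / 180) / kappa
}

#' Measure the lamellar d-spacing of a configuration
#'
#' Full pipeline: director, commensurate layer count, tilt angle to the
#' director-matched box axis, then \eqn{d = L\cos\theta/\kappa}.
#'
#' @param system a [dpd_system()].
#' @param ... passed to [layer_count()].
#' @return list with `d`, `theta` (degrees), `kappa`, `director`.
#' @export
measure_lamellar <- function(system, ...) {
  dir <- lamellar_director(system)
  if (is.null(dir)) stop("no director: ", attr(dir, "reason"),
                         call. = FALSE)
  lc <- layer_count(system, dir, ...)
  axis <- which.max(abs(lc$kappa_vec))
  # use the wave vector itself for the tilt: it is the PBC-commensurate
  # realization of the director
  kv <- lc$kappa_vec
  ct <- abs(kv[axis]) / sqrt(sum(kv^2))
  theta <- acos(pmin(ct, 1)) * 180 / pi
  list(d = d_spacing(system$box_edge, theta, lc$kappa), theta = theta,
       kappa = lc$kappa, kappa_vec = lc$kappa_vec, director = dir,
       power_ratio = lc$power_ratio)
}

#' Catalog of PBC-allowed lamellar d-spacings
#'
#' Periodic boundaries restrict the layer normal to integer wave vectors,
#' so the allowed spacings in a cubic box of edge L are
#' \eqn{d = L / \sqrt{\kappa_x^2 + \kappa_y^2 + \kappa_z^2}} over
#' non-negative integers not all zero. Values are deduplicated at 3
#' significant figures (the resolution at which they are reported).
#'
#' @param L box edge.
#' @param d_min,d_max open interval of spacings to keep.
#' @param kmax integer search bound.
#' @return a `spacing_catalog` data frame with `d` and the generating
#'   integer triple, sorted by decreasing d.
#' @export
allowed_d_spacings <- function(L, d_min, d_max, kmax = 12) {
  stopifnot(d_min > 0, d_max > d_min)
  kv <- as.matrix(expand.grid(kx = 0:kmax, ky = 0:kmax, kz = 0:kmax))
  kv <- kv[rowSums(kv) > 0, , drop = FALSE]
  k2 <- rowSums(kv^2)
  d <- L / sqrt(k2)
  keep <- d > d_min & d < d_max
  kv <- kv[keep, , drop = FALSE]; d <- d[keep]
  ord <- order(-d, rowSums(kv^2))
  kv <- kv[ord, , drop = FALSE]; d <- d[ord]
  dup <- duplicated(signif(d, 3))
  out <- data.frame(d = d[!dup], kx = kv[!dup, 1], ky = kv[!dup, 2],
                    kz = kv[!dup, 3])
  class(out) <- c("spacing_catalog", class(out))
  attr(out, "mode") <- "lamellar"
  attr(out, "box_edge") <- L
  out
}

# ------------------------------------------------------------ hexagonal ----

#' Detect rods and their axis in a hexagonal configuration
#'
#' The rod axis is the box axis along which the tail-bead density is
#' translationally invariant (lowest low-order structure-factor power).
#' Tail beads are projected onto the transverse plane and clustered by
#' periodic density peaks; cluster centroids (periodic means) are the rod
#' centres.
#'
#' @param system a [dpd_system()].
#' @param tail_species rod-forming bead species.
#' @param grid_n transverse histogram resolution per box edge.
#' @param min_rods minimum rod count for a lattice fit.
#' @return list with `axis` (1 = x, 2 = y, 3 = z), `centers` (n x 2 matrix
#'   in the transverse plane, wrapped into the primary cell).
#' @export
detect_rods <- function(system, tail_species = c("CT", "CM"), grid_n = 64,
                        min_rods = 3) {
  idx <- which(system$species %in% tail_species)
  if (!length(idx)) stop("no tail beads", call. = FALSE)
  x <- system$positions[idx, , drop = FALSE]
  L <- system$box_edge
  xs <- x
  if (nrow(xs) > 8000) {
    xs <- xs[round(seq(1, nrow(xs), length.out = 8000)), , drop = FALSE]
  }
  # the rod axis is the one whose transverse plane shows the strongest
  # Bragg peak (rods are translationally invariant along themselves, so
  # all their density structure lives in the transverse wave vectors)
  grid2 <- as.matrix(expand.grid(-6:6, -6:6))
  grid2 <- grid2[rowSums(grid2^2) > 0, , drop = FALSE]
  peak <- vapply(1:3, function(ax) {
    trx <- setdiff(1:3, ax)
    kv <- matrix(0, nrow(grid2), 3)
    kv[, trx] <- grid2
    max(structure_factor_power(xs, kv, L))
  }, numeric(1))
  axis <- which.max(peak)
  tr <- setdiff(1:3, axis)
  xy <- x[, tr, drop = FALSE]
  h <- L / grid_n
  gi <- floor(xy / h) %% grid_n + 1
  dens <- matrix(0, grid_n, grid_n)
  for (k in seq_len(nrow(gi))) {
    dens[gi[k, 1], gi[k, 2]] <- dens[gi[k, 1], gi[k, 2]] + 1
  }
  thr <- max(mean(dens), 0.5)
  occ <- dens > thr
  if (!any(occ)) stop("no transverse density peaks", call. = FALSE)
  # periodic connected components on the occupancy grid (4-neighbour)
  lab <- matrix(0L, grid_n, grid_n)
  cur <- 0L
  for (i0 in seq_len(grid_n)) for (j0 in seq_len(grid_n)) {
    if (!occ[i0, j0] || lab[i0, j0]) next
    cur <- cur + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- cur
    while (length(stack)) {
      ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- (ij[1] + dd[1] - 1) %% grid_n + 1
        jj <- (ij[2] + dd[2] - 1) %% grid_n + 1
        if (occ[ii, jj] && !lab[ii, jj]) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  # a rod is localized in BOTH transverse directions; a component spanning
  # the cell in one direction is a layer stripe, not a rod
  for (cl in seq_len(cur)) {
    cells <- which(lab == cl, arr.ind = TRUE)
    if (length(unique(cells[, 1])) > 0.6 * grid_n ||
        length(unique(cells[, 2])) > 0.6 * grid_n) {
      stop("striped transverse density (layer-like): not hexagonal",
           call. = FALSE)
    }
  }
  centers <- t(vapply(seq_len(cur), function(cl) {
    cells <- which(lab == cl, arr.ind = TRUE)
    w <- dens[lab == cl]
    vapply(1:2, function(c2) {
      ang <- (cells[, c2] - 0.5) * 2 * pi / grid_n
      m <- atan2(sum(w * sin(ang)), sum(w * cos(ang)))
      (m %% (2 * pi)) * L / (2 * pi)
    }, numeric(1))
  }, numeric(2)))
  if (nrow(centers) < min_rods) {
    stop(sprintf("only %d rod(s) found (< %d): not hexagonal",
                 nrow(centers), min_rods), call. = FALSE)
  }
  list(axis = axis, centers = centers)
}

#' Fit the transverse rod lattice and inter-rod spacing
#'
#' Chooses the two shortest independent minimum-image difference vectors
#' among the rod centres (each averaged over all matching rod pairs),
#' Lagrange-reduces the basis, verifies that integer combinations tile the
#' periodic transverse cell, and reports the three nearest-neighbour
#' distances \eqn{|a|, |b|, |a-b|} and their mean, the average inter-rod
#' spacing \eqn{r_S}.
#'
#' @param rod_centers n x 2 matrix of transverse rod centres.
#' @param L transverse box edge.
#' @param d_co near-hexagonality cutoff: the three lengths may pairwise
#'   differ by at most this.
#' @param tol_match clustering tolerance for grouping difference vectors.
#' @param tiling_tol integer-tiling tolerance.
#' @return a `hexagonal_metrics` list: `a`, `b`, `lengths`, `r_s`,
#'   `commensurate`, `hexagonal` (within `d_co`), `orientation`
#'   (`"parallel"`, `"perpendicular"` or `"other"`), `residual`.
#' @export
fit_hexagonal_lattice <- function(rod_centers, L, d_co = 1.5,
                                  tol_match = 0.75, tiling_tol = 0.05) {
  ctr <- as.matrix(rod_centers)
  if (nrow(ctr) < 3) stop("need at least 3 rod centres", call. = FALSE)
  n <- nrow(ctr)
  diffs <- NULL
  for (i in seq_len(n - 1)) {
    d <- min_image_disp(ctr[(i + 1):n, , drop = FALSE][, 1:2, drop = FALSE] -
                          matrix(ctr[i, ], n - i, 2, byrow = TRUE), L)
    diffs <- rbind(diffs, d)
  }
  # canonical sign: first nonzero coordinate positive
  flip <- diffs[, 1] < 0 | (abs(diffs[, 1]) < 1e-9 & diffs[, 2] < 0)
  diffs[flip, ] <- -diffs[flip, ]
  len <- sqrt(rowSums(diffs^2))
  ord <- order(len)
  diffs <- diffs[ord, , drop = FALSE]; len <- len[ord]
  group_mean <- function(v) {
    sel <- sqrt(rowSums((diffs - matrix(v, nrow(diffs), 2,
                                        byrow = TRUE))^2)) < tol_match
    colMeans(diffs[sel, , drop = FALSE])
  }
  a <- group_mean(diffs[1, ])
  indep <- abs(diffs[, 1] * a[2] - diffs[, 2] * a[1]) / (len * sqrt(sum(a^2)))
  cand <- which(indep > 0.3)
  if (!length(cand)) stop("rod centres are collinear", call. = FALSE)
  b <- group_mean(diffs[cand[1], ])
  red <- lagrange_reduce(a, b)
  a <- red$a; b <- red$b
  lens <- three_lengths(a, b)
  # integer tiling: (L,0) and (0,L) must be integer combos of (a, b)
  M <- solve(cbind(a, b), diag(2) * L)
  residual <- max(abs(M - round(M)))
  commensurate <- residual < tiling_tol * max(abs(round(M)), 1)
  hexagonal <- (max(lens) - min(lens)) <= d_co
  # orientation: judged on all three nearest-neighbour vectors, since the
  # reduced basis is only defined up to unimodular transforms
  nn <- list(a, b, if (sum((a - b)^2) <= sum((a + b)^2)) a - b else a + b)
  align <- vapply(nn, function(v) max(abs(v)) / sqrt(sum(v^2)), numeric(1))
  best_nn <- nn[[which.max(align)]]
  orientation <- if (max(align) > cos(5 * pi / 180)) {
    if (abs(best_nn[1]) >= abs(best_nn[2])) "parallel" else "perpendicular"
  } else "other"
  structure(
    list(a = a, b = b, lengths = lens, r_s = mean(lens),
         commensurate = commensurate, residual = residual,
         hexagonal = hexagonal, d_co = d_co, orientation = orientation),
    class = "hexagonal_metrics"
  )
}

#' @export
print.hexagonal_metrics <- function(x, ...) {
  cat(sprintf(
    "hexagonal_metrics: r_S = %.3f (|a| = %.3f, |b| = %.3f, |a-b| = %.3f)\n",
    x$r_s, x$lengths[1], x$lengths[2], x$lengths[3]))
  cat(sprintf("  commensurate: %s (residual %.2g); orientation: %s\n",
              x$commensurate, x$residual, x$orientation))
  invisible(x)
}

lagrange_reduce <- function(a, b) {
  repeat {
    if (sum(a^2) > sum(b^2)) { tmp <- a; a <- b; b <- tmp }
    mu <- round(sum(a * b) / sum(a * a))
    b2 <- b - mu * a
    if (sum(b2^2) >= sum(b^2)) break
    b <- b2
  }
  list(a = a, b = b)
}

three_lengths <- function(a, b) {
  c(sqrt(sum(a^2)), sqrt(sum(b^2)),
    min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2))))
}

#' Measure the hexagonal inter-rod spacing of a configuration
#'
#' @param system a [dpd_system()].
#' @param d_co near-hexagonality cutoff for the lattice fit.
#' @param ... passed to [detect_rods()].
#' @export
measure_hexagonal <- function(system, d_co = 1.5, ...) {
  rods <- detect_rods(system, ...)
  fit <- fit_hexagonal_lattice(rods$centers, system$box_edge, d_co = d_co)
  fit$axis <- rods$axis
  fit$n_rods <- nrow(rods$centers)
  fit
}

#' Catalog of PBC-allowed hexagonal inter-rod spacings
#'
#' Enumerates every two-dimensional lattice whose points contain the
#' periodic images (L, 0) and (0, L) — the transverse-cell tiling
#' constraint — via the Hermite-normal-form parametrization of the
#' superlattices of \eqn{L\,Z^2}. Each lattice is reduced to its shortest
#' basis; the three nearest-neighbour lengths \eqn{|a|, |b|, |a-b|} must
#' pairwise differ by no more than `d_co` (rods deform only so far from the
#' perfect hexagonal arrangement), and the average \eqn{r_S} of the three
#' is recorded, deduplicated at 3 significant figures.
#'
#' @param L transverse box edge.
#' @param d_co near-hexagonality cutoff (1.5 by default).
#' @param r_min,r_max open interval of average spacings to keep.
#' @param max_index Hermite-form index bound (rods per cell); the default
#'   covers all spacings above ~2 reduced units for L <= 50.
#' @return a `spacing_catalog` data frame with `r_s`, the three lengths and
#'   the generating reduced basis, sorted by increasing r_s.
#' @export
allowed_r_s <- function(L, d_co = 1.5, r_min, r_max, max_index = 700) {
  stopifnot(d_co > 0, r_min < r_max)
  rows <- list()
  for (p in seq_len(max_index)) {
    rmaxq <- max_index %/% p
    if (rmaxq < 1) break
    for (r in seq_len(rmaxq)) {
      for (q in 0:(r - 1)) {
        a <- c(L / p, 0)
        b <- c(-q * L / (p * r), L / r)
        red <- lagrange_reduce(a, b)
        lens <- three_lengths(red$a, red$b)
        if (max(lens) - min(lens) > d_co) next
        rs <- mean(lens)
        if (rs <= r_min || rs >= r_max) next
        rows[[length(rows) + 1L]] <- c(rs, sort(lens), red$a, red$b)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(r_s = numeric(), l1 = numeric(), l2 = numeric(),
                      l3 = numeric(), ax = numeric(), ay = numeric(),
                      bx = numeric(), by = numeric())
  } else {
    m <- do.call(rbind, rows)
    m <- m[order(m[, 1]), , drop = FALSE]
    dup <- duplicated(signif(m[, 1], 3))
    m <- m[!dup, , drop = FALSE]
    out <- data.frame(r_s = m[, 1], l1 = m[, 2], l2 = m[, 3], l3 = m[, 4],
                      ax = m[, 5], ay = m[, 6], bx = m[, 7], by = m[, 8])
  }
  class(out) <- c("spacing_catalog", class(out))
  attr(out, "mode") <- "hexagonal"
  attr(out, "box_edge") <- L
  attr(out, "d_co") <- d_co
  out
}

#' Brute-force oracle for the hexagonal spacing catalog
#'
#' Scans all integer index matrices with entries bounded by `bound`
#' (lattice basis = L x inverse of the index matrix) instead of the
#' Hermite-form parametrization. Slow; used to cross-validate
#' [allowed_r_s()].
#'
#' @inheritParams allowed_r_s
#' @param bound integer entry bound.
#' @return sorted vector of distinct r_s values (3 significant figures).
#' @export
allowed_r_s_bruteforce <- function(L, d_co = 1.5, r_min, r_max, bound = 8) {
  vals <- numeric(0)
  rng <- -bound:bound
  for (n1 in rng) for (n2 in rng) for (n3 in rng) for (n4 in rng) {
    dt <- n1 * n4 - n2 * n3
    if (dt == 0) next
    a <- L / dt * c(n4, -n3)
    b <- L / dt * c(-n2, n1)
    red <- lagrange_reduce(a, b)
    lens <- three_lengths(red$a, red$b)
    if (max(lens) - min(lens) > d_co) next
    rs <- mean(lens)
    if (rs > r_min && rs < r_max) vals <- c(vals, rs)
  }
  sort(unique(signif(vals, 3)))
}

# -------------------------------------------------------- classification ---

#' Classify the phase of a configuration
#'
#' Rule-based classification from the percolation dimensionality of the
#' tail-bead clusters: finite clusters give a micellar phase (worm-like
#' when large clusters are strongly elongated), clusters percolating one
#' axis give hexagonal (successful rod-lattice fit) or worm-like micellar
#' (failed fit), two-or-three-axis percolation gives lamellar, split into
#' perfect/imperfect by water-slab bridging. When both a rod lattice and a
#' layer stack fit, the hybrid label is returned.
#'
#' @param systems a `dpd_system`, list of frames, or `dpd_trajectory`
#'   (multiple frames sharpen the bridge-rate estimate).
#' @param cutoff contact cutoff for clustering.
#' @param tail_species hydrophobic core species.
#' @param bridge_threshold fraction of bridged frames above which a
#'   lamellar phase is called imperfect.
#' @return a `phase_classification`: `label`, `evidence` list.
#' @export
classify_phase <- function(systems, cutoff = 1.0,
                           tail_species = c("CT", "CM"),
                           bridge_threshold = 0.05) {
  systems <- as_system_list(systems)
  sys1 <- systems[[1]]
  L <- sys1$box_edge
  tail_idx <- which(sys1$species %in% tail_species)
  if (!length(tail_idx)) stop("no tail beads", call. = FALSE)
  # bead-level percolation of tail clusters on the first frame
  pairs <- cpp_contact_pairs(sys1$positions, L, cutoff,
                             as.integer(tail_idx))
  gm <- igraph::make_empty_graph(n = length(tail_idx), directed = FALSE)
  if (nrow(pairs)) {
    e <- cbind(match(pairs[, 1], tail_idx), match(pairs[, 2], tail_idx))
    gm <- igraph::add_edges(gm, t(e))
  }
  memb <- igraph::components(gm)$membership
  big <- as.integer(names(which.max(table(memb))))
  beads <- tail_idx[memb == big]
  uw <- unwrap_cluster(sys1$positions[beads, , drop = FALSE], L, cutoff)
  ext <- apply(uw$positions, 2, function(u) diff(range(u)))
  n_perc <- sum(ext > L - 2 * cutoff)
  lam <- try(measure_lamellar(sys1), silent = TRUE)
  hex <- try(measure_hexagonal(sys1), silent = TRUE)
  lam_ok <- !inherits(lam, "try-error")
  hex_ok <- !inherits(hex, "try-error") && isTRUE(hex$hexagonal)
  label <- NULL
  evidence <- list(percolation_axes = n_perc,
                   largest_cluster = length(beads),
                   n_clusters = max(memb))
  if (n_perc == 0) {
    # finite aggregates: micellar, worm-like if strongly elongated
    elong <- max(ext) / max(min(ext), 1e-9)
    label <- if (length(beads) > 10 && elong > 4) "worm-like micellar" else
      "micellar"
    evidence$elongation <- elong
  } else if (n_perc == 1) {
    label <- if (hex_ok) "hexagonal" else "worm-like micellar"
    if (hex_ok) evidence$r_s <- hex$r_s
  } else {
    if (lam_ok && hex_ok) {
      label <- "hexagonal/lamellar"
    } else if (lam_ok) {
      br <- vapply(systems, lamellar_bridged, logical(1),
                   cutoff = cutoff, kappa = lam$kappa)
      rate <- mean(br)
      evidence$bridge_rate <- rate
      evidence$d <- lam$d
      label <- if (rate > bridge_threshold) "lamellar-imperfect" else
        "lamellar-perfect"
    } else {
      label <- "indeterminate"
    }
  }
  structure(list(label = label, evidence = evidence,
                 lamellar = if (lam_ok) lam else NULL,
                 hexagonal = if (hex_ok) hex else NULL),
            class = "phase_classification")
}

#' @export
print.phase_classification <- function(x, ...) {
  cat("phase:", x$label, "\n")
  invisible(x)
}

# a lamellar frame is "bridged" when the water beads form fewer distinct
# slabs than there are bilayers (a channel connects adjacent water layers)
lamellar_bridged <- function(system, cutoff = 1.0, kappa) {
  w_idx <- which(system$species == "W")
  if (!length(w_idx)) return(FALSE)
  pairs <- cpp_contact_pairs(system$positions, system$box_edge, cutoff,
                             as.integer(w_idx))
  g <- igraph::make_empty_graph(n = length(w_idx), directed = FALSE)
  if (nrow(pairs)) {
    e <- cbind(match(pairs[, 1], w_idx), match(pairs[, 2], w_idx))
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)
  n_slabs <- sum(comp$csize > 0.2 * length(w_idx) / max(kappa, 1))
  n_slabs < kappa
}

# ------------------------------------------------- concentration model -----

#' Fit the surfactant-layer thickness of the d-spacing volume model
#'
#' The d-spacing of a lamellar stack is the combined thickness of one
#' surfactant layer and its adjacent water layer. If the surfactant-layer
#' thickness d_s is concentration independent, volume balance gives
#' \deqn{d = d_s \frac{N_s V_s + N_I V_I + N_w V_w}{N_s V_s}}
#' with bead volumes from the species self-cutoffs. This fits the lone
#' parameter d_s by least squares through the origin.
#'
#' @param d_obs observed d-spacings (one per concentration).
#' @param volume_ratio the ratio \eqn{(N_s V_s + N_I V_I + N_w V_w)/(N_s
#'   V_s)} per observation (compute with [composition_volume_ratio()]).
#' @return list with `d_s`, `fitted`, `residuals`.
#' @export
fit_d_model <- function(d_obs, volume_ratio) {
  stopifnot(length(d_obs) == length(volume_ratio))
  if (length(d_obs) < 3) stop("need at least 3 concentrations",
                              call. = FALSE)
  ds <- sum(volume_ratio * d_obs) / sum(volume_ratio^2)
  fitted <- ds * volume_ratio
  list(d_s = ds, fitted = fitted, residuals = d_obs - fitted)
}

#' Volume ratio of a box composition for the d-spacing model
#'
#' @param composition a [composition_from_weight_percent()] result.
#' @param force_field force field supplying self-cutoffs.
#' @param radius_convention passed to [bead_volume()].
#' @export
composition_volume_ratio <- function(composition,
                                     force_field = load_force_field(),
                                     radius_convention = "half_cutoff") {
  ff <- force_field
  vol <- bead_volume(diag(ff$cutoff), radius_convention)
  names(vol) <- ff$species
  v_chain <- sum(vapply(seq_along(composition$topologies), function(t) {
    composition$molecule_counts[t] *
      sum(vol[composition$topologies[[t]]$bead_sequence])
  }, numeric(1)))
  v_ion <- composition$sodium_count * vol[["Na"]]
  v_wat <- composition$water_count * vol[["W"]]
  (v_chain + v_ion + v_wat) / v_chain
}

#' Interpolation coordinate of a polydisperse spacing
#'
#' Places the spacing of a polydisperse system on the line between the two
#' monodisperse references: \eqn{n_{Int} = (d_{poly} - d_0)/(d_1 - d_0)}.
#' When the polydisperse mixture behaves like its mean ethoxylation, this
#' equals that mean.
#'
#' @param d_0,d_1 monodisperse spacings at n = 0 and n = 1.
#' @param d_poly polydisperse spacing.
#' @export
interpolate_ethoxylation <- function(d_0, d_1, d_poly) {
  if (abs(d_1 - d_0) < 1e-12) {
    stop("d_0 and d_1 coincide: interpolation undefined", call. = FALSE)
  }
  (d_poly - d_0) / (d_1 - d_0)
}
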