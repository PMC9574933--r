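# Micelle identification, aggregation statistics and shape analysis.

#' Identify micelles by tail-bead contact clustering
#'
#' Two surfactant molecules belong to the same micelle when any pair of
#' their hydrophobic tail beads lies within the contact cutoff (minimum
#' image). Whole molecules follow their tail assignment. Per-micelle radii
#' of gyration are computed over the tail (core) beads after unwrapping the
#' cluster across periodic images.
#'
#' @param system a [dpd_system()] with molecule ids.
#' @param cutoff contact distance (1 reduced unit by default).
#' @param tail_species character vector of tail bead species.
#' @param ethoxy_species species counted for per-molecule ethoxylation.
#' @return A `micelle_set`: `assignment` (molecule id -> cluster),
#'   `sizes` (aggregation number N per cluster), `r_gyration` per cluster,
#'   and a per-cluster ethoxylation histogram.
#' @export
find_micelles <- function(system, cutoff = 1.0,
                          tail_species = c("CT", "CM"),
                          ethoxy_species = "EO") {
  stopifnot(cutoff > 0, length(tail_species) > 0)
  mol <- system$molecule
  # molecules = any bead with a molecule id
  surf_mols <- sort(unique(mol[!is.na(mol)]))
  if (!length(surf_mols)) {
    return(structure(list(assignment = integer(0), sizes = integer(0),
                          r_gyration = numeric(0),
                          composition = list(), percolating = logical(0)),
                     class = "micelle_set"))
  }
  tail_idx <- which(system$species %in% tail_species & !is.na(mol))
  pairs <- cpp_contact_pairs(system$positions, system$box_edge, cutoff,
                             as.integer(tail_idx))
  # molecule-level graph
  mol_f <- match(mol, surf_mols)
  g <- igraph::make_empty_graph(n = length(surf_mols), directed = FALSE)
  if (nrow(pairs)) {
    edges <- unique(cbind(mol_f[pairs[, 1]], mol_f[pairs[, 2]]))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  # relabel clusters by decreasing size, ties by smallest member
  sizes_raw <- table(memb)
  ord <- order(-as.integer(sizes_raw), as.integer(names(sizes_raw)))
  relab <- stats::setNames(seq_along(ord), names(sizes_raw)[ord])
  cluster <- unname(relab[as.character(memb)])
  assignment <- stats::setNames(cluster, surf_mols)
  ncl <- max(cluster)
  sizes <- tabulate(cluster, ncl)
  rg <- numeric(ncl)
  perc <- logical(ncl)
  n_per_mol <- tapply(system$species %in% ethoxy_species & !is.na(mol),
                      mol, sum)
  composition <- vector("list", ncl)
  for (cl in seq_len(ncl)) {
    mols_cl <- surf_mols[cluster == cl]
    beads <- which(mol %in% mols_cl & system$species %in% tail_species)
    res <- unwrap_cluster(system$positions[beads, , drop = FALSE],
                          system$box_edge, cutoff)
    rg[cl] <- rg_of(res$positions)
    perc[cl] <- res$percolating
    composition[[cl]] <- table(n_per_mol[as.character(mols_cl)])
  }
  if (any(perc)) {
    warning(sum(perc), " cluster(s) span more than half the box; ",
            "their R_G is reported but unreliable (percolation)",
            call. = FALSE)
  }
  structure(list(assignment = assignment, sizes = sizes, r_gyration = rg,
                 composition = composition, percolating = perc),
            class = "micelle_set")
}

#' @export
print.micelle_set <- function(x, ...) {
  cat(sprintf("micelle_set: %d clusters from %d molecules, N_agg = %.2f\n",
              length(x$sizes), sum(x$sizes), mean(x$sizes)))
  invisible(x)
}

# unwrap a compact cluster across periodic images by minimum-image chaining
# from an arbitrary root bead (BFS over the contact graph)
unwrap_cluster <- function(pos, L, cutoff) {
  n <- nrow(pos)
  if (n <= 1) return(list(positions = pos, percolating = FALSE))
  pairs <- cpp_contact_pairs(pos, L, max(cutoff, 1.0), seq_len(n))
  adj <- vector("list", n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- pos
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in adj[[i]]) {
      if (!seen[j]) {
        out[j, ] <- out[i, ] + min_image_disp(pos[j, ] - pos[i, ], L)
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  # disconnected stragglers (possible if cutoff < chaining distance): place
  # by minimum image relative to the cluster mean
  if (any(!seen)) {
    ctr <- colMeans(out[seen, , drop = FALSE])
    for (j in which(!seen)) {
      out[j, ] <- ctr + min_image_disp(pos[j, ] - ctr, L)
    }
  }
  ext <- apply(out, 2, function(u) diff(range(u)))
  list(positions = out, percolating = any(ext > L / 2))
}

rg_of <- function(pos) {
  if (nrow(pos) == 0) return(NA_real_)
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, ctr)^2)))
}

#' Radius of gyration of a bead set
#'
#' Root-mean-square distance to the centre of mass (equal bead masses),
#' with the member positions unwrapped across periodic images by
#' minimum-image chaining before the moment is taken. Clusters spanning
#' more than half the box in any direction are flagged as percolating.
#'
#' @param member_positions N x 3 matrix of member bead positions.
#' @param box_edge box edge L (`Inf` to skip unwrapping).
#' @param cutoff chaining distance used for the unwrap.
#' @return radius of gyration (attribute `percolating` carries the flag).
#' @export
radius_of_gyration <- function(member_positions, box_edge = Inf,
                               cutoff = 1.0) {
  member_positions <- as.matrix(member_positions)
  if (nrow(member_positions) < 1) stop("need at least one bead",
                                       call. = FALSE)
  if (is.finite(box_edge)) {
    res <- unwrap_cluster(wrap_positions(member_positions, box_edge),
                          box_edge, cutoff)
    if (res$percolating) {
      warning("cluster spans more than half the box: percolating, R_G unreliable",
              call. = FALSE)
    }
    structure(rg_of(res$positions), percolating = res$percolating)
  } else {
    structure(rg_of(member_positions), percolating = FALSE)
  }
}

#' Sphere radius from the radius of gyration
#'
#' For a uniform-density sphere \eqn{R_S = \sqrt{5/3}\, R_G}.
#' @param R_G radius of gyration (vectorised).
#' @export
sphere_radius <- function(R_G) {
  stopifnot(all(R_G >= 0))
  sqrt(5 / 3) * R_G
}

#' Mean aggregation number along a trajectory
#'
#' Computes the per-frame mean aggregation number. `weighting = "micelle"`
#' averages N over micelles (the default used throughout);
#' `"molecule"` weights each micelle by its own size (the mass-weighted
#' mean a scattering experiment is closer to).
#'
#' @param systems list of [dpd_system()] frames (or a `dpd_trajectory`).
#' @param cutoff contact cutoff.
#' @param weighting `"micelle"` or `"molecule"`.
#' @param include_monomers include size-1 clusters in the mean.
#' @param ... passed to [find_micelles()].
#' @return data frame with `frame`, `time`, `n_agg`, `n_micelles`.
#' @export
aggregation_series <- function(systems, cutoff = 1.0,
                               weighting = c("micelle", "molecule"),
                               include_monomers = TRUE, ...) {
  weighting <- match.arg(weighting)
  systems <- as_system_list(systems)
  if (!length(systems)) stop("need at least one frame", call. = FALSE)
  rows <- lapply(seq_along(systems), function(fi) {
    ms <- find_micelles(systems[[fi]], cutoff = cutoff, ...)
    sz <- ms$sizes
    if (!include_monomers) sz <- sz[sz > 1]
    nagg <- if (!length(sz)) NA_real_ else if (weighting == "micelle") {
      mean(sz)
    } else {
      sum(sz^2) / sum(sz)
    }
    data.frame(frame = fi, time = systems[[fi]]$time, n_agg = nagg,
               n_micelles = length(sz))
  })
  do.call(rbind, rows)
}

as_system_list <- function(x) {
  if (inherits(x, "dpd_trajectory")) {
    base <- x$system
    lapply(x$frames, function(fr) {
      s <- base
      s$positions <- fr$positions
      s$velocities <- fr$velocities
      s$time <- fr$time
      s$shear_offset <- fr$shear_offset
      s
    })
  } else if (inherits(x, "dpd_system")) {
    list(x)
  } else {
    x
  }
}

#' Detect the equilibration point of an aggregation series
#'
#' Splits the series into blocks of `block_span` time units and returns the
#' start frame of the earliest block from which every subsequent block mean
#' stays within one pooled (within-block) standard deviation of their joint
#' mean — the block-average plateau criterion.
#'
#' @param series data frame with `time` and `n_agg` (or a numeric vector
#'   with `times` supplied).
#' @param block_span block duration in reduced time units.
#' @param times frame times when `series` is a bare vector.
#' @return list with `frame` (index into the series) and `block`, or the
#'   string `"not equilibrated"` when no plateau exists.
#' @export
equilibration_point <- function(series, block_span = 5000, times = NULL) {
  if (is.data.frame(series)) {
    vals <- series$n_agg
    times <- series$time
  } else {
    vals <- as.numeric(series)
    if (is.null(times)) times <- seq_along(vals)
  }
  t0 <- min(times)
  blk <- floor((times - t0) / block_span) + 1L
  nb <- max(blk)
  if (nb < 3) stop("series must cover at least 3 blocks", call. = FALSE)
  bm <- tapply(vals, blk, mean)
  bv <- tapply(vals, blk, function(v) {
    if (length(v) > 1) stats::var(v) else 0
  })
  for (b in seq_len(nb - 1)) {
    sel <- b:nb
    mu <- mean(bm[sel])
    sp <- sqrt(mean(bv[sel]))
    if (sp == 0) sp <- stats::sd(bm[sel])
    if (is.na(sp) || sp == 0) {
      if (all(bm[sel] == mu)) return(list(frame = which(blk == b)[1],
                                          block = b))
      next
    }
    if (all(abs(bm[sel] - mu) <= sp)) {
      return(list(frame = which(blk == b)[1], block = b))
    }
  }
  "not equilibrated"
}

#' Sphericity profile of pooled micelles
#'
#' For spherical micelles with an N-independent core density,
#' \eqn{R_G^3 \propto N}, so \eqn{R_G^3/N} is flat in N; deviations flag
#' non-spherical shapes. Micelles are pooled across systems, binned in N
#' with width 5, and the minimum of the profile — the most spherical
#' aggregation number — is located by a quadratic fit through the three
#' lowest bins.
#'
#' @param micelle_sets a `micelle_set` or list of them (pooled).
#' @param bin_width aggregation-number bin width.
#' @param min_count drop bins with fewer micelles than this.
#' @return a `sphericity_profile`: per-bin centre, mean and SD of
#'   \eqn{R_G^3/N}, count; `N_star` and `R_G_star` at the fitted minimum
#'   (both `NA` with `minimum_defined = FALSE` when the profile is flat or
#'   too sparse).
#' @export
sphericity_profile <- function(micelle_sets, bin_width = 5, min_count = 1) {
  if (inherits(micelle_sets, "micelle_set")) {
    micelle_sets <- list(micelle_sets)
  }
  N <- unlist(lapply(micelle_sets, `[[`, "sizes"))
  rg <- unlist(lapply(micelle_sets, `[[`, "r_gyration"))
  keep <- N > 0 & !is.na(rg)
  N <- keep_vec(N, keep); rg <- keep_vec(rg, keep)
  if (!length(N)) stop("no micelles supplied", call. = FALSE)
  y <- rg^3 / N
  centre <- round(N / bin_width) * bin_width
  agg <- data.frame(
    bin = sort(unique(centre)),
    mean = as.numeric(tapply(y, centre, mean)),
    sd = as.numeric(tapply(y, centre, stats::sd)),
    n = as.integer(table(centre))
  )
  agg <- agg[agg$n >= min_count, , drop = FALSE]
  prof <- list(bins = agg, bin_width = bin_width)
  if (nrow(agg) < 3) {
    prof$minimum_defined <- FALSE
    prof$reason <- "fewer than 3 populated bins"
    prof$N_star <- NA_real_; prof$R_G_star <- NA_real_
    return(structure(prof, class = "sphericity_profile"))
  }
  # three bins with the lowest profile values, quadratic through them
  ord <- order(agg$mean)[1:3]
  xs <- agg$bin[ord]; ys <- agg$mean[ord]
  fit <- stats::lm(ys ~ xs + I(xs^2))
  cf <- stats::coef(fit)
  flat <- max(ys) - min(ys) < 1e-9 * max(abs(ys), 1)
  if (flat || is.na(cf[3]) || cf[3] <= 0) {
    prof$minimum_defined <- FALSE
    prof$reason <- if (flat) "profile is flat" else "no interior minimum"
    prof$N_star <- NA_real_; prof$R_G_star <- NA_real_
    return(structure(prof, class = "sphericity_profile"))
  }
  nstar <- -cf[2] / (2 * cf[3])
  ystar <- cf[1] + cf[2] * nstar + cf[3] * nstar^2
  prof$minimum_defined <- TRUE
  prof$N_star <- unname(nstar)
  prof$R_G_star <- unname((ystar * nstar)^(1 / 3))
  structure(prof, class = "sphericity_profile")
}

keep_vec <- function(v, keep) v[keep]

#' @export
print.sphericity_profile <- function(x, ...) {
  cat(sprintf("sphericity_profile: %d bins (width %g)\n", nrow(x$bins),
              x$bin_width))
  if (isTRUE(x$minimum_defined)) {
    cat(sprintf("  minimum at N* = %.1f, R_G* = %.3f\n", x$N_star,
                x$R_G_star))
  } else {
    cat("  minimum undefined:", x$reason, "\n")
  }
  invisible(x)
}

#' Ethoxylation mixing statistic per micelle
#'
#' Tests whether micelles recruit molecules of different ethoxylation in
#' the same ratios as present overall: for each micelle, the chi-squared
#' distance between its n-histogram and the global distribution, plus the
#' quantile of that distance under the multinomial null (micelle size as
#' the draw count), estimated by seeded simulation.
#'
#' @param micelle_set a [find_micelles()] result on a polydisperse system.
#' @param global_distribution list with `support` and `weights`; defaults
#'   to the pooled composition of the set itself.
#' @param n_null null-simulation draws per micelle size.
#' @param seed seed for the null simulation.
#' @return data frame with `micelle`, `size`, `chisq`, `null_quantile`.
#' @export
composition_mixing <- function(micelle_set, global_distribution = NULL,
                               n_null = 2000, seed = 1L) {
  comp <- micelle_set$composition
  if (!length(comp)) stop("empty micelle set", call. = FALSE)
  all_n <- sort(unique(unlist(lapply(comp, function(tb) {
    as.integer(names(tb))
  }))))
  if (length(all_n) < 2) {
    stop("monodisperse system: mixing statistic is meaningless",
         call. = FALSE)
  }
  counts <- t(vapply(comp, function(tb) {
    v <- stats::setNames(rep(0, length(all_n)), all_n)
    v[names(tb)] <- as.numeric(tb)
    v
  }, numeric(length(all_n))))
  if (is.null(global_distribution)) {
    tot <- colSums(counts)
    global_distribution <- list(support = all_n, weights = tot / sum(tot))
  }
  w <- global_distribution$weights[match(all_n,
                                         global_distribution$support)]
  w[is.na(w)] <- 0
  if (any(w == 0 & colSums(counts) > 0)) {
    w <- w + 1e-12
  }
  w <- w / sum(w)
  chisq_of <- function(obs) {
    n <- sum(obs)
    e <- n * w
    sum((obs - e)^2 / pmax(e, 1e-12))
  }
  chisq <- apply(counts, 1, chisq_of)
  sizes <- rowSums(counts)
  set.seed(seed)
  null_q <- vapply(seq_along(chisq), function(i) {
    draws <- stats::rmultinom(n_null, sizes[i], w)
    null_stats <- apply(draws, 2, chisq_of)
    mean(null_stats <= chisq[i])
  }, numeric(1))
  data.frame(micelle = seq_along(chisq), size = sizes, chisq = chisq,
             null_quantile = null_q)
}
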