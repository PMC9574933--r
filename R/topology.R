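# Surfactant molecule construction and box composition.

#' Build an SLEnS molecule topology
#'
#' Constructs the coarse-grained sodium lauryl ether sulfate chain with `n`
#' ethoxy beads inserted between the alkyl tail and the sulfate head. Bond
#' rest lengths come from the force field's heavy-atom rule; every
#' consecutive bead triple carries a harmonic angle at the configured
#' equilibrium (180 degrees by default). The chain's net charge is -1,
#' balanced by one free sodium counterion bead (not part of the chain).
#'
#' @param n number of ethoxy beads (>= 0).
#' @param force_field a [load_force_field()] object.
#' @return A `molecule_topology`: bead sequence, bonds (`from`, `to`, `l0`),
#'   angles, ethoxylation and net charge.
#' @export
build_slens <- function(n, force_field = load_force_field()) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  ff <- force_field
  mol <- ff_molecule(ff)
  beads <- c(mol$tail, rep(mol$ethoxy, n), mol$head)
  nb <- length(beads)
  heavy <- ff$heavy_atoms[beads]
  l0 <- bond_length(heavy[-nb], heavy[-1], ff$bond_rule)
  bonds <- data.frame(from = seq_len(nb - 1), to = 2:nb, l0 = l0,
                      C = ff$bond_C)
  angles <- if (nb >= 3) {
    data.frame(i = seq_len(nb - 2), j = 2:(nb - 1), k = 3:nb,
               theta0 = ff$angle_theta0, D = ff$angle_D)
  } else {
    data.frame(i = integer(), j = integer(), k = integer(),
               theta0 = numeric(), D = numeric())
  }
  structure(
    list(bead_sequence = beads, bonds = bonds, angles = angles,
         ethoxylation = as.integer(n),
         net_charge = sum(ff$charges[beads]),
         counterion = mol$counterion),
    class = "molecule_topology"
  )
}

ff_molecule <- function(ff) {
  # molecule block is parsed from the config but load_force_field keeps the
  # raw document out of its return; re-read lazily with a cached default
  if (!is.null(ff$molecule)) return(ff$molecule)
  cfg <- jsonlite::fromJSON(default_force_field_path())
  cfg$molecule
}

#' Molar mass of a surfactant molecule (chain + counterion)
#'
#' Weight percentages are defined on an as-is molecular basis: the
#' surfactant mass includes the bare sodium counterion, while the waters
#' hydrating the sodium bead are counted as water.
#' @param topology a [build_slens()] result.
#' @param force_field force field supplying per-bead molar masses.
#' @export
molecule_molar_mass <- function(topology, force_field = load_force_field()) {
  ff <- force_field
  sum(ff$molar_masses[topology$bead_sequence]) +
    ff$molar_masses[[topology$counterion]]
}

#' Sample a polydisperse ethoxylation composition
#'
#' Draws per-molecule ethoxylation numbers from a discrete distribution
#' (multinomial counts), as in a commercial AES product where `n` varies
#' between molecules.
#'
#' @param distribution list with `support` (integer n values) and `weights`
#'   (non-negative, summing to 1).
#' @param n_molecules number of molecules to assign.
#' @param seed integer seed; draws are deterministic given the seed.
#' @return named integer vector of counts per support value.
#' @export
sample_ethoxylation <- function(distribution, n_molecules, seed = 1L) {
  w <- distribution$weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("distribution weights must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (n_molecules <= 0) stop("`n_molecules` must be positive", call. = FALSE)
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n_molecules, w))
  names(counts) <- as.character(distribution$support)
  counts
}

#' Default AES ethoxylation distribution
#'
#' A distribution over n in 0..3 with mean 0.76, matching the simplified
#' commercial AES composition the simulations emulate. The exact weights of
#' the source product are not public; these are chosen to hit the mean with
#' a plausible monotone-decreasing profile and are config-replaceable for
#' quantitative work.
#' @export
aes_distribution <- function() {
  w <- c(0.52, 0.28, 0.12, 0.08)
  list(support = 0:3, weights = w, mean = sum(0:3 * w))
}

#' Solve a box composition for a target weight percentage
#'
#' Determines the molecule, counterion and water bead counts that realize a
#' requested surfactant weight percent in a cubic box of edge `L` at reduced
#' bead density 3. Each chain brings one sodium counterion; the hydrating
#' waters in the sodium bead count toward the water mass.
#'
#' @param L box edge (reduced units).
#' @param weight_percent target surfactant mass fraction x 100 (0 <= wt < 100).
#' @param topology_set list of `molecule_topology` objects.
#' @param topology_weights relative frequency of each topology (normalized).
#' @param force_field force field with molar masses.
#' @param reduced_density bead number density (3 by default).
#' @return a `system_composition`: per-topology molecule counts, water and
#'   sodium counts, total beads, and the realized weight percent.
#' @export
composition_from_weight_percent <- function(L, weight_percent,
                                            topology_set,
                                            topology_weights = NULL,
                                            force_field = load_force_field(),
                                            reduced_density = 3) {
  if (weight_percent < 0 || weight_percent >= 100) {
    stop("`weight_percent` must be in [0, 100)", call. = FALSE)
  }
  if (inherits(topology_set, "molecule_topology")) {
    topology_set <- list(topology_set)
  }
  ff <- force_field
  ntot <- round(reduced_density * L^3)
  if (is.null(topology_weights)) {
    topology_weights <- rep(1, length(topology_set))
  }
  topology_weights <- topology_weights / sum(topology_weights)
  m_w <- ff$molar_masses[[ff$water_species]]
  beads_per_mol <- vapply(topology_set, function(tp) {
    length(tp$bead_sequence)
  }, numeric(1))
  mass_per_mol <- vapply(topology_set, molecule_molar_mass, numeric(1),
                         force_field = ff)
  # averages over the topology mixture; +1 bead for the counterion
  b_avg <- sum(topology_weights * (beads_per_mol + 1))
  m_surf_avg <- sum(topology_weights * mass_per_mol)
  f <- weight_percent / 100
  if (f == 0) {
    counts <- rep(0L, length(topology_set))
  } else {
    # unknowns: m molecules, w water beads, with m*b_avg + w = ntot and
    # m*m_surf / (m*m_surf + (w + m)*m_w) = f  (each Na bead carries one
    # water-bead worth of hydration water mass);
    # substituting w gives m*[m_surf*(1-f) + f*m_w*(b_avg - 1)] = f*ntot*m_w
    m_real <- f * ntot * m_w / (m_surf_avg * (1 - f) + f * m_w * (b_avg - 1))
    counts_real <- topology_weights * m_real
    counts <- round(counts_real)
    if (sum(counts) < 1) {
      stop("box too small to hold one molecule at the requested concentration",
           call. = FALSE)
    }
  }
  m <- sum(counts)
  chain_beads <- sum(counts * beads_per_mol)
  water <- ntot - chain_beads - m
  if (water < 0) {
    stop("box too small: surfactant beads exceed the total bead budget",
         call. = FALSE)
  }
  mass_surf <- sum(counts * mass_per_mol)
  mass_water <- (water + m) * m_w
  realized <- if (mass_surf + mass_water > 0) {
    100 * mass_surf / (mass_surf + mass_water)
  } else 0
  total_charge <- sum(counts * vapply(topology_set, function(tp) {
    tp$net_charge
  }, numeric(1))) + m * ff$charges[[topology_set[[1]]$counterion %||% "Na"]]
  structure(
    list(box_edge = L, weight_percent_requested = weight_percent,
         weight_percent_realized = realized,
         molecule_counts = counts, topologies = topology_set,
         water_count = as.integer(water), sodium_count = as.integer(m),
         total_bead_count = as.integer(ntot), total_charge = total_charge,
         reduced_density = reduced_density),
    class = "system_composition"
  )
}

#' @export
print.system_composition <- function(x, ...) {
  cat(sprintf(
    "composition: L = %g, %d beads, wt%% requested %.2f realized %.2f\n",
    x$box_edge, x$total_bead_count, x$weight_percent_requested,
    x$weight_percent_realized))
  cat(sprintf("  %d chains (+%d Na), %d water beads, net charge %g\n",
              sum(x$molecule_counts), x$sodium_count, x$water_count,
              x$total_charge))
  invisible(x)
}

#' Random initial configuration for a composition
#'
#' Chains are placed as Gaussian random walks at their bonded rest lengths
#' (soft DPD potentials tolerate the resulting overlaps), water and sodium
#' beads uniformly at random. Velocities are Maxwell-Boltzmann at kT = 1 and
#' shifted to zero total momentum. Deterministic for a fixed seed.
#'
#' @param composition a [composition_from_weight_percent()] result.
#' @param seed integer seed.
#' @param kT reduced temperature for the initial velocities.
#' @return a [dpd_system()].
#' @export
random_initial_configuration <- function(composition, seed = 1L, kT = 1) {
  set.seed(seed)
  L <- composition$box_edge
  specs <- character(0)
  mols <- integer(0)
  pos <- list()
  bonds <- list()
  angles <- list()
  offset <- 0L
  mol_id <- 0L
  counter_species <- character(0)
  for (t in seq_along(composition$topologies)) {
    tp <- composition$topologies[[t]]
    cnt <- composition$molecule_counts[t]
    if (cnt == 0) next
    nb <- length(tp$bead_sequence)
    for (mm in seq_len(cnt)) {
      mol_id <- mol_id + 1L
      start <- stats::runif(3, 0, L)
      steps <- matrix(stats::rnorm(3 * (nb - 1)), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) * tp$bonds$l0
      xyz <- rbind(start, start + apply(steps, 2, cumsum))
      if (nb == 2) xyz <- rbind(start, start + steps)
      pos[[length(pos) + 1L]] <- xyz
      specs <- c(specs, tp$bead_sequence)
      mols <- c(mols, rep(mol_id, nb))
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = tp$bonds$from + offset, j = tp$bonds$to + offset,
        l0 = tp$bonds$l0, C = tp$bonds$C)
      if (nrow(tp$angles)) {
        angles[[length(angles) + 1L]] <- data.frame(
          i = tp$angles$i + offset, j = tp$angles$j + offset,
          k = tp$angles$k + offset, theta0 = tp$angles$theta0,
          D = tp$angles$D)
      }
      offset <- offset + nb
      counter_species <- c(counter_species, tp$counterion %||% "Na")
    }
  }
  ns <- composition$sodium_count
  nw <- composition$water_count
  if (ns > 0) {
    pos[[length(pos) + 1L]] <- matrix(stats::runif(3 * ns, 0, L), ncol = 3)
    specs <- c(specs, counter_species)
    mols <- c(mols, rep(NA_integer_, ns))
  }
  if (nw > 0) {
    pos[[length(pos) + 1L]] <- matrix(stats::runif(3 * nw, 0, L), ncol = 3)
    specs <- c(specs, rep("W", nw))
    mols <- c(mols, rep(NA_integer_, nw))
  }
  positions <- do.call(rbind, pos)
  n <- nrow(positions)
  vel <- matrix(stats::rnorm(3 * n, sd = sqrt(kT)), ncol = 3)
  vel <- sweep(vel, 2, colMeans(vel))
  ff <- load_force_field()
  charge <- ff$charges[specs]
  dpd_system(positions = positions, velocities = vel, species = specs,
             molecule = mols, charge = unname(charge), box_edge = L,
             bonds = if (length(bonds)) do.call(rbind, bonds) else
               empty_bonds(),
             angles = if (length(angles)) do.call(rbind, angles) else
               empty_angles())
}
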