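# Reduced-unit system and force-field constant registry.

#' Physical constants used by the unit mapping
#'
#' CODATA values for the Boltzmann constant, Avogadro's number, the
#' elementary charge and the vacuum permittivity, plus the molar mass of
#' water. These anchor the mapping between DPD reduced units and SI.
#'
#' @format A named list of scalars (SI units; molar mass in kg/mol).
#' @export
dpd_constants <- list(
  k_B = 1.380649e-23,       # J/K
  N_A = 6.02214076e23,      # 1/mol
  e   = 1.602176634e-19,    # C
  eps0 = 8.8541878128e-12,  # F/m
  M_water = 18.015e-3       # kg/mol
)

#' Map DPD reduced units onto SI units
#'
#' The reduced-unit system sets the solvent cutoff \eqn{r_C}, the bead mass
#' \eqn{m} and the thermal energy \eqn{k_B T} to 1. The physical length scale
#' follows from matching the reduced bead number density \eqn{\rho r_C^3} to
#' the experimental mass density of water, with each water bead standing for
#' a fixed number of water molecules:
#' \deqn{r_C = (\rho\, m_{bead} / \rho_{water})^{1/3}}
#' The time scale is the derived quantity
#' \eqn{\tau = r_C \sqrt{m / k_B T}}.
#'
#' @param temperature_kelvin absolute temperature (K).
#' @param water_mass_density mass density of water (kg/m^3).
#' @param water_molecules_per_bead number of water molecules per solvent bead.
#' @param reduced_density reduced bead number density \eqn{\rho r_C^3}.
#' @return An object of class `unit_map` with fields `length_scale` (m),
#'   `mass_scale` (kg), `energy_scale` (J) and `time_scale` (s).
#' @examples
#' um <- build_unit_map(298.15, 997, 2, 3)
#' um$length_scale * 1e10  # r_C in Angstrom, about 5.65
#' @export
build_unit_map <- function(temperature_kelvin = 298.15,
                           water_mass_density = 997,
                           water_molecules_per_bead = 2,
                           reduced_density = 3) {
  args <- list(temperature_kelvin = temperature_kelvin,
               water_mass_density = water_mass_density,
               water_molecules_per_bead = water_molecules_per_bead,
               reduced_density = reduced_density)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  mass_scale <- water_molecules_per_bead * dpd_constants$M_water /
    dpd_constants$N_A
  energy_scale <- dpd_constants$k_B * temperature_kelvin
  length_scale <- (reduced_density * mass_scale / water_mass_density)^(1 / 3)
  time_scale <- length_scale * sqrt(mass_scale / energy_scale)
  structure(
    list(length_scale = length_scale, mass_scale = mass_scale,
         energy_scale = energy_scale, time_scale = time_scale,
         temperature_kelvin = temperature_kelvin),
    class = "unit_map"
  )
}

#' @export
print.unit_map <- function(x, ...) {
  cat("DPD unit map:\n")
  cat(sprintf("  length  r_C = %.4g m (%.3f Angstrom)\n",
              x$length_scale, x$length_scale * 1e10))
  cat(sprintf("  mass    m   = %.4g kg\n", x$mass_scale))
  cat(sprintf("  energy  kT  = %.4g J\n", x$energy_scale))
  cat(sprintf("  time    tau = %.4g s\n", x$time_scale))
  invisible(x)
}

#' Convert a quantity between reduced and SI units
#'
#' The dimension signature gives integer exponents over (length, mass,
#' energy, time); e.g. a force is energy/length, `c(-1, 0, 1, 0)`, and a
#' friction coefficient mass/time is `c(0, 1, 0, -1)`. Conversion multiplies
#' by the product of the unit-map scales raised to those exponents.
#'
#' @param value numeric quantity (vectorised).
#' @param dims integer exponents, a named or unnamed length-4 vector in the
#'   order length, mass, energy, time.
#' @param direction `"to_si"` or `"to_reduced"`.
#' @param unit_map a [build_unit_map()] result.
#' @return converted numeric vector.
#' @examples
#' um <- build_unit_map()
#' convert_units(7.52, c(length = 1), "to_si", um) * 1e9 # nm
#' @export
convert_units <- function(value, dims, direction = c("to_si", "to_reduced"),
                          unit_map) {
  direction <- match.arg(direction)
  stopifnot(inherits(unit_map, "unit_map"))
  full <- c(length = 0, mass = 0, energy = 0, time = 0)
  if (is.null(names(dims))) {
    if (length(dims) != 4L) {
      stop("unnamed `dims` must have length 4 (length, mass, energy, time)",
           call. = FALSE)
    }
    full[] <- dims
  } else {
    bad <- setdiff(names(dims), names(full))
    if (length(bad)) {
      stop("unknown dimension token(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    full[names(dims)] <- dims
  }
  if (any(full != round(full))) stop("dimension exponents must be integers",
                                     call. = FALSE)
  fac <- unit_map$length_scale^full[["length"]] *
    unit_map$mass_scale^full[["mass"]] *
    unit_map$energy_scale^full[["energy"]] *
    unit_map$time_scale^full[["time"]]
  if (direction == "to_si") value * fac else value / fac
}

#' Friction coefficient from the thermostat noise amplitude
#'
#' The fluctuation-dissipation constraint ties the dissipative and random
#' pair forces together: \eqn{\sigma^2 = 2 \gamma k_B T}. Given the noise
#' amplitude and the reduced temperature this returns the friction
#' coefficient \eqn{\gamma = \sigma^2 / (2 k_B T)}.
#'
#' @param sigma noise amplitude (reduced units).
#' @param kT reduced temperature, must be positive.
#' @export
gamma_from_sigma <- function(sigma, kT = 1) {
  if (!is.numeric(kT) || any(kT <= 0)) stop("`kT` must be positive",
                                            call. = FALSE)
  sigma^2 / (2 * kT)
}

#' @rdname gamma_from_sigma
#' @param gamma friction coefficient (reduced units).
#' @export
sigma_from_gamma <- function(gamma, kT = 1) {
  if (!is.numeric(kT) || any(kT <= 0)) stop("`kT` must be positive",
                                            call. = FALSE)
  sqrt(2 * gamma * kT)
}

#' Equilibrium bond length from heavy-atom counts
#'
#' Unstretched bond lengths between chain beads grow with the number of
#' heavy atoms (C, O, S) the two beads carry. The rule is configurable: a
#' `linear_heavy` rule takes \eqn{l_0 = c (n_i + n_j)}, while a `pair_table`
#' rule looks the pair up in an explicit table. The shipped default is a
#' linear rule calibrated so that two 2-heavy-atom alkyl beads sit at the
#' projected length of two C-C bonds.
#'
#' @param heavy_i,heavy_j heavy-atom counts of the bonded beads (>= 1).
#' @param bond_rule a list with `type` (`"linear_heavy"` or `"pair_table"`)
#'   and either `coefficient` or `table` (named by "ni-nj" with ni <= nj).
#' @return unstretched bond length \eqn{l_0} in reduced units; symmetric in
#'   its two arguments.
#' @export
bond_length <- function(heavy_i, heavy_j,
                        bond_rule = list(type = "linear_heavy",
                                         coefficient = 0.1125)) {
  if (any(heavy_i < 1) || any(heavy_j < 1)) {
    stop("heavy-atom counts must be >= 1", call. = FALSE)
  }
  if (bond_rule$type == "linear_heavy") {
    bond_rule$coefficient * (heavy_i + heavy_j)
  } else if (bond_rule$type == "pair_table") {
    key <- paste(pmin(heavy_i, heavy_j), pmax(heavy_i, heavy_j), sep = "-")
    out <- unlist(bond_rule$table[key], use.names = FALSE)
    missing_k <- key[!(key %in% names(bond_rule$table))]
    if (length(missing_k)) {
      stop("no bond-length entry for heavy-atom pair(s): ",
           paste(unique(missing_k), collapse = ", "), call. = FALSE)
    }
    out
  } else {
    stop("unknown bond rule type: ", bond_rule$type, call. = FALSE)
  }
}

#' Electrostatic coupling constant for a unit map
#'
#' The dimensionless coupling \eqn{\Gamma = e^2 / (k_B T \epsilon_0
#' \epsilon_r r_C)} fixes the strength of the smeared Coulomb interaction in
#' reduced units.
#'
#' @param unit_map a [build_unit_map()] result.
#' @param relative_permittivity solvent relative permittivity.
#' @export
electro_coupling <- function(unit_map, relative_permittivity = 78.3) {
  stopifnot(inherits(unit_map, "unit_map"))
  dpd_constants$e^2 / (unit_map$energy_scale * dpd_constants$eps0 *
                         relative_permittivity * unit_map$length_scale)
}

#' Bead volume from its self-cutoff
#'
#' The layer-spacing volume model needs per-bead volumes; these are derived
#' from the species self-cutoff \eqn{R_{ii}^C}, with the radius convention
#' (half the cutoff, the default, or the full cutoff) selectable.
#'
#' @param self_cutoff self interaction cutoff \eqn{R_{ii}^C}.
#' @param radius_convention `"half_cutoff"` or `"cutoff"`.
#' @export
bead_volume <- function(self_cutoff,
                        radius_convention = c("half_cutoff", "cutoff")) {
  radius_convention <- match.arg(radius_convention)
  r <- if (radius_convention == "half_cutoff") self_cutoff / 2 else self_cutoff
  4 / 3 * pi * r^3
}

#' Load and validate a force-field configuration
#'
#' Reads a JSON force-field document (species, charges, heavy-atom counts,
#' per-bead molar masses, symmetric repulsion and cutoff matrices, bonded
#' constants, thermostat and electrostatics settings) and validates every
#' structural invariant: matrix symmetry, positive cutoffs, a water-water
#' cutoff of exactly 1, and the fluctuation-dissipation link
#' \eqn{\sigma^2 = 2\gamma k_B T}. Violations are reported collectively.
#'
#' The shipped default, `forcefield_slens_synthetic.json`, is a synthetic
#' reconstruction of a published alkyl-sulfate parameterization scheme (see
#' the package vignette); it is editable data, not code.
#'
#' @param config path to a JSON document, or an already-parsed list.
#' @param unit_map unit map used to derive the electrostatic coupling.
#' @return A validated `dpd_force_field` object.
#' @export
load_force_field <- function(config = default_force_field_path(),
                             unit_map = build_unit_map()) {
  cfg <- if (is.character(config)) {
    jsonlite::fromJSON(config, simplifyVector = TRUE)
  } else {
    config
  }
  problems <- character()
  species <- cfg$species
  ns <- length(species)
  if (ns < 1) problems <- c(problems, "no species defined")
  amat <- as.matrix(cfg$repulsion)
  rmat <- as.matrix(cfg$cutoff)
  dimnames(amat) <- dimnames(rmat) <- list(species, species)
  if (!isTRUE(all.equal(dim(amat), c(ns, ns)))) {
    problems <- c(problems, "repulsion matrix has wrong dimensions")
  }
  asym <- which(abs(amat - t(amat)) > 1e-12, arr.ind = TRUE)
  if (nrow(asym)) {
    pairs <- unique(apply(asym, 1, function(ij) {
      paste(sort(species[ij]), collapse = "-")
    }))
    problems <- c(problems,
                  paste0("repulsion matrix not symmetric for pair(s): ",
                         paste(pairs, collapse = ", ")))
  }
  rsym <- which(abs(rmat - t(rmat)) > 1e-12, arr.ind = TRUE)
  if (nrow(rsym)) {
    pairs <- unique(apply(rsym, 1, function(ij) {
      paste(sort(species[ij]), collapse = "-")
    }))
    problems <- c(problems,
                  paste0("cutoff matrix not symmetric for pair(s): ",
                         paste(pairs, collapse = ", ")))
  }
  if (any(rmat <= 0)) problems <- c(problems, "all cutoffs must be positive")
  wi <- match(cfg$water_species %||% "W", species)
  if (is.na(wi)) {
    problems <- c(problems, "water species not found in species list")
  } else if (abs(rmat[wi, wi] - 1) > 1e-12) {
    problems <- c(problems, "water-water cutoff must be exactly 1")
  }
  th <- cfg$thermostat
  gamma <- th$gamma %||% gamma_from_sigma(th$sigma, th$kT)
  if (abs(th$sigma^2 - 2 * gamma * th$kT) > 1e-9) {
    problems <- c(problems, sprintf(
      "fluctuation-dissipation violated: sigma^2 = %.4g but 2 gamma kT = %.4g",
      th$sigma^2, 2 * gamma * th$kT))
  }
  if (!is.null(th$dt) && th$dt <= 0) {
    problems <- c(problems, "time step must be positive")
  }
  if (length(problems)) {
    stop("invalid force field:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  charges <- unlist(cfg$charges)[species]
  heavy <- unlist(cfg$heavy_atoms)[species]
  molar <- unlist(cfg$molar_masses_gmol)[species]
  el <- cfg$electrostatics %||% list()
  eps_r <- el$relative_permittivity %||% 78.3
  structure(
    list(
      species = species,
      charges = charges,
      heavy_atoms = heavy,
      molar_masses = molar,
      repulsion = amat,
      cutoff = rmat,
      water_species = species[wi],
      bond_rule = cfg$bond_rule,
      bond_C = cfg$bonds$C %||% 150,
      angle_D = cfg$angles$D %||% 5,
      angle_theta0 = cfg$angles$theta0 %||% 180,
      thermostat = list(sigma = th$sigma, gamma = gamma, kT = th$kT,
                        dt = th$dt %||% 0.01),
      electrostatics = list(
        enabled = isTRUE(el$enabled),
        slater_beta = el$slater_beta %||% 0.929,
        relative_permittivity = eps_r,
        coupling = electro_coupling(unit_map, eps_r)
      ),
      unit_map = unit_map
    ),
    class = "dpd_force_field"
  )
}

#' Path to the shipped synthetic SLEnS force-field file
#' @export
default_force_field_path <- function() {
  system.file("extdata", "forcefield_slens_synthetic.json",
              package = "dpdmeso", mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
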