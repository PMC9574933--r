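# Particle configuration container.

#' Construct a particle configuration
#'
#' A `dpd_system` bundles positions, velocities, species labels, molecule
#' ids, charges, the bonded topology and the periodic box. Positions are
#' wrapped into the primary cell `[0, L)^3` on construction.
#'
#' @param positions N x 3 matrix of reduced coordinates.
#' @param velocities N x 3 matrix of reduced velocities (defaults to zero).
#' @param species character vector of bead species labels.
#' @param molecule integer molecule id per bead (`NA` for solvent).
#' @param charge numeric charge per bead in elementary units.
#' @param box_edge cubic box edge L (reduced units).
#' @param bonds data frame with columns `i`, `j`, `l0`, `C` (may be empty).
#' @param angles data frame with columns `i`, `j`, `k`, `theta0`, `D`
#'   (`j` is the central bead).
#' @param shear_offset accumulated Lees-Edwards boundary displacement.
#' @param time reduced simulation time.
#' @return A `dpd_system` object.
#' @export
dpd_system <- function(positions, velocities = NULL, species, molecule = NULL,
                       charge = NULL, box_edge,
                       bonds = empty_bonds(), angles = empty_angles(),
                       shear_offset = 0, time = 0) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, box_edge > 0)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  if (is.null(molecule)) molecule <- rep(NA_integer_, n)
  if (is.null(charge)) charge <- rep(0, n)
  if (length(species) != n || nrow(velocities) != n ||
      length(molecule) != n || length(charge) != n) {
    stop("positions, velocities, species, molecule and charge must agree in length",
         call. = FALSE)
  }
  dimnames(positions) <- NULL
  dimnames(velocities) <- NULL
  positions <- wrap_positions(positions, box_edge)
  shear_offset <- shear_offset %% box_edge
  structure(
    list(positions = positions, velocities = velocities,
         species = as.character(species), molecule = as.integer(molecule),
         charge = as.numeric(charge), box_edge = box_edge,
         bonds = bonds, angles = angles,
         shear_offset = shear_offset, time = time),
    class = "dpd_system"
  )
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), l0 = numeric(), C = numeric())
}

empty_angles <- function() {
  data.frame(i = integer(), j = integer(), k = integer(),
             theta0 = numeric(), D = numeric())
}

#' Wrap coordinates into the primary box
#' @param positions N x 3 matrix.
#' @param box_edge box edge L.
#' @export
wrap_positions <- function(positions, box_edge) {
  positions - box_edge * floor(positions / box_edge)
}

#' Minimum-image displacement vectors
#'
#' @param d matrix (or vector) of raw displacements.
#' @param box_edge box edge L.
#' @export
min_image_disp <- function(d, box_edge) {
  d - box_edge * round(d / box_edge)
}

#' @export
print.dpd_system <- function(x, ...) {
  n <- nrow(x$positions)
  nm <- length(unique(stats::na.omit(x$molecule)))
  cat(sprintf("dpd_system: %d beads (%d molecules) in L = %g box, t = %g\n",
              n, nm, x$box_edge, x$time))
  cat("  species:", paste(sprintf("%s:%d", names(table(x$species)),
                                  table(x$species)), collapse = " "), "\n")
  if (x$shear_offset != 0) cat(sprintf("  shear offset: %g\n", x$shear_offset))
  invisible(x)
}

#' Total momentum of a configuration
#' @param system a `dpd_system` (unit bead masses).
#' @export
total_momentum <- function(system) {
  colSums(system$velocities)
}

#' Instantaneous kinetic temperature
#'
#' Mean kinetic energy per degree of freedom times 2, i.e.
#' \eqn{\sum m v^2 / (3N - 3)} for unit masses with the centre-of-mass
#' momentum removed.
#' @param system a `dpd_system`.
#' @export
kinetic_temperature <- function(system) {
  n <- nrow(system$positions)
  sum(system$velocities^2) / (3 * n - 3)
}
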