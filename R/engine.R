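# DPD force evaluation and time integration (R front end to the compiled
# kernels in src/dpd.cpp).

#' Conservative (soft repulsive) pair force
#'
#' Linear soft repulsion \eqn{F^C = a_{ij} (1 - r/R^C_{ij}) \hat r} for
#' \eqn{r < R^C_{ij}}, zero beyond the cutoff, directed from j to i.
#' Coincident beads receive the maximum repulsion `a_ij` along a seeded
#' random direction (overlaps are legal for soft potentials).
#'
#' @param r_ij vector from bead j to bead i (length 3).
#' @param a_ij maximum repulsion.
#' @param R_cut pair cutoff.
#' @param seed seed for the degenerate coincident-bead direction.
#' @return force on bead i (length-3 vector).
#' @export
conservative_force <- function(r_ij, a_ij, R_cut, seed = 1L) {
  r <- sqrt(sum(r_ij^2))
  if (r >= R_cut) return(c(0, 0, 0))
  if (r < 1e-12) {
    set.seed(seed)
    u <- stats::rnorm(3)
    return(a_ij * u / sqrt(sum(u^2)))
  }
  a_ij * (1 - r / R_cut) * r_ij / r
}

#' Dissipative and random thermostat pair forces
#'
#' The pair thermostat:
#' \deqn{F^D = -\gamma\, \omega^D(r) (\hat r \cdot v_{ij}) \hat r, \quad
#'       F^R = \sigma\, \omega^R(r)\, \zeta\, \Delta t^{-1/2} \hat r}
#' with \eqn{\omega^R(r) = 1 - r/R^C} below the cutoff and
#' \eqn{\omega^D = (\omega^R)^2}, the choice that closes the
#' fluctuation-dissipation relation when \eqn{\sigma^2 = 2\gamma k_B T}.
#'
#' @param r_ij separation vector (i minus j).
#' @param v_ij relative velocity (i minus j).
#' @param gamma friction coefficient.
#' @param sigma noise amplitude.
#' @param R_cut pair cutoff.
#' @param dt time step (must be positive; enters as \eqn{\Delta t^{-1/2}}).
#' @param noise the symmetric unit-variance Gaussian draw \eqn{\zeta_{ij}}.
#' @return list with `dissipative` and `random` force vectors on bead i.
#' @export
pair_thermostat_forces <- function(r_ij, v_ij, gamma, sigma, R_cut, dt,
                                   noise) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  r <- sqrt(sum(r_ij^2))
  if (r >= R_cut || r < 1e-12) {
    return(list(dissipative = c(0, 0, 0), random = c(0, 0, 0)))
  }
  rhat <- r_ij / r
  w <- 1 - r / R_cut
  fd <- -gamma * w^2 * sum(rhat * v_ij) * rhat
  fr <- sigma * w * noise / sqrt(dt) * rhat
  list(dissipative = fd, random = fr)
}

#' Harmonic bond force
#'
#' Forces from \eqn{U = (C/2)(r - l_0)^2}: a restoring pair along the bond,
#' antisymmetric between the partners.
#'
#' @param r_ij separation vector from j to i.
#' @param l0 unstretched bond length.
#' @param C spring constant.
#' @return list with `force_i` and `force_j`.
#' @export
bond_force <- function(r_ij, l0, C) {
  stopifnot(l0 > 0, C > 0)
  r <- sqrt(sum(r_ij^2))
  if (r < 1e-12) return(list(force_i = c(0, 0, 0), force_j = c(0, 0, 0)))
  f <- -C * (r - l0) * r_ij / r
  list(force_i = f, force_j = -f)
}

#' Harmonic angle force
#'
#' Forces from \eqn{U = (D/2)(\theta - \theta_0)^2} on an i-j-k triple
#' (j central). The net force and net torque of the triple vanish;
#' collinear configurations at \eqn{\theta_0 = 180^\circ} are handled by
#' the analytic limit rather than a division by zero.
#'
#' @param pos_i,pos_j,pos_k bead positions (length-3 vectors).
#' @param theta0 equilibrium angle in degrees.
#' @param D angle constant.
#' @return list with `force_i`, `force_j`, `force_k` and the angle `theta`
#'   (degrees).
#' @export
angle_force <- function(pos_i, pos_j, pos_k, theta0 = 180, D = 5) {
  a <- pos_i - pos_j
  b <- pos_k - pos_j
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2))
  stopifnot(la > 1e-12, lb > 1e-12)
  ca <- max(-1, min(1, sum(a * b) / (la * lb)))
  th <- acos(ca)
  s <- sqrt(max(1 - ca^2, 0))
  th0 <- theta0 * pi / 180
  dth <- th - th0
  if (abs(dth) < 1e-14 || (s < 1e-8 && abs(th0 - pi) < 1e-8)) {
    z <- c(0, 0, 0)
    return(list(force_i = z, force_j = z, force_k = z, theta = th * 180 / pi))
  }
  f <- D * dth / max(s, 1e-8)
  fi <- f * (b / lb - ca * a / la) / la
  fk <- f * (a / la - ca * b / lb) / lb
  list(force_i = fi, force_j = -(fi + fk), force_k = fk,
       theta = th * 180 / pi)
}

#' Slater-smeared Coulomb pair energy (closed form)
#'
#' \deqn{u(r) = \frac{\Gamma q_i q_j}{4\pi r}
#'   \left[1 - (1 + \beta^* r) e^{-2\beta^* r}\right]}
#' finite at contact (limit \eqn{\Gamma q_i q_j \beta^*/4\pi}) and
#' approaching the point-charge Coulomb form at large separation.
#'
#' @param r separation (reduced units), vectorised.
#' @param qi,qj charges.
#' @param coupling dimensionless coupling \eqn{\Gamma}.
#' @param beta Slater smearing parameter \eqn{\beta^*}.
#' @export
slater_pair_energy <- function(r, qi, qj, coupling, beta = 0.929) {
  ke <- coupling / (4 * pi)
  ifelse(r < 1e-12, ke * qi * qj * beta,
         ke * qi * qj / r * (1 - (1 + beta * r) * exp(-2 * beta * r)))
}

ewald_settings <- function(L, coupling, accuracy = 1e-4) {
  # choose real cutoff + splitting + k extent for the target force accuracy
  rcut <- min(L / 2, 5)
  alpha <- sqrt(-log(accuracy * 0.1)) / rcut
  kmax <- max(4L, as.integer(ceiling(alpha * L * sqrt(-log(accuracy * 0.1)) /
                                       pi)))
  list(rcut = rcut, alpha = alpha, kmax = kmax)
}

electro_list <- function(system, force_field, enabled = NULL) {
  el <- force_field$electrostatics
  on <- if (is.null(enabled)) el$enabled else enabled
  on <- on && any(system$charge != 0)
  if (!on) return(list(enabled = FALSE))
  if (abs(sum(system$charge)) > 1e-9) {
    stop("electrostatics requires a charge-neutral system", call. = FALSE)
  }
  if (system$shear_offset != 0) {
    stop("Ewald electrostatics is implemented for orthogonal boxes only; ",
         "disable electrostatics or run at zero shear offset", call. = FALSE)
  }
  es <- ewald_settings(system$box_edge, el$coupling)
  list(enabled = TRUE, coupling = el$coupling, beta = el$slater_beta,
       alpha = es$alpha, rcut = es$rcut, kmax = es$kmax)
}

sys_spec_idx <- function(system, force_field) {
  idx <- match(system$species, force_field$species)
  if (anyNA(idx)) {
    stop("species not in force field: ",
         paste(unique(system$species[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  idx
}

bonds_mats <- function(system) {
  b <- system$bonds
  a <- system$angles
  list(bonds = cbind(as.integer(b$i), as.integer(b$j)),
       bond_l0 = as.numeric(b$l0), bond_C = as.numeric(b$C),
       angles = cbind(as.integer(a$i), as.integer(a$j), as.integer(a$k)),
       angle_th0 = as.numeric(a$theta0), angle_D = as.numeric(a$D))
}

#' Evaluate all forces on a configuration
#'
#' Computes the full force breakdown (conservative, dissipative, random,
#' bond, angle, electrostatic) at a given integration step. The random
#' contribution is drawn from a counter-based stream keyed on
#' `(seed, step, sorted pair ids)`, so the result is reproducible and
#' independent of pair traversal order.
#'
#' @param system a [dpd_system()].
#' @param force_field a [load_force_field()] object.
#' @param seed integer RNG stream seed.
#' @param step integration step index.
#' @param method `"cell"` for linked-cell lists or `"brute"` for the
#'   all-pairs reference path (identical results to 1e-12).
#' @param electrostatics override the force field's electrostatics switch.
#' @param breakdown return per-component force matrices.
#' @return list with `force` (N x 3) plus the component matrices and the
#'   electrostatic energy when `breakdown = TRUE`.
#' @export
compute_forces <- function(system, force_field = load_force_field(),
                           seed = 1L, step = 0L,
                           method = c("cell", "brute"),
                           electrostatics = NULL, breakdown = FALSE) {
  method <- match.arg(method)
  ff <- force_field
  spec <- sys_spec_idx(system, ff)
  bm <- bonds_mats(system)
  el <- electro_list(system, ff, electrostatics)
  cpp_forces(system$positions, system$velocities, spec, system$charge,
             system$box_edge, system$shear_offset, 0,
             ff$repulsion, ff$cutoff,
             ff$thermostat$sigma, ff$thermostat$gamma, ff$thermostat$dt,
             bm$bonds, bm$bond_l0, bm$bond_C,
             bm$angles, bm$angle_th0, bm$angle_D,
             el, as.double(seed), as.double(step),
             method == "cell", breakdown)
}

#' Electrostatic forces and energy under periodic boundaries
#'
#' Slater-smeared Coulomb interactions evaluated by Ewald splitting, with
#' settings auto-tuned for ~1e-4 relative force accuracy. Requires a
#' charge-neutral system.
#'
#' @inheritParams compute_forces
#' @return list with `force` (N x 3, electrostatic only) and `energy`.
#' @export
electrostatic_forces <- function(system, force_field = load_force_field()) {
  ff <- force_field
  # suppress the short-range DPD terms by zeroing the repulsion matrix
  ff$repulsion[] <- 0
  ff$thermostat$sigma <- 0
  ff$thermostat$gamma <- 0
  sys <- system
  sys$bonds <- empty_bonds()
  sys$angles <- empty_angles()
  res <- compute_forces(sys, ff, electrostatics = TRUE, breakdown = TRUE)
  list(force = res$electrostatic, energy = res$energy_elec)
}

#' Reference direct-sum electrostatics for small boxes
#'
#' Brute-force lattice sum of the smeared Coulomb interaction over periodic
#' images, used only to cross-validate the Ewald solver in tests. O(N^2 M^3)
#' cost; keep `n_images` and N small.
#'
#' Cubic-shell summation converges to the vacuum (spherical) boundary
#' condition; the default subtracts the cell-dipole surface term so the
#' result matches the tinfoil (conducting) boundary the Ewald solver uses.
#'
#' @param system charge-neutral `dpd_system`.
#' @param force_field force field (coupling, smearing).
#' @param n_images images summed per direction.
#' @param boundary `"tinfoil"` (dipole term removed) or `"vacuum"`.
#' @export
direct_sum_electrostatics <- function(system,
                                      force_field = load_force_field(),
                                      n_images = 6,
                                      boundary = c("tinfoil", "vacuum")) {
  boundary <- match.arg(boundary)
  el <- force_field$electrostatics
  ke <- el$coupling / (4 * pi)
  beta <- el$slater_beta
  x <- system$positions
  q <- system$charge
  L <- system$box_edge
  n <- nrow(x)
  f <- matrix(0, n, 3)
  energy <- 0
  shifts <- as.matrix(expand.grid(-n_images:n_images, -n_images:n_images,
                                  -n_images:n_images)) * L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (q[i] == 0 || q[j] == 0) next
      for (s in seq_len(nrow(shifts))) {
        if (i == j && all(shifts[s, ] == 0)) next
        d <- x[i, ] - x[j, ] + shifts[s, ]
        r <- sqrt(sum(d^2))
        g <- (1 - (1 + beta * r) * exp(-2 * beta * r)) / r
        energy <- energy + 0.5 * ke * q[i] * q[j] * g
        # f = -du/dr
        dg <- (-1 / r^2) * (1 - (1 + beta * r) * exp(-2 * beta * r)) +
          (1 / r) * (2 * beta * (1 + beta * r) - beta) * exp(-2 * beta * r)
        fm <- -ke * q[i] * q[j] * dg
        f[i, ] <- f[i, ] + fm * d / r
      }
    }
  }
  if (boundary == "tinfoil") {
    M <- colSums(q * x)
    V <- L^3
    energy <- energy - ke * 2 * pi * sum(M^2) / (3 * V)
    f <- f + ke * 4 * pi / (3 * V) * outer(q, M)
  }
  list(force = f, energy = energy)
}

#' Advance a configuration by DPD time steps
#'
#' Runs the modified velocity-Verlet integrator (Groot-Warren, lambda =
#' 0.65 by default) for `n_steps` steps of the force field's `dt`, with
#' optional Lees-Edwards shear (flow along x, gradient along z). Bitwise
#' reproducible for a fixed seed; a run restarted from its final state
#' continues identically.
#'
#' @param system a [dpd_system()].
#' @param force_field a [load_force_field()] object.
#' @param n_steps number of integration steps.
#' @param seed integer seed for the thermostat noise stream.
#' @param snapshot_stride save a frame every this many steps (0 = none;
#'   frame 0 is always included when > 0).
#' @param shear_rate Lees-Edwards shear rate (reduced units; 0 = off).
#' @param lambda velocity-prediction parameter of the integrator.
#' @param method pair search method.
#' @param electrostatics override the force field's electrostatics switch.
#' @param step0 index of the first step (used for restarts so the noise
#'   stream continues rather than repeats).
#' @param restart_force N x 3 force matrix from a previous run's
#'   checkpoint (`$force`); supplying it makes the continuation bitwise
#'   identical to an uninterrupted run.
#' @param temperature_stride record instantaneous kinetic temperature every
#'   this many steps (0 = never).
#' @return a `dpd_trajectory`: list with the final `system`, `frames`
#'   (each with positions, velocities, time, shear offset), and the
#'   temperature series.
#' @export
run_dpd <- function(system, force_field = load_force_field(),
                    n_steps = 1000L, seed = 1L, snapshot_stride = 0L,
                    shear_rate = 0, lambda = 0.65,
                    method = c("cell", "brute"), electrostatics = NULL,
                    step0 = 0L, temperature_stride = 0L,
                    restart_force = NULL) {
  method <- match.arg(method)
  ff <- force_field
  spec <- sys_spec_idx(system, ff)
  bm <- bonds_mats(system)
  el <- electro_list(system, ff, electrostatics)
  res <- cpp_run(system$positions, system$velocities, spec, system$charge,
                 system$box_edge, system$shear_offset, shear_rate,
                 ff$repulsion, ff$cutoff,
                 ff$thermostat$sigma, ff$thermostat$gamma, ff$thermostat$dt,
                 bm$bonds, bm$bond_l0, bm$bond_C,
                 bm$angles, bm$angle_th0, bm$angle_D,
                 el, as.double(seed), as.double(step0),
                 as.integer(n_steps), as.integer(snapshot_stride),
                 lambda, method == "cell", system$time,
                 as.integer(temperature_stride),
                 if (is.null(restart_force)) matrix(0, 0, 3) else
                   restart_force)
  out_sys <- system
  out_sys$positions <- res$positions
  out_sys$velocities <- res$velocities
  out_sys$time <- res$time
  out_sys$shear_offset <- res$shear_offset
  structure(
    list(system = out_sys, frames = res$frames, force = res$force,
         temperature = res$temperature,
         temperature_time = res$temperature_time,
         step = res$step, seed = seed, shear_rate = shear_rate),
    class = "dpd_trajectory"
  )
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat(sprintf("dpd_trajectory: %d frames, final t = %g (step %d)\n",
              length(x$frames), x$system$time, x$step))
  invisible(x)
}

#' Apply a Lees-Edwards boundary update to a configuration
#'
#' Advances the accumulated boundary offset by `shear_rate * L * dt`
#' (modulo L) and re-wraps particles, applying the image displacement and
#' image-velocity correction to beads crossing the sheared (z) boundary.
#' With `shear_rate = 0` this reduces to a plain periodic wrap.
#'
#' @param system a [dpd_system()].
#' @param shear_rate shear rate (reduced units).
#' @param dt time increment over which the offset advances.
#' @export
apply_lees_edwards <- function(system, shear_rate, dt) {
  stopifnot(is.finite(shear_rate))
  L <- system$box_edge
  system$shear_offset <- (system$shear_offset + shear_rate * L * dt) %% L
  nz <- floor(system$positions[, 3] / L)
  cross <- nz != 0
  if (any(cross)) {
    system$positions[cross, 3] <- system$positions[cross, 3] - nz[cross] * L
    system$positions[cross, 1] <- system$positions[cross, 1] -
      nz[cross] * system$shear_offset
    system$velocities[cross, 1] <- system$velocities[cross, 1] -
      nz[cross] * shear_rate * L
  }
  system$positions <- wrap_positions(system$positions, L)
  system
}
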