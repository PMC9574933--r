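# shared objects for the suite: load the force field once
ff_default <- load_force_field()
um_default <- build_unit_map()

random_water_box <- function(n, L, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- sweep(v, 2, colMeans(v))
  dpd_system(positions = matrix(runif(3 * n, 0, L), ncol = 3),
             velocities = v, species = rep("W", n), box_edge = L)
}

# brute-force union-find clustering oracle at molecule level
oracle_clusters <- function(system, cutoff = 1.0,
                            tail_species = c("CT", "CM")) {
  mol <- system$molecule
  mols <- sort(unique(mol[!is.na(mol)]))
  parent <- seq_along(mols)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  tidx <- which(system$species %in% tail_species & !is.na(mol))
  L <- system$box_edge
  for (a in seq_along(tidx)) {
    for (b in seq_len(a - 1)) {
      d <- min_image_disp(system$positions[tidx[a], ] -
                            system$positions[tidx[b], ], L)
      if (sum(d^2) <= cutoff^2) {
        ra <- find(match(mol[tidx[a]], mols))
        rb <- find(match(mol[tidx[b]], mols))
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(mols), find, integer(1))
  match(roots, unique(roots))
}

expect_same_partition <- function(a, b) {
  # two cluster labelings are the same partition iff the label pairing is
  # one-to-one
  expect_equal(length(a), length(b))
  tab <- table(a, b)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# far-from-equilibrium start: bimodal speeds with zero total momentum
bimodal_v <- function(n3) {
  v <- matrix(sample(c(-1.5, 1.5), n3, replace = TRUE), ncol = 3)
  sweep(v, 2, colMeans(v))
}
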