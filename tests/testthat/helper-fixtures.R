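# shared fixture builders and independent oracles

# minimal topology data.frame; all arguments recycled to n
make_topology <- function(role, n = length(role), name = role,
                          resname = "UNK", bead_radius = 0.26,
                          tail_position = NA_integer_,
                          molecule_id = seq_len(n), groove = NA_character_) {
  helix <- ifelse(role %in% c("DNA_BB", "DNA_BASE", "ETHYL"), 0L, NA_integer_)
  strand <- ifelse(is.na(helix), NA_integer_, 0L)
  df <- data.frame(particle_id = seq_len(n), role = rep_len(role, n),
                   molecule_id = rep_len(molecule_id, n),
                   helix_id = rep_len(helix, n), strand_id = rep_len(strand, n),
                   residue_index = seq_len(n),
                   bead_radius = rep_len(bead_radius, n),
                   tail_position = rep_len(tail_position, n),
                   name = rep_len(name, n), resname = rep_len(resname, n),
                   groove = rep_len(groove, n), stringsAsFactors = FALSE)
  new("ParticleTopology", particles = df)
}

# trajectory from a list of n x 3 position matrices
make_traj <- function(topology, frames, box = c(20, 20, 20), dt = 50) {
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(frames[[1]])
  co <- array(0, c(n, 3, length(frames)))
  for (i in seq_along(frames)) co[, , i] <- frames[[i]]
  new("Trajectory", topology = topology, coords = co,
      times = (seq_along(frames) - 1) * dt,
      box = matrix(box, length(frames), 3, byrow = TRUE))
}

# static single-frame trajectory of the ideal tube as smooth cylinders
cylinder_tube_traj <- function(model = buildHexagonalScaffold(), dz = 0.05) {
  cyl <- modelAsCylinders(model, dz = dz)
  make_traj(cyl$topology, cyl$frame$positions, box = cyl$frame$box)
}

# exhaustive xy-grid oracle for the largest-inscribed-sphere slice radius.
# P: particle coords in the axis frame, R: radii; independent of the
# annealed implementation.
grid_slice_oracle <- function(P, R, z0, half_extent = 1, step = 0.01) {
  gx <- seq(-half_extent, half_extent, by = step)
  gy <- seq(-half_extent, half_extent, by = step)
  G <- as.matrix(expand.grid(x = gx, y = gy))
  best <- rep(Inf, nrow(G))
  for (i in seq_len(nrow(P))) {
    d <- sqrt((G[, 1] - P[i, 1])^2 + (G[, 2] - P[i, 2])^2 +
                (P[i, 3] - z0)^2) - R[i]
    best <- pmin(best, d)
  }
  max(best)
}

# closed-form rmsd between two already-superposed coordinate sets
plain_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
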