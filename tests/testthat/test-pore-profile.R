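# HOLE-style largest-inscribed-sphere profiling and conductance

ring_traj <- function(c_radius = 1.5, bead_r = 0.3, n = 24, z = 10,
                      nz = 5, dz_step = 0.3) {
  pos <- do.call(rbind, lapply(seq_len(nz), function(k) {
    ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    cbind(10 + c_radius * cos(ang), 10 + c_radius * sin(ang),
          z + (k - (nz + 1) / 2) * dz_step)
  }))
  topo <- make_topology("DNA_BB", n = nrow(pos), bead_radius = bead_r,
                        resname = "DNT0")
  make_traj(topo, pos)
}

test_that("a centred bead ring gives pore radius c - r_bead", {
  traj <- ring_traj(c_radius = 1.5, bead_r = 0.3)
  fr <- getFrame(traj, 1)
  axis <- list(point = c(10, 10, 10), dir = c(0, 0, 1))
  res <- poreRadiusSlice(fr$positions, topology(traj), z = 0, axis = axis,
                         seed = 3L)
  expect_equal(res$radius, 1.2, tolerance = 1e-3)
  expect_false(res$open)
  expect_lt(sum(res$center^2), 1e-4)
})

test_that("an empty slice reports the cap radius flagged open", {
  traj <- ring_traj()
  fr <- getFrame(traj, 1)
  axis <- list(point = c(10, 10, 10), dir = c(0, 0, 1))
  res <- poreRadiusSlice(fr$positions, topology(traj), z = 50, axis = axis,
                         r_cap = 5)
  expect_true(res$open)
  expect_equal(res$radius, 5)
})

test_that("annealed slice radii match an exhaustive grid oracle on random slices", {
  n_trials <- 25L
  worst <- 0
  for (trial in seq_len(n_trials)) {
    set.seed(1000 + trial)
    n <- 50L
    P <- cbind(runif(n, -2, 2), runif(n, -2, 2), runif(n, -0.6, 0.6))
    # keep a lumen open near the origin
    keep <- sqrt(P[, 1]^2 + P[, 2]^2) > 0.4
    P <- P[keep, , drop = FALSE]
    R <- runif(nrow(P), 0.15, 0.3)
    oracle <- grid_slice_oracle(P, R, z0 = 0, half_extent = 1, step = 0.01)
    got <- DNTPore:::.slice_anneal(P, R, z0 = 0, start = c(0, 0), r_cap = 5,
                                   seed = trial)
    worst <- max(worst, oracle - got$radius)
  }
  expect_lt(worst, 0.01)
})

test_that("adding a particle never increases a slice radius", {
  set.seed(21)
  for (k in 1:10) {
    n <- 30L
    P <- cbind(runif(n, -2, 2), runif(n, -2, 2), runif(n, -0.5, 0.5))
    R <- rep(0.25, n)
    base <- DNTPore:::.slice_anneal(P, R, 0, c(0, 0), 5, seed = k)
    P2 <- rbind(P, c(runif(1, -1, 1), runif(1, -1, 1), 0))
    more <- DNTPore:::.slice_anneal(P2, c(R, 0.25), 0, c(0, 0), 5, seed = k)
    expect_lte(more$radius, base$radius + 0.01)
  }
})

test_that("profiles are identical across frames of a static system and invariant under rotation", {
  cyl <- modelAsCylinders(buildHexagonalScaffold())
  traj <- make_traj(cyl$topology,
                    list(cyl$frame$positions, cyl$frame$positions,
                         cyl$frame$positions), box = cyl$frame$box)
  pp <- poreProfileOverTime(traj, z_range = c(-1, 1), dz = 0.25, seed = 5L)
  # identical geometry per frame; independent annealing seeds agree to the
  # optimizer's accuracy
  expect_equal(pp@radius[1, ], pp@radius[2, ], tolerance = 1e-3)
  expect_equal(pp@radius[2, ], pp@radius[3, ], tolerance = 1e-3)
  expect_equal(pp@sd_radius, rep(0, length(pp@z)), tolerance = 1e-3)

  # rigid rotation of system + axis leaves the profile unchanged
  th <- 25 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
               3, 3, byrow = TRUE)
  ctr <- colMeans(cyl$frame$positions)
  rot <- sweep(sweep(cyl$frame$positions, 2, ctr) %*% t(Rx), 2, ctr, "+")
  traj_r <- make_traj(cyl$topology, rot, box = cyl$frame$box)
  pp_r <- poreProfileOverTime(traj_r, z_range = c(-1, 1), dz = 0.25, seed = 5L)
  expect_equal(pp_r@mean_radius, pp@mean_radius, tolerance = 1e-3)
})

test_that("the ideal six-duplex tube has a ~1 nm open lumen", {
  pp <- poreProfileOverTime(cylinder_tube_traj(), z_range = c(-2, 2),
                            dz = 0.1, seed = 1L)
  expect_equal(mean(pp@mean_radius), 1.0, tolerance = 0.02)
})

test_that("a breathing pore has radius SD a/sqrt(2)", {
  a <- 0.2; r0 <- 1.5
  nf <- 64L
  phases <- 2 * pi * (seq_len(nf) - 1) / nf
  frames <- lapply(phases, function(ph) {
    n <- 36
    ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    r <- r0 + a * sin(ph)
    do.call(rbind, lapply(-2:2, function(k)
      cbind(10 + r * cos(ang), 10 + r * sin(ang), 10 + k * 0.2)))
  })
  topo <- make_topology("DNA_BB", n = nrow(frames[[1]]), bead_radius = 0.26,
                        resname = "DNT0")
  traj <- make_traj(topo, frames)
  pp <- poreProfileOverTime(traj, z_range = c(0, 0), dz = 0.1, seed = 2L)
  expect_equal(mean(pp@radius[, 1]), r0 - 0.26, tolerance = 0.01)
  expect_equal(sd(pp@radius[, 1]), a / sqrt(2), tolerance = 0.02)
})

test_that("conductance modes agree on a cylinder and scale with resistivity", {
  zs <- seq(-2, 2, by = 0.1)
  mk_profile <- function(r) new("PoreProfile", z = zs,
                                radius = matrix(r, 1, length(zs)),
                                center_x = matrix(0, 1, length(zs)),
                                center_y = matrix(0, 1, length(zs)),
                                mean_radius = rep(r, length(zs)),
                                sd_radius = rep(0, length(zs)),
                                r_cap = 9, times = 0)
  cyl <- mk_profile(1.0)
  gu <- conductanceEstimate(cyl, 8.9, mode = "uniform")
  gs <- conductanceEstimate(cyl, 8.9, mode = "series_integral")
  expect_equal(gu$g_nS, gs$g_nS, tolerance = 1e-9)
  # analytic check: g = pi R^2 / (rho L)
  expect_equal(gu$g_nS, pi * 1^2 / (8.9e7 * gu$length_nm) * 1e9,
               tolerance = 1e-9)
  # two electrolytes, same geometry: ratio = rho2/rho1
  g2 <- conductanceEstimate(cyl, 27.4, mode = "series_integral")
  expect_equal(gs$g_nS / g2$g_nS, 27.4 / 8.9, tolerance = 1e-12)
  # a closed slice short-circuits series mode to zero
  closed <- mk_profile(1.0)
  closed@mean_radius[20] <- 0
  gc_ <- conductanceEstimate(closed, 8.9, mode = "series_integral")
  expect_equal(gc_$g_nS, 0)
  expect_equal(gc_$closed_at, zs[20])
})

test_that("series-integral conductance is stable under dz refinement", {
  mk <- function(dz) {
    zs <- seq(-2, 2, by = dz)
    r <- 1 + 0.3 * sin(zs)
    new("PoreProfile", z = zs, radius = matrix(r, 1, length(zs)),
        center_x = matrix(0, 1, length(zs)),
        center_y = matrix(0, 1, length(zs)),
        mean_radius = r, sd_radius = rep(0, length(zs)), r_cap = 9, times = 0)
  }
  g1 <- conductanceEstimate(mk(0.1), 8.9)$g_nS
  g2 <- conductanceEstimate(mk(0.05), 8.9)$g_nS
  expect_equal(g1, g2, tolerance = 0.02)
})

test_that("conductance ratios follow geometry and resistivity", {
  zs <- seq(-2, 2, by = 0.1)
  mk <- function(r) new("PoreProfile", z = zs,
                        radius = matrix(r, 1, length(zs), byrow = TRUE),
                        center_x = matrix(0, 1, length(zs)),
                        center_y = matrix(0, 1, length(zs)),
                        mean_radius = rep_len(r, length(zs)),
                        sd_radius = rep(0, length(zs)), r_cap = 9, times = 0)
  same <- conductanceRatio(mk(1.0), mk(1.0), 27.4, 8.9)
  expect_equal(same$ratio, 27.4 / 8.9, tolerance = 1e-12)
  # a narrower high-salt pore reduces the ratio below rho_low/rho_high
  narrower <- conductanceRatio(mk(1.0), mk(0.8), 27.4, 8.9)
  expect_lt(narrower$ratio, 27.4 / 8.9)
})
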