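# radial densities, thickness, order parameters, RDFs, ion selectivity

test_that("the pore axis is recovered for straight and tilted tubes", {
  tt <- modelToTopology(buildHexagonalScaffold())
  fr <- tt$frame
  ax <- poreAxis(fr$positions, tt$topology)
  expect_lt(sum(abs(ax$dir - c(0, 0, 1))), 1e-3)

  # rotate 10 degrees about x through the COM
  ctr <- colMeans(fr$positions)
  th <- 10 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
               3, 3, byrow = TRUE)
  rot <- sweep(sweep(fr$positions, 2, ctr) %*% t(Rx), 2, ctr, "+")
  ax10 <- poreAxis(rot, tt$topology)
  expect_equal(acos(abs(ax10$dir[3])) * 180 / pi, 10, tolerance = 0.5)

  # degenerate planar set errors
  flat <- fr$positions
  flat[, 3] <- 0
  expect_error(poreAxis(flat, tt$topology), "degenerate")
  expect_error(poreAxis(fr$positions[1:2, ], tt$topology), "3 DNT")
})

test_that("uniform annulus density matches the analytic value and mass is conserved", {
  set.seed(31)
  n <- 4000
  r <- sqrt(runif(n, 2^2, 4^2))
  th <- runif(n, 0, 2 * pi)
  z <- runif(n, -2, 2)
  pos <- cbind(10 + r * cos(th), 10 + r * sin(th), 10 + z)
  topo <- make_topology("WATER", n = n)
  traj <- make_traj(topo, pos)
  rd <- radialDensity(traj, roles = c("WATER", "ION_NA"), shell_width = 0.25,
                      cylinder_half_length = 2)
  expected <- n / (pi * (4^2 - 2^2) * 4)
  mid <- rd$r_mid > 2.3 & rd$r_mid < 3.7
  expect_equal(mean(rd$WATER[mid]), expected, tolerance = 0.05)
  expect_true(all(rd$ION_NA == 0))
  # density conservation: sum(density * shell volume) = mean in-cylinder count
  vol <- pi * (rd$r_hi^2 - rd$r_lo^2) * 4
  expect_equal(sum(rd$WATER * vol), attr(rd, "mean_count")[["WATER"]],
               tolerance = 1e-6)
})

test_that("DNA radial density peaks at the lumen wall of the built tube", {
  sys <- generateMembraneSystem(
    membraneSystemParams(seed = 8L, lipid_count = 80L, water_count = 0L,
                         bulk_ion_pairs = 0L, lumen_ion_count = 0L,
                         jitter_sd = 0.02),
    n_frames = 3L)
  rd <- radialDensity(sys$trajectory, roles = "DNA_BB", shell_width = 0.1)
  expect_equal(sum(rd$DNA_BB[rd$r_hi <= 0.8]), 0)      # open lumen
  peak_r <- rd$r_mid[which.max(rd$DNA_BB)]
  expect_equal(peak_r, 1.0, tolerance = 0.25)           # inner wall radius
})

test_that("thickness profiling recovers the thinning parameters within 10%", {
  p <- membraneSystemParams(seed = 3L, thinning_amplitude = 0.8,
                            thinning_decay = 1.0, lipid_count = 450L,
                            water_count = 0L, bulk_ion_pairs = 0L,
                            lumen_ion_count = 0L)
  sys <- generateMembraneSystem(p, n_frames = 20L)
  th <- thicknessProfile(sys$trajectory, shell_width = 0.2)
  fit <- fitThinningProfile(th, sys$ground_truth$r_wall)
  expect_equal(unname(fit["h0"]), 4.0, tolerance = 0.1)
  expect_equal(unname(fit["A"]), 0.8, tolerance = 0.1)
  expect_equal(unname(fit["lambda"]), 1.0, tolerance = 0.1)
  # thinning persists ~2 nm from the wall: beyond 3*lambda thickness is back
  far <- th$r_mid > sys$ground_truth$r_wall + 3 & !is.na(th$thickness)
  expect_lt(max(abs(th$thickness[far] - 4.0)), 0.15)
})

test_that("thickness is invariant under rigid translation of the system", {
  sys <- generateMembraneSystem(
    membraneSystemParams(seed = 6L, lipid_count = 150L, water_count = 0L,
                         bulk_ion_pairs = 0L, lumen_ion_count = 0L),
    n_frames = 4L)
  th1 <- thicknessProfile(sys$trajectory, shell_width = 0.4)
  shifted <- sys$trajectory
  shifted@coords <- shifted@coords + 1.7
  th2 <- thicknessProfile(shifted, shell_width = 0.4)
  expect_equal(th1$thickness, th2$thickness, tolerance = 1e-9)
})

test_that("order parameter hits its exact bounds and stays within them", {
  mkchain <- function(step) {
    nb <- 5L
    topo <- make_topology("LIPID_TAIL_SN1", n = nb, name = paste0("C", 1:nb, "B"),
                          tail_position = 1:nb, molecule_id = 1L)
    pos <- sweep(t(vapply(0:(nb - 1), function(k) k * step, numeric(3))), 2,
                 c(5, 5, 5), "+")
    make_traj(topo, pos, box = c(10, 10, 10))
  }
  gz <- orderParameterGrid(mkchain(c(0, 0, 0.47)), min_samples = 1)
  expect_equal(max(gz$S, na.rm = TRUE), 1.0)
  gx <- orderParameterGrid(mkchain(c(0.47, 0, 0)), min_samples = 1)
  expect_equal(min(gx$S, na.rm = TRUE), -0.5)

  # isotropic random bonds: |S| small; bounds always hold
  set.seed(77)
  nb <- 10001L
  topo <- make_topology("LIPID_TAIL_SN2", n = nb, name = "C1A",
                        tail_position = rep(1:2, length.out = nb),
                        molecule_id = rep(seq_len(ceiling(nb / 2)), each = 2)[1:nb])
  u <- matrix(rnorm(nb * 3), nb, 3)
  u <- u / sqrt(rowSums(u^2)) * 0.47
  pos <- matrix(5, nb, 3)
  even <- which(seq_len(nb) %% 2 == 0)
  pos[even, ] <- pos[even - 1L, ] + u[even, ]
  g <- orderParameterGrid(make_traj(topo, pos, box = c(10, 10, 10)),
                          grid_cell = 10, min_samples = 1)
  expect_lt(abs(g$S[which.max(g$n)]), 0.02)
  expect_true(all(g$S >= -0.5 - 1e-12 & g$S <= 1 + 1e-12, na.rm = TRUE))
  # sparsely sampled cells are flagged missing, not zero-filled
  g10 <- orderParameterGrid(mkchain(c(0, 0, 0.47)), min_samples = 10)
  expect_true(all(is.na(g10$S)))
})

test_that("RDFs normalise to 1 for Poisson particles and spike at fixed pairs", {
  set.seed(12)
  n <- 600L
  topo <- make_topology("WATER", n = n)
  frames <- lapply(1:4, function(i) matrix(runif(n * 3, 0, 12), n, 3))
  traj <- make_traj(topo, frames, box = c(12, 12, 12))
  g <- rdfProfile(traj, 1:n, 1:n, bin_width = 0.3)
  expect_equal(mean(g$g[g$r_mid > 1]), 1.0, tolerance = 0.05)
  expect_true(all(g$g >= 0))

  # two fixed particles 0.7 nm apart: single-bin spike
  topo2 <- make_topology("ION_NA", n = 2)
  pos2 <- rbind(c(5, 5, 5), c(5.7, 5, 5))
  g2 <- rdfProfile(make_traj(topo2, pos2, box = c(12, 12, 12)), 1L, 2L,
                   bin_width = 0.1)
  expect_equal(g2$r_mid[which(g2$g > 0)], 0.75)
  expect_error(rdfProfile(make_traj(topo2, pos2), integer(), 1L), "non-empty")
})

test_that("RDF first peak sits at a templated contact distance", {
  set.seed(5)
  n <- 200L
  dna <- matrix(runif(n * 3, 4, 8), n, 3)
  u <- matrix(rnorm(n * 3), n, 3)
  u <- u / sqrt(rowSums(u^2))
  head_pos <- dna + 0.9 * u
  topo <- make_topology(c(rep("DNA_BB", n), rep("LIPID_NC3", n)), n = 2L * n)
  traj <- make_traj(topo, rbind(dna, head_pos), box = c(12, 12, 12))
  g <- rdfProfile(traj, 1:n, n + 1:n, bin_width = 0.05, r_max = 3)
  # restrict to r beyond accidental near-contacts of the dense template
  far <- g$r_mid > 0.3
  expect_equal(g$r_mid[far][which.max(g$g[far])], 0.925, tolerance = 0.05)
})

test_that("ion selectivity handles balanced, skewed and anion-free lumens", {
  mkions <- function(n_na, n_cl) {
    n <- n_na + n_cl
    topo <- make_topology(c(rep("ION_NA", n_na), rep("ION_CL", n_cl)), n = n)
    ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    pos <- cbind(10 + 0.5 * cos(ang), 10 + 0.5 * sin(ang),
                 10 + seq(-2, 2, length.out = n))
    make_traj(topo, pos)
  }
  eq <- ionSelectivity(mkions(40, 40), radius = 1, half_length = 3)
  expect_equal(eq$ratio, 1.0)
  sk <- ionSelectivity(mkions(40, 20), radius = 1, half_length = 3)
  expect_equal(sk$ratio, 2.0)
  expect_true(sk$ci[1] < 2 && 2 < sk$ci[2])
  inf <- ionSelectivity(mkions(10, 0), radius = 1, half_length = 3)
  expect_true(is.infinite(inf$ratio))
  expect_equal(inf$mean_na, 10)
  expect_equal(inf$mean_cl, 0)
})
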