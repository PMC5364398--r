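#' @include membrane_profiles.R
NULL

# largest-inscribed-sphere radius in one slice plane (axis-aligned coords).
# P: n x 3 particle coords, R: bead radii. Sphere centres move in xy at fixed
# z0; the clearance function is min_i(|c - p_i| - R_i) over ALL particles
# (3D distances, as in HOLE). Maximized in two stages: a deterministic
# coarse scan (0.05 nm grid restricted to a search disc around the seed
# centre, which keeps the path inside the channel) followed by
# simulated-annealing Monte Carlo refinement of the best-separated coarse
# candidates (geometric step cooling, Metropolis acceptance with temperature
# proportional to the step, deterministic seed).
.slice_anneal <- function(P, R, z0, start, r_cap, n_moves = 1000L,
                          step0 = 0.1, step1 = 0.005, seed = 1L,
                          search_radius = 1.5, coarse_step = 0.05,
                          n_candidates = 3L) {
  keep <- abs(P[, 3] - z0) <= r_cap + max(R, 0)
  if (!any(keep))
    return(list(radius = r_cap, center = start, open = TRUE))
  P <- P[keep, , drop = FALSE]
  R <- R[keep]
  dz2 <- (P[, 3] - z0)^2
  clearance <- function(cx, cy)
    min(sqrt((cx - P[, 1])^2 + (cy - P[, 2])^2 + dz2) - R)

  # stage 1: coarse scan of the search disc
  g <- seq(-search_radius, search_radius, by = coarse_step)
  G <- as.matrix(expand.grid(start[1] + g, start[2] + g))
  G <- G[(G[, 1] - start[1])^2 + (G[, 2] - start[2])^2 <= search_radius^2 &
           G[, 1]^2 + G[, 2]^2 <= r_cap^2, , drop = FALSE]
  if (!nrow(G)) G <- matrix(start, 1, 2)
  vals <- rep(Inf, nrow(G))
  for (i in seq_len(nrow(P)))
    vals <- pmin(vals, sqrt((G[, 1] - P[i, 1])^2 +
                              (G[, 2] - P[i, 2])^2 + dz2[i]) - R[i])
  ord <- order(vals, decreasing = TRUE)
  sel <- ord[1]
  for (j in ord) {
    if (length(sel) >= n_candidates) break
    if (all((G[j, 1] - G[sel, 1])^2 + (G[j, 2] - G[sel, 2])^2 > 0.04))
      sel <- c(sel, j)
  }

  # stage 2: annealed refinement of each candidate
  with_seed(seed, {
    best <- G[sel[1], ]
    f_best <- vals[sel[1]]
    per <- max(1L, n_moves %/% length(sel))
    steps <- step0 * (step1 / step0)^((seq_len(per) - 1) / max(per - 1, 1))
    for (s in sel) {
      cur <- G[s, ]
      f_cur <- vals[s]
      for (m in seq_len(per)) {
        cand <- cur + stats::rnorm(2, 0, steps[m])
        if (sum(cand^2) > r_cap^2 ||
            sum((cand - start)^2) > search_radius^2) next
        f_cand <- clearance(cand[1], cand[2])
        if (f_cand > f_cur ||
            stats::runif(1) < exp((f_cand - f_cur) / (0.5 * steps[m]))) {
          cur <- cand; f_cur <- f_cand
          if (f_cur > f_best) { best <- cur; f_best <- f_cur }
        }
      }
    }
    list(radius = max(min(f_best, r_cap), 0), center = best,
         open = f_best >= r_cap)
  })
}

#' Largest-inscribed-sphere pore radius in one slice
#'
#' HOLE-style: the radius of the largest sphere centred in the plane z = `z`
#' (in the axis frame) that touches no particle's surface, found by
#' simulated-annealing Monte Carlo over the sphere centre's xy position.
#' Water and ions are excluded by default; remaining particles use their
#' topology `bead_radius`. The radius is capped at `r_cap` (default half the
#' smaller lateral box length); a slice with no particles in range reports
#' `r_cap` flagged open.
#'
#' @param positions n x 3 coordinates (nm)
#' @param topology a [ParticleTopology-class]
#' @param z slice coordinate along the axis (nm, relative to `axis$point`)
#' @param axis list(`point`, `dir`) as from [poreAxis()]
#' @param exclude_roles roles removed before profiling
#' @param probe_radius extra probe radius added to every bead radius, nm
#' @param r_cap radius cap, nm
#' @param start starting centre (xy, axis frame)
#' @param n_moves,step0,step1 annealing schedule
#' @param seed deterministic annealing seed
#' @return list(`radius` nm, `center` xy, `open` flag)
#' @export
poreRadiusSlice <- function(positions, topology, z, axis,
                            exclude_roles = c("WATER", "ION_NA", "ION_CL"),
                            probe_radius = 0, r_cap = NULL,
                            start = c(0, 0), n_moves = 1000L,
                            step0 = 0.1, step1 = 0.01, seed = 1L) {
  p <- particleData(topology)
  idx <- which(!(p$role %in% exclude_roles))
  if (!length(idx)) stopf("no particles left after exclusions")
  R <- p$bead_radius[idx]
  if (anyNA(R) || any(R <= 0)) stopf("pore profiling requires bead_radius > 0")
  if (is.null(r_cap)) r_cap <- 10
  B <- .axis_basis(axis$dir)
  rel <- sweep(positions[idx, , drop = FALSE], 2, axis$point) %*% B
  .slice_anneal(rel, R + probe_radius, z, start, r_cap,
                n_moves = n_moves, step0 = step0, step1 = step1, seed = seed)
}

#' Pore radius profile over z and time
#'
#' Computes the largest-inscribed-sphere radius on a z grid for every frame.
#' Within a frame, slices are optimized sequentially with each slice's centre
#' seeded from the previous slice's optimum (keeping the centre path
#' continuous, as HOLE does), with an independent restart from the axis every
#' `restart_every` slices to escape side channels. z is measured along the
#' per-frame pore axis from the bilayer midplane (tube COM when no lipids
#' are present). Mean and SD per z are over frames whose slice is not capped.
#'
#' @param traj a [Trajectory-class] (apply [analysisWindow()] first)
#' @param z_range length-2 axial range, nm
#' @param dz slice spacing, nm
#' @param tm_region z-range for the axis fit (NULL: all DNT particles)
#' @param restart_every independent restart period, slices
#' @param seed base seed; each (frame, slice) derives a fixed sub-seed
#' @inheritParams poreRadiusSlice
#' @return a [PoreProfile-class]
#' @export
poreProfileOverTime <- function(traj, z_range = c(-2, 2), dz = 0.1,
                                exclude_roles = c("WATER", "ION_NA", "ION_CL"),
                                probe_radius = 0, r_cap = NULL,
                                tm_region = NULL, restart_every = 10L,
                                n_moves = 1000L, seed = 1L) {
  nf <- nFrames(traj)
  if (nf == 0L) stopf("trajectory holds no frames")
  topo <- topology(traj)
  p <- particleData(topo)
  idx <- which(!(p$role %in% exclude_roles))
  if (!length(idx)) stopf("no particles left after exclusions")
  R0 <- p$bead_radius[idx] + probe_radius
  zs <- seq(z_range[1], z_range[2], by = dz)
  nz <- length(zs)
  if (is.null(r_cap)) r_cap <- min(traj@box[1, 1:2]) / 2
  rad <- cx <- cy <- matrix(NA_real_, nf, nz)
  for (f in seq_len(nf)) {
    fr <- getFrame(traj, f)
    ax <- .frame_axis(fr$positions, topo, tm_region, fr$box)
    mid <- bilayerMidplane(fr$positions, topo)
    if (!is.na(mid) && abs(ax$dir[3]) > 1e-9) {
      lam <- (mid - ax$point[3]) / ax$dir[3]
      origin <- ax$point + lam * ax$dir
    } else origin <- ax$point
    B <- .axis_basis(ax$dir)
    rel <- sweep(fr$positions[idx, , drop = FALSE], 2, origin) %*% B
    prev <- c(0, 0)
    for (s in seq_len(nz)) {
      st <- if ((s - 1L) %% restart_every == 0L) c(0, 0) else prev
      res <- .slice_anneal(rel, R0, zs[s], st, r_cap,
                           n_moves = n_moves,
                           seed = mix_seed(seed, f, s))
      rad[f, s] <- res$radius
      cx[f, s] <- res$center[1]; cy[f, s] <- res$center[2]
      prev <- res$center
    }
  }
  valid <- rad < r_cap - 1e-9
  mean_r <- vapply(seq_len(nz), function(s) {
    v <- rad[valid[, s], s]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  sd_r <- vapply(seq_len(nz), function(s) {
    v <- rad[valid[, s], s]
    if (length(v) > 1) stats::sd(v) else NA_real_
  }, numeric(1))
  new("PoreProfile", z = zs, radius = rad, center_x = cx, center_y = cy,
      mean_radius = mean_r, sd_radius = sd_r, r_cap = r_cap,
      times = frameTimes(traj))
}

#' Electrolyte resistivity defaults (Ohm cm)
#'
#' Overridable defaults for common electrolytes; the pore conductance model
#' takes resistivity as an explicit argument.
#' @return named numeric vector, Ohm cm
#' @export
resistivityTable <- function() {
  c("KCl_1.0M" = 8.9, "KCl_0.3M" = 27.4, "NaCl_0.15M" = 62)
}

#' Pore conductance from a radius profile
#'
#' `g = pi R^2 / (rho L)` for a pore of radius `R`, length `L` and
#' electrolyte resistivity `rho`. `"uniform"` mode uses the mean radius over
#' valid (uncapped) slices; `"series_integral"` treats each slice as a
#' resistor in series: `1/g = (rho/pi) * sum(dz / R(z)^2)`. A zero radius in
#' series mode gives g = 0 with a `closed_at` flag.
#'
#' @param profile a [PoreProfile-class]
#' @param resistivity Ohm cm
#' @param mode `"uniform"` or `"series_integral"`
#' @return list(`g_nS`, `mode`, `resistivity_ohm_cm`, `length_nm`,
#'   `mean_radius_nm`, `closed_at`)
#' @export
conductanceEstimate <- function(profile, resistivity,
                                mode = c("series_integral", "uniform")) {
  mode <- match.arg(mode)
  ok <- is.finite(profile@mean_radius)
  if (!any(ok)) stopf("profile holds no valid (uncapped) slices")
  r <- profile@mean_radius[ok]
  z <- profile@z[ok]
  dz <- if (length(z) > 1) stats::median(diff(profile@z)) else 1
  L <- length(r) * dz
  rho_nm <- resistivity * 1e7          # Ohm cm -> Ohm nm
  closed_at <- NULL
  if (mode == "uniform") {
    Rm <- mean(r)
    g <- pi * Rm^2 / (rho_nm * L)      # Siemens
  } else {
    if (any(r <= 0)) {
      closed_at <- z[r <= 0]
      g <- 0
      Rm <- mean(r)
    } else {
      g <- 1 / ((rho_nm / pi) * sum(dz / r^2))
      Rm <- mean(r)
    }
  }
  list(g_nS = g * 1e9, mode = mode, resistivity_ohm_cm = resistivity,
       length_nm = L, mean_radius_nm = Rm, closed_at = closed_at)
}

#' Conductance ratio between two electrolyte conditions
#'
#' `g_high / g_low` with each conductance computed by [conductanceEstimate()]
#' in series-integral mode from that condition's own radius profile and
#' resistivity.
#'
#' @param profile_low,profile_high [PoreProfile-class] at low / high salt
#' @param rho_low,rho_high resistivities, Ohm cm
#' @param mode conductance mode
#' @return list(`ratio`, `g_low_nS`, `g_high_nS`)
#' @export
conductanceRatio <- function(profile_low, profile_high, rho_low, rho_high,
                             mode = "series_integral") {
  gl <- conductanceEstimate(profile_low, rho_low, mode)
  gh <- conductanceEstimate(profile_high, rho_high, mode)
  list(ratio = gh$g_nS / gl$g_nS, g_low_nS = gl$g_nS, g_high_nS = gh$g_nS)
}
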