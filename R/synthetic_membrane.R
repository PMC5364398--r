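#' @include model_builder.R
NULL

#' Parameters for the synthetic membrane/DNT system generator
#'
#' Defaults emulate the coarse-grained study system: a ~18 x 18 x 25 nm box,
#' a PC bilayer of equilibrium phosphate-phosphate thickness 4.0 nm that
#' thins exponentially near the tube wall (amplitude 0.8 nm, decay 1.0 nm,
#' so thinning persists to roughly 2 nm from the surface), a six-duplex DNT
#' with a 7-ring hydrophobic band centred in the membrane core, a cation-rich
#' lumen and a neutral bulk electrolyte.
#'
#' @param box box lengths, nm
#' @param bilayer_thickness_h0 far-field P-P thickness, nm
#' @param thinning_amplitude thinning at the tube wall, nm
#' @param thinning_decay exponential decay length, nm
#' @param lipid_count lipids per leaflet
#' @param tube a [DNTModel-class] (bands placed); NULL for a membrane-only system
#' @param tilt_angle tube tilt about x, degrees
#' @param lumen_cation_anion_ratio target Na+:Cl- ratio inside the lumen
#' @param lumen_ion_count ions placed inside the lumen
#' @param bulk_ion_pairs neutral NaCl pairs in the bulk
#' @param water_count water beads
#' @param order_param_target list with `breaks` (radial zone edges from the
#'   tube wall, nm) and `S` (target order parameter per zone)
#' @param jitter_sd per-frame thermal jitter SD per coordinate, nm
#' @param seed RNG seed
#' @return parameter list
#' @export
membraneSystemParams <- function(box = c(18, 18, 25),
                                 bilayer_thickness_h0 = 4.0,
                                 thinning_amplitude = 0.8,
                                 thinning_decay = 1.0,
                                 lipid_count = 450L,
                                 tube = placeHydrophobicBands(buildHexagonalScaffold(), "7-band"),
                                 tilt_angle = 0,
                                 lumen_cation_anion_ratio = 14,
                                 lumen_ion_count = 100L,
                                 bulk_ion_pairs = 200L,
                                 water_count = 1000L,
                                 order_param_target = list(breaks = 1.5,
                                                           S = c(0.25, 0.45)),
                                 jitter_sd = 0.05,
                                 seed = 1L) {
  stopifnot(bilayer_thickness_h0 > 0, lumen_cation_anion_ratio >= 0,
            lipid_count >= 0, lumen_ion_count >= 0, bulk_ion_pairs >= 0,
            water_count >= 0)
  as.list(environment())
}

# zone order parameter for radial distance from the tube wall
.zone_S <- function(r_from_wall, target) {
  zone <- findInterval(r_from_wall, target$breaks) + 1L
  target$S[pmin(zone, length(target$S))]
}

#' Generate a synthetic membrane/DNT trajectory with known ground truth
#'
#' Lipids are rigid templated bead chains (CG POPC naming: NC3, PO4, GL1/GL2,
#' four beads per acyl chain) jittered per frame, not dynamically simulated.
#' Leaflet phosphate planes follow `h(r) = h0 - A exp(-(r - r_wall)/lambda)`
#' outside the tube wall radius. Tail bonds are drawn with a fixed polar
#' angle chosen so the per-zone order parameter equals its target exactly in
#' expectation, with uniform azimuth. Lumen ions are cations with probability
#' `ratio/(1+ratio)` (binomial ground truth recorded); the bulk holds equal
#' numbers of Na+ and Cl-. Identical seed and parameters give bit-identical
#' output.
#'
#' @param params see [membraneSystemParams()]
#' @param n_frames frames to generate
#' @param frame_interval ps between frames
#' @return list(`trajectory` = [Trajectory-class], `ground_truth` = list)
#' @export
generateMembraneSystem <- function(params = membraneSystemParams(),
                                   n_frames = 25L, frame_interval = 50) {
  p <- params
  with_seed(p$seed, {
    cx <- p$box[1] / 2; cy <- p$box[2] / 2; cz <- p$box[3] / 2
    tube <- p$tube
    r_wall <- if (is.null(tube)) 0 else tube@spacing_d + tube@helix_radius
    half_len <- if (is.null(tube)) 0 else
      (tube@length_bp - 1) / 2 * tube@rise_per_bp

    # --- lipids -------------------------------------------------------------
    free_area <- p$box[1] * p$box[2] - pi * (r_wall + 0.3)^2
    if (p$lipid_count * 0.40 > free_area)
      stopf("lipid area (%g nm^2) exceeds available box area (%g nm^2)",
            p$lipid_count * 0.40, free_area)
    sample_xy <- function(n) {
      out <- matrix(NA_real_, 0, 2)
      while (nrow(out) < n) {
        m <- cbind(stats::runif(2 * n, 0, p$box[1]),
                   stats::runif(2 * n, 0, p$box[2]))
        r <- sqrt((m[, 1] - cx)^2 + (m[, 2] - cy)^2)
        out <- rbind(out, m[r > r_wall + 0.3, , drop = FALSE])
      }
      out[seq_len(n), , drop = FALSE]
    }
    bead_names <- c("NC3", "PO4", "GL1", "GL2",
                    "C1A", "D2A", "C3A", "C4A",
                    "C1B", "C2B", "C3B", "C4B")
    bead_roles <- c("LIPID_NC3", "LIPID_PO4", "LIPID_GLY", "LIPID_GLY",
                    rep("LIPID_TAIL_SN2", 4), rep("LIPID_TAIL_SN1", 4))
    bead_tailpos <- c(NA, NA, NA, NA, 1:4, 1:4)
    build_leaflet <- function(n, upper) {
      xy <- sample_xy(n)
      r <- sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)
      h <- p$bilayer_thickness_h0 -
        p$thinning_amplitude * exp(-pmax(r - r_wall, 0) / p$thinning_decay)
      sgn <- if (upper) 1 else -1
      S <- .zone_S(r - r_wall, p$order_param_target)
      cos_th <- sqrt((2 * S + 1) / 3)
      b <- 0.47
      pos <- array(NA_real_, c(n, 12, 3))
      pos[, 1, ] <- cbind(xy, cz + sgn * (h / 2 + 0.30))
      pos[, 2, ] <- cbind(xy, cz + sgn * h / 2)
      pos[, 3, ] <- cbind(xy, cz + sgn * (h / 2 - 0.30))
      pos[, 4, ] <- cbind(xy + 0.25, cz + sgn * (h / 2 - 0.35))
      for (chain in 0:1) {
        anchor <- pos[, 3 + chain, , drop = FALSE]
        cur <- matrix(anchor, n, 3)
        for (kk in 1:4) {
          az <- stats::runif(n, 0, 2 * pi)
          sin_th <- sqrt(pmax(1 - cos_th^2, 0))
          step <- cbind(b * sin_th * cos(az), b * sin_th * sin(az),
                        -sgn * b * cos_th)
          cur <- cur + step
          pos[, 4 + chain * 4 + kk, ] <- cur
        }
      }
      pos
    }
    up <- build_leaflet(p$lipid_count, TRUE)
    lo <- build_leaflet(p$lipid_count, FALSE)
    lipid_pos <- rbind(matrix(aperm(up, c(2, 1, 3)), ncol = 3),
                       matrix(aperm(lo, c(2, 1, 3)), ncol = 3))
    n_lip <- 2L * p$lipid_count
    lipid_top <- data.frame(
      role = rep(bead_roles, n_lip),
      molecule_id = rep(seq_len(n_lip), each = 12L),
      helix_id = NA_integer_, strand_id = NA_integer_,
      residue_index = rep(seq_len(n_lip), each = 12L),
      bead_radius = 0.26,
      tail_position = rep(bead_tailpos, n_lip),
      name = rep(bead_names, n_lip), resname = "POPC",
      groove = NA_character_, stringsAsFactors = FALSE)

    # --- tube ---------------------------------------------------------------
    tube_top <- NULL; tube_pos <- NULL
    rot <- rotation_matrix(c(1, 0, 0), p$tilt_angle)
    if (!is.null(tube)) {
      tt <- modelToTopology(tube, box = p$box)
      tube_top <- particleData(tt$topology)[, -1]
      rel <- sweep(tt$frame$positions, 2, c(cx, cy, cz))
      tube_pos <- sweep(rel %*% t(rot), 2, c(cx, cy, cz), "+")
    }

    # --- ions ---------------------------------------------------------------
    ion_top <- NULL; ion_pos <- NULL
    gt_lumen <- list(cations = 0L, anions = 0L)
    if (!is.null(tube) && p$lumen_ion_count > 0L) {
      n <- p$lumen_ion_count
      rr <- 0.6 * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      zz <- stats::runif(n, -(half_len - 0.5), half_len - 0.5)
      rel <- cbind(rr * cos(th), rr * sin(th), zz)
      lum <- sweep(rel %*% t(rot), 2, c(cx, cy, cz), "+")
      p_cat <- p$lumen_cation_anion_ratio / (1 + p$lumen_cation_anion_ratio)
      is_cat <- stats::runif(n) < p_cat
      gt_lumen <- list(cations = sum(is_cat), anions = sum(!is_cat))
      ion_pos <- lum
      ion_role <- ifelse(is_cat, "ION_NA", "ION_CL")
    } else {
      ion_role <- character()
      ion_pos <- matrix(0, 0, 3)
    }
    if (p$bulk_ion_pairs > 0L) {
      n <- 2L * p$bulk_ion_pairs
      repeat {
        bx <- cbind(stats::runif(2 * n, 0, p$box[1]),
                    stats::runif(2 * n, 0, p$box[2]),
                    stats::runif(2 * n, 0, p$box[3]))
        rxy <- sqrt((bx[, 1] - cx)^2 + (bx[, 2] - cy)^2)
        # outside the membrane slab and clear of the lumen cylinder, so the
        # lumen ion ratio stays the recorded ground truth
        ok <- abs(bx[, 3] - cz) > p$bilayer_thickness_h0 / 2 + 0.5 &
          !(rxy < 1.5 & abs(bx[, 3] - cz) < half_len + 0.5)
        bx <- bx[ok, , drop = FALSE]
        if (nrow(bx) >= n) break
      }
      ion_pos <- rbind(ion_pos, bx[seq_len(n), ])
      ion_role <- c(ion_role, rep(c("ION_NA", "ION_CL"), p$bulk_ion_pairs))
    }
    if (length(ion_role)) {
      ion_top <- data.frame(
        role = ion_role, molecule_id = seq_along(ion_role),
        helix_id = NA_integer_, strand_id = NA_integer_,
        residue_index = seq_along(ion_role), bead_radius = 0.23,
        tail_position = NA_integer_,
        name = ifelse(ion_role == "ION_NA", "NA+", "CL-"),
        resname = "ION", groove = NA_character_, stringsAsFactors = FALSE)
    }

    # --- water --------------------------------------------------------------
    wat_top <- NULL; wat_pos <- NULL
    if (p$water_count > 0L) {
      n <- p$water_count
      n_lum <- if (is.null(tube)) 0L else as.integer(round(0.1 * n))
      n_bulk <- n - n_lum
      repeat {
        bx <- cbind(stats::runif(3 * n_bulk, 0, p$box[1]),
                    stats::runif(3 * n_bulk, 0, p$box[2]),
                    stats::runif(3 * n_bulk, 0, p$box[3]))
        rxy <- sqrt((bx[, 1] - cx)^2 + (bx[, 2] - cy)^2)
        ok <- abs(bx[, 3] - cz) > p$bilayer_thickness_h0 / 2 + 0.4 &
          !(rxy < 1.5 & abs(bx[, 3] - cz) < half_len + 0.5)
        bx <- bx[ok, , drop = FALSE]
        if (nrow(bx) >= n_bulk) break
      }
      wat_pos <- bx[seq_len(n_bulk), , drop = FALSE]
      if (n_lum > 0L) {
        rr <- 0.8 * sqrt(stats::runif(n_lum))
        th <- stats::runif(n_lum, 0, 2 * pi)
        zz <- stats::runif(n_lum, -(half_len - 0.5), half_len - 0.5)
        rel <- cbind(rr * cos(th), rr * sin(th), zz)
        wat_pos <- rbind(wat_pos, sweep(rel %*% t(rot), 2, c(cx, cy, cz), "+"))
      }
      wat_top <- data.frame(
        role = "WATER", molecule_id = seq_len(n),
        helix_id = NA_integer_, strand_id = NA_integer_,
        residue_index = seq_len(n), bead_radius = 0.26,
        tail_position = NA_integer_, name = "W", resname = "W",
        groove = NA_character_, stringsAsFactors = FALSE)
    }

    # --- assemble -----------------------------------------------------------
    tops <- list(lipid_top, tube_top, ion_top, wat_top)
    tops <- tops[!vapply(tops, is.null, logical(1))]
    top <- do.call(rbind, tops)
    # renumber molecules consecutively across blocks
    sizes <- vapply(tops, function(x) max(x$molecule_id), numeric(1))
    off <- cumsum(c(0, utils::head(sizes, -1)))
    k <- 0L
    for (i in seq_along(tops)) {
      rows <- seq_len(nrow(tops[[i]])) + k
      top$molecule_id[rows] <- top$molecule_id[rows] + off[i]
      k <- k + nrow(tops[[i]])
    }
    top <- cbind(particle_id = seq_len(nrow(top)), top)
    rownames(top) <- NULL
    topo <- new("ParticleTopology", particles = top)
    base <- rbind(lipid_pos, tube_pos, ion_pos, wat_pos)
    stopifnot(nrow(base) == nrow(top))

    nfr <- as.integer(n_frames)
    coords <- array(0, c(nrow(base), 3, nfr))
    for (f in seq_len(nfr))
      coords[, , f] <- base +
        matrix(stats::rnorm(length(base), 0, p$jitter_sd), nrow(base), 3)
    traj <- new("Trajectory", topology = topo, coords = coords,
                times = (seq_len(nfr) - 1) * frame_interval,
                box = matrix(p$box, nfr, 3, byrow = TRUE))

    gt <- list(params = p[setdiff(names(p), "tube")],
               r_wall = r_wall, tube_half_length = half_len,
               lumen_cations = gt_lumen$cations,
               lumen_anions = gt_lumen$anions,
               midplane_z = cz, tilt_angle = p$tilt_angle)
    list(trajectory = traj, ground_truth = gt)
  })
}
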