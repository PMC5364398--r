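#' @include AllClasses.R
NULL

#' Parameters for the synthetic steered-MD force trace generator
#'
#' Defaults emulate constant-velocity pushing of the DNT through the bilayer
#' at 10 nm per microsecond: a broad entry force build-up peaking at
#' ~1000 kJ mol^-1 nm^-1 as the tube enters the membrane, a zero-force
#' transmembrane plateau, and an exit barrier of ~400 kJ mol^-1 nm^-1 caused
#' by the hydrophobic band (set `exit_peak = 0` for a band-free tube, which
#' leaves the bilayer without resistance).
#'
#' @param pull_velocity nm per microsecond
#' @param entry_peak,exit_peak barrier heights, kJ mol^-1 nm^-1
#' @param entry_width,exit_width Gaussian widths of the barriers along the
#'   pulled COM coordinate, nm
#' @param plateau_force transmembrane plateau force, kJ mol^-1 nm^-1
#' @param noise_sd white force noise SD, kJ mol^-1 nm^-1
#' @param bilayer_half bilayer half-thickness, nm (barrier centres sit at
#'   -/+ this COM-z)
#' @param z_start initial band-COM z relative to bilayer COM, nm
#' @param seed RNG seed
#' @return parameter list
#' @export
smdTraceParams <- function(pull_velocity = 10, entry_peak = 1000,
                           exit_peak = 400, entry_width = 0.8,
                           exit_width = 0.8, plateau_force = 0,
                           noise_sd = 50, bilayer_half = 2.0,
                           z_start = -8, seed = 1L) {
  stopifnot(pull_velocity > 0, entry_peak >= 0, exit_peak >= 0)
  as.list(environment())
}

#' Generate a synthetic SMD force trace
#'
#' The pulled COM advances at constant velocity; the applied force is the sum
#' of Gaussian entry and exit bumps (centred where the band COM crosses the
#' lower and upper bilayer boundaries), the plateau force, and white noise.
#' Ground truth (true peak heights and locations) is stored on the trace.
#'
#' @param params see [smdTraceParams()]
#' @param duration microseconds
#' @param dt sampling interval, ps
#' @return a [ForceTrace-class]
#' @export
generateSMDTrace <- function(params = smdTraceParams(), duration = 2, dt = 10) {
  p <- params
  with_seed(p$seed, {
    t <- seq(0, duration * 1e6, by = dt)      # ps
    z <- p$z_start + p$pull_velocity * 1e-6 * t
    f <- p$entry_peak * exp(-(z + p$bilayer_half)^2 / (2 * p$entry_width^2)) +
      p$exit_peak * exp(-(z - p$bilayer_half)^2 / (2 * p$exit_width^2)) +
      p$plateau_force * as.numeric(abs(z) < p$bilayer_half)
    if (p$noise_sd > 0) f <- f + stats::rnorm(length(t), 0, p$noise_sd)
    new("ForceTrace", time = t, force = f, com_z = z,
        pull_velocity = p$pull_velocity,
        ground_truth = list(entry_peak = p$entry_peak,
                            exit_peak = p$exit_peak,
                            entry_z = -p$bilayer_half,
                            exit_z = p$bilayer_half,
                            entry_width = p$entry_width,
                            exit_width = p$exit_width,
                            noise_sd = p$noise_sd,
                            bilayer_half = p$bilayer_half))
  })
}

#' Generate a synthetic COM displacement trace
#'
#' Emulates the relaxation / exit behaviour of a DNT displaced by `delta_z0`
#' along the bilayer normal. `"relax"` mode decays exponentially back to zero
#' with decay constant `relax_time / 3` (so the trace has essentially
#' relaxed, to exp(-3) of the initial offset, at `relax_time`); `"exit"` mode
#' drifts monotonically away with superimposed diffusion.
#'
#' @param delta_z0 initial displacement, nm
#' @param mode `"relax"` or `"exit"`
#' @param relax_time relaxation time scale, ns
#' @param duration trace length, ns
#' @param dt sampling interval, ps
#' @param noise_sd measurement noise SD, nm
#' @param drift_velocity exit-mode drift, nm per ns
#' @param diffusion_sd exit-mode random-walk step SD per sample, nm
#' @param seed RNG seed
#' @return data.frame with columns `time` (ps) and `dz` (nm); ground truth in
#'   `attr(, "ground_truth")`
#' @export
generateDisplacementTrace <- function(delta_z0, mode = c("relax", "exit"),
                                      relax_time = 40, duration = 200,
                                      dt = 50, noise_sd = 0.05,
                                      drift_velocity = 0.05,
                                      diffusion_sd = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(duration > 0)
  with_seed(seed, {
    t <- seq(0, duration * 1000, by = dt)     # ps
    if (mode == "relax") {
      dz <- delta_z0 * exp(-3 * t / (relax_time * 1000))
    } else {
      sgn <- if (delta_z0 >= 0) 1 else -1
      dz <- delta_z0 + sgn * drift_velocity * t / 1000 +
        cumsum(stats::rnorm(length(t), 0, diffusion_sd))
    }
    if (noise_sd > 0) dz <- dz + stats::rnorm(length(t), 0, noise_sd)
    out <- data.frame(time = t, dz = dz)
    attr(out, "ground_truth") <- list(delta_z0 = delta_z0, mode = mode,
                                      relax_time = relax_time,
                                      noise_sd = noise_sd)
    out
  })
}

#' Generate a lipid/DNA contact fixture trajectory for residence analysis
#'
#' Builds a small trajectory in which representative lipid beads toggle
#' between a contact position (within the contact cutoff of a groove-labelled
#' DNA bead) and a distant position, with contact lifetimes drawn from
#' exponential distributions whose means differ per bead type and per groove.
#' The sn2 defaults are longer than sn1, emulating the asymmetry of
#' acyl-chain/groove interactions.
#'
#' @param n_frames frames
#' @param frame_interval ps
#' @param mean_on named numeric vector: mean contact lifetime (ps) per bead
#'   name
#' @param groove_factor multiplier on `mean_on` per groove
#' @param mean_off mean off (no contact) time, ps
#' @param n_repeats lipid beads per (bead, groove) combination
#' @param seed RNG seed
#' @return list(`trajectory`, `ground_truth`)
#' @export
generateContactFixture <- function(n_frames = 400L, frame_interval = 50,
                                   mean_on = c(NC3 = 300, PO4 = 300,
                                               C1A = 600, C1B = 200),
                                   groove_factor = c(minor = 0.7, major = 1.0),
                                   mean_off = 400, n_repeats = 6L,
                                   seed = 1L) {
  with_seed(seed, {
    role_of <- function(nm) switch(substr(nm, 1, 3),
      NC3 = "LIPID_NC3", PO4 = "LIPID_PO4",
      C1A = "LIPID_TAIL_SN2", D2A = "LIPID_TAIL_SN2",
      C1B = "LIPID_TAIL_SN1", "OTHER")
    grooves <- names(groove_factor)
    # DNA anchor beads, one per groove, far apart
    dna_pos <- cbind(c(0, 6), 0, 0)
    dna_top <- data.frame(
      role = "DNA_BB", molecule_id = 1L, helix_id = 0L, strand_id = 0L,
      residue_index = 1:2, bead_radius = 0.26, tail_position = NA_integer_,
      name = "BBA", resname = "DNT0", groove = grooves,
      stringsAsFactors = FALSE)
    combos <- expand.grid(bead = names(mean_on), groove = grooves,
                          rep = seq_len(n_repeats), stringsAsFactors = FALSE)
    n_lip <- nrow(combos)
    lip_top <- data.frame(
      role = vapply(combos$bead, role_of, character(1)),
      molecule_id = 1L + seq_len(n_lip),
      helix_id = NA_integer_, strand_id = NA_integer_,
      residue_index = seq_len(n_lip), bead_radius = 0.26,
      tail_position = ifelse(grepl("^C1", combos$bead), 1L, NA_integer_),
      name = combos$bead, resname = "POPC", groove = NA_character_,
      stringsAsFactors = FALSE)
    top <- rbind(dna_top, lip_top)
    top <- cbind(particle_id = seq_len(nrow(top)), top)
    rownames(top) <- NULL
    topo <- new("ParticleTopology", particles = top)

    span <- n_frames * frame_interval
    contact <- matrix(FALSE, n_lip, n_frames)
    true_mean <- numeric(n_lip)
    for (i in seq_len(n_lip)) {
      mu <- mean_on[[combos$bead[i]]] * groove_factor[[combos$groove[i]]]
      true_mean[i] <- mu
      t0 <- stats::rexp(1, 1 / mean_off)
      on <- FALSE
      state <- logical(n_frames)
      tt <- t0
      while (tt < span) {
        dur <- stats::rexp(1, 1 / (if (on) mean_off else mu))
        on <- !on
        idx <- which((seq_len(n_frames) - 1) * frame_interval >= tt &
                       (seq_len(n_frames) - 1) * frame_interval < tt + dur)
        state[idx] <- on
        tt <- tt + dur
      }
      contact[i, ] <- state
    }
    anchor <- ifelse(combos$groove == grooves[1], 1L, 2L)
    coords <- array(0, c(nrow(top), 3, n_frames))
    for (f in seq_len(n_frames)) {
      pos <- matrix(0, nrow(top), 3)
      pos[1:2, ] <- dna_pos
      lp <- cbind(dna_pos[anchor, 1], 0.3, 0)
      far <- cbind(dna_pos[anchor, 1], 3.0, 0)
      onf <- contact[, f]
      pos[-(1:2), ] <- ifelse(matrix(onf, n_lip, 3), lp, far)
      coords[, , f] <- pos
    }
    traj <- new("Trajectory", topology = topo, coords = coords,
                times = (seq_len(n_frames) - 1) * frame_interval,
                box = matrix(c(50, 50, 50), n_frames, 3, byrow = TRUE))
    list(trajectory = traj,
         ground_truth = list(combos = combos, mean_on = mean_on,
                             groove_factor = groove_factor,
                             true_mean = true_mean, mean_off = mean_off))
  })
}
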