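#' @include AllClasses.R
NULL

#' Build an idealized six-duplex DNA nanotube scaffold
#'
#' Places `n_helices` parallel B-DNA duplexes on a regular hexagonal grid of
#' side `spacing_d` (hexagon side equals circumradius, so for six helices the
#' centre-to-axis distance also equals `spacing_d`). Each duplex carries two
#' backbone strands as one pseudo-particle per nucleotide on ideal helical
#' paths (default rise 0.34 nm/bp, twist 34.3 deg/bp, strand phase offset
#' 144 deg). Helix starting phases advance by 60 deg per helix so the n = 6
#' model maps onto itself under a 60 deg rotation about the tube axis.
#'
#' With the default spacing of 2.0 nm and the canonical B-DNA duplex radius
#' of 1.0 nm adjacent duplex surfaces touch (surface gap 0); the builder
#' warns if parameters imply overlapping duplexes.
#'
#' @param n_helices number of duplexes, 1..6
#' @param spacing_d inter-helix hexagon side, nm
#' @param helix_radius backbone helix radius (canonical B-DNA: 1.0 nm)
#' @param length_bp base pairs per duplex
#' @param rise_per_bp nm per bp
#' @param twist_per_bp degrees per bp
#' @param strand_offset_deg backbone strand phase offset, degrees
#' @return a [DNTModel-class]
#' @export
buildHexagonalScaffold <- function(n_helices = 6L, spacing_d = 2.0,
                                   helix_radius = 1.0, length_bp = 42L,
                                   rise_per_bp = 0.34, twist_per_bp = 34.3,
                                   strand_offset_deg = 144) {
  n_helices <- as.integer(n_helices)
  if (n_helices < 1L || n_helices > 6L) stopf("n_helices must be in 1..6")
  for (v in c(spacing_d, helix_radius, length_bp, rise_per_bp, twist_per_bp))
    if (!is.finite(v) || v <= 0) stopf("geometry parameters must be positive")
  length_bp <- as.integer(length_bp)

  if (n_helices == 1L) {
    ax_xy <- matrix(0, 1, 2)
  } else {
    ang <- (seq_len(n_helices) - 1L) * 60 * pi / 180
    ax_xy <- cbind(spacing_d * cos(ang), spacing_d * sin(ang))
  }
  helix_axes <- data.frame(helix_id = seq_len(n_helices) - 1L,
                           x = ax_xy[, 1], y = ax_xy[, 2], z = 0,
                           dx = 0, dy = 0, dz = 1)

  bp <- seq_len(length_bp) - 1L
  z <- (bp - (length_bp - 1) / 2) * rise_per_bp
  res <- do.call(rbind, lapply(seq_len(n_helices) - 1L, function(h) {
    phase0 <- 60 * h
    do.call(rbind, lapply(0:1, function(s) {
      phase <- (phase0 + bp * twist_per_bp + s * strand_offset_deg) %% 360
      data.frame(helix_id = h, strand_id = s, bp = bp,
                 x = ax_xy[h + 1L, 1] + helix_radius * cos(phase * pi / 180),
                 y = ax_xy[h + 1L, 2] + helix_radius * sin(phase * pi / 180),
                 z = z, phase = phase,
                 groove = NA_character_, band = NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(res) <- NULL

  gap <- spacing_d - 2 * helix_radius
  if (n_helices > 1L && gap < -1e-9)
    warning(sprintf("adjacent duplex surfaces overlap by %g nm", -gap))

  new("DNTModel", n_helices = n_helices, spacing_d = spacing_d,
      helix_radius = helix_radius, length_bp = length_bp,
      rise_per_bp = rise_per_bp, twist_per_bp = twist_per_bp,
      strand_offset_deg = strand_offset_deg,
      helix_axes = helix_axes, residues = res)
}

#' Adjacent-duplex surface gap (nm)
#'
#' `spacing_d - 2 * helix_radius`; zero for touching duplexes.
#' @param model a [DNTModel-class]
#' @return gap in nm
#' @export
duplexSurfaceGap <- function(model) model@spacing_d - 2 * model@helix_radius

.known_band_layouts <- c("7-band", "6-band", "1-ring", "2-adjacent",
                         "2-distal", "full-coverage")

#' Place hydrophobic band rings on a DNT model
#'
#' A band is one axial ring: every backbone residue at a given bp level. The
#' named layouts place contiguous rings centred at tube mid-height (the
#' membrane-core position), except `"2-distal"`, which splits two rings
#' symmetrically about mid-height, and `"full-coverage"`, which flags every
#' bp level. An explicit integer vector of bp levels (0-based) may be given
#' instead of a layout name; an empty vector leaves the model unchanged.
#'
#' @param model a [DNTModel-class]
#' @param band_spec layout name (one of `r paste(DNTPore:::.known_band_layouts, collapse=", ")`)
#'   or integer vector of bp levels
#' @param distal_gap_bp gap between the two rings of the `"2-distal"` layout
#' @return the model with `band` membership set (band index per ring)
#' @export
placeHydrophobicBands <- function(model, band_spec = "7-band",
                                  distal_gap_bp = 10L) {
  L <- model@length_bp
  mid <- (L - 1L) %/% 2L
  if (is.character(band_spec)) {
    if (!band_spec %in% .known_band_layouts)
      stopf("unknown band layout '%s'; known layouts: %s", band_spec,
            paste(.known_band_layouts, collapse = ", "))
    levels_bp <- switch(band_spec,
      "7-band" = mid + (-3:3),
      "6-band" = mid + (-2:3),
      "1-ring" = mid,
      "2-adjacent" = mid + 0:1,
      "2-distal" = mid + c(-(distal_gap_bp %/% 2 + 1), distal_gap_bp %/% 2 + 1),
      "full-coverage" = 0:(L - 1L))
  } else {
    levels_bp <- as.integer(band_spec)
    if (length(levels_bp) == 0L) return(model)
  }
  if (any(levels_bp < 0L | levels_bp >= L))
    stopf("band bp levels outside model (0..%d)", L - 1L)
  res <- model@residues
  res$band <- NA_integer_
  for (i in seq_along(levels_bp))
    res$band[res$bp == levels_bp[i]] <- i
  model@residues <- res
  validObject(model)
  model
}

#' Axial extent of the hydrophobic band (nm)
#' @param model a [DNTModel-class] with bands placed
#' @return numeric length-2 z range, or NULL if no band
#' @export
bandZExtent <- function(model) {
  z <- model@residues$z[!is.na(model@residues$band)]
  if (!length(z)) return(NULL)
  range(z)
}

#' Build an elastic-network specification for a DNT model
#'
#' Harmonic bonds between all backbone residue pairs within `cutoff` inside
#' each duplex, plus inter-helix "junction" bonds between nearest residues of
#' adjacent helices at the bp levels in `junction_bp`. Rest lengths equal the
#' build-time distances exactly. Soft mode assigns a force constant of
#' 100 kJ mol^-1 nm^-2 to every bond; stiff mode uses `k_stiff`.
#'
#' @param model a [DNTModel-class]
#' @param stiffness_mode `"stiff"` or `"soft"`
#' @param cutoff bond distance cutoff, nm
#' @param k_stiff stiff-mode force constant, kJ mol^-1 nm^-2
#' @param junction_bp bp levels at which adjacent helices are cross-linked
#' @return an [ENMSpec-class]
#' @export
buildENM <- function(model, stiffness_mode = c("stiff", "soft"), cutoff = 1.0,
                     k_stiff = 500, junction_bp = integer()) {
  stiffness_mode <- match.arg(stiffness_mode)
  if (cutoff <= 0) stopf("cutoff must be > 0")
  k <- if (stiffness_mode == "soft") 100 else k_stiff
  res <- model@residues
  pos <- as.matrix(res[, c("x", "y", "z")])
  bonds <- list()
  for (h in unique(res$helix_id)) {
    idx <- which(res$helix_id == h)
    if (length(idx) < 2L) next
    d <- as.matrix(stats::dist(pos[idx, , drop = FALSE]))
    pair <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (nrow(pair))
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = idx[pair[, 1]], j = idx[pair[, 2]],
        rest_length = d[pair], k = k, junction = FALSE)
  }
  # junction bonds: closest residue pair between hexagon-adjacent helices at
  # the flagged bp levels
  if (length(junction_bp) && model@n_helices > 1L) {
    ax <- as.matrix(model@helix_axes[, c("x", "y")])
    for (bpl in junction_bp) {
      for (h1 in seq_len(model@n_helices) - 1L) {
        for (h2 in seq_len(model@n_helices) - 1L) {
          if (h2 <= h1) next
          dax <- sqrt(sum((ax[h1 + 1, ] - ax[h2 + 1, ])^2))
          if (abs(dax - model@spacing_d) > 1e-6) next
          i1 <- which(res$helix_id == h1 & res$bp == bpl)
          i2 <- which(res$helix_id == h2 & res$bp == bpl)
          if (!length(i1) || !length(i2)) next
          dd <- sqrt(outer(pos[i1, 1], pos[i2, 1], "-")^2 +
                       outer(pos[i1, 2], pos[i2, 2], "-")^2 +
                       outer(pos[i1, 3], pos[i2, 3], "-")^2)
          w <- which(dd == min(dd), arr.ind = TRUE)[1, ]
          bonds[[length(bonds) + 1L]] <- data.frame(
            i = i1[w[1]], j = i2[w[2]], rest_length = min(dd), k = k,
            junction = TRUE)
        }
      }
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(), j = integer(), rest_length = numeric(),
               k = numeric(), junction = logical())
  rownames(bonds) <- NULL
  new("ENMSpec", bonds = bonds, stiffness_mode = stiffness_mode)
}

#' Convert a DNT model to a particle topology and frame
#'
#' Backbone residues become `DNA_BB` particles (or `ETHYL` where a
#' hydrophobic band is placed), with helix and strand ids filled in and the
#' package-native naming (resname `DNT<h>`, atoms `BBA`/`BBB`/`ETA`/`ETB`)
#' so a written structure reads back with identical roles.
#'
#' @param model a [DNTModel-class]
#' @param box box lengths, nm
#' @param bead_radius bead radius for pore profiling, nm
#' @return list(`topology`, `frame`)
#' @export
modelToTopology <- function(model, box = c(18, 18, 25), bead_radius = 0.26) {
  res <- model@residues
  n <- nrow(res)
  role <- ifelse(is.na(res$band), "DNA_BB", "ETHYL")
  base <- ifelse(is.na(res$band), "BB", "ET")
  nm <- paste0(base, ifelse(res$strand_id == 0L, "A", "B"))
  df <- data.frame(
    particle_id = seq_len(n), role = role,
    molecule_id = res$helix_id + 1L,
    helix_id = res$helix_id, strand_id = res$strand_id,
    residue_index = res$bp + 1L,
    bead_radius = bead_radius, tail_position = NA_integer_,
    name = nm, resname = paste0("DNT", res$helix_id),
    groove = res$groove, stringsAsFactors = FALSE)
  topo <- new("ParticleTopology", particles = df)
  pos <- as.matrix(res[, c("x", "y", "z")])
  pos[, 1] <- pos[, 1] + box[1] / 2
  pos[, 2] <- pos[, 2] + box[2] / 2
  pos[, 3] <- pos[, 3] + box[3] / 2
  list(topology = topo,
       frame = list(time = 0, box = box, positions = unname(pos)))
}

#' Represent the duplexes as smooth cylinders for pore profiling
#'
#' Samples each helix axis every `dz` nm and assigns each sample bead a
#' radius equal to the duplex cylinder radius, so the largest-inscribed-
#' sphere profiler sees six smooth touching cylinders instead of discrete
#' backbone beads. This is the idealized geometry for which the profile has
#' a closed form (centred sphere of radius `spacing_d - helix_radius`).
#'
#' @param model a [DNTModel-class]
#' @param dz axial sampling interval, nm
#' @param box box lengths, nm (tube centred in the box)
#' @return list(`topology`, `frame`)
#' @export
modelAsCylinders <- function(model, dz = 0.05, box = c(18, 18, 25)) {
  zs <- seq(-(model@length_bp - 1) / 2 * model@rise_per_bp,
            (model@length_bp - 1) / 2 * model@rise_per_bp, by = dz)
  ax <- model@helix_axes
  pos <- do.call(rbind, lapply(seq_len(nrow(ax)), function(i)
    cbind(ax$x[i], ax$y[i], zs)))
  hid <- rep(ax$helix_id, each = length(zs))
  n <- nrow(pos)
  df <- data.frame(
    particle_id = seq_len(n), role = "DNA_BB", molecule_id = hid + 1L,
    helix_id = hid, strand_id = 0L, residue_index = rep(seq_along(zs), nrow(ax)),
    bead_radius = model@helix_radius, tail_position = NA_integer_,
    name = "CYL", resname = paste0("DNT", hid), groove = NA_character_,
    stringsAsFactors = FALSE)
  pos[, 1] <- pos[, 1] + box[1] / 2
  pos[, 2] <- pos[, 2] + box[2] / 2
  pos[, 3] <- pos[, 3] + box[3] / 2
  list(topology = new("ParticleTopology", particles = df),
       frame = list(time = 0, box = box, positions = unname(pos)))
}

#' Assign contact points to DNA grooves by helical phase
#'
#' For each query point: find the nearest helix axis, compute the point's
#' angular phase about that axis, and compare it with the local reference
#' (strand 0) phase at the point's z. Points whose phase lies within
#' `half_window` degrees of the minor-groove bisector (reference phase +
#' half the strand offset) are labelled `"minor"`, the remainder `"major"`.
#' This phase-window rule is the package's declared convention.
#'
#' @param model a [DNTModel-class]
#' @param points m x 3 matrix of positions in the model's frame (tube centred
#'   at the origin, axis along z)
#' @param half_window window half-width about the minor bisector, degrees
#' @return character vector `"minor"`/`"major"`
#' @export
grooveAssignment <- function(model, points, half_window = 60) {
  points <- matrix(points, ncol = 3)
  ax <- as.matrix(model@helix_axes[, c("x", "y")])
  d2 <- outer(points[, 1], ax[, 1], "-")^2 + outer(points[, 2], ax[, 2], "-")^2
  nearest <- max.col(-d2)
  phase <- atan2(points[, 2] - ax[nearest, 2],
                 points[, 1] - ax[nearest, 1]) * 180 / pi
  phase0 <- 60 * model@helix_axes$helix_id[nearest] +
    (points[, 3] / model@rise_per_bp + (model@length_bp - 1) / 2) *
      model@twist_per_bp
  bisector <- phase0 + model@strand_offset_deg / 2
  delta <- (phase - bisector + 180) %% 360 - 180
  ifelse(abs(delta) <= half_window, "minor", "major")
}
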