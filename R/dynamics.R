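#' @include membrane_profiles.R
NULL

#' Lipid/DNA contact residence times per bead type and groove
#'
#' A contact event is a maximal run of frames in which a lipid bead's
#' minimum-image distance to any selected DNA particle is at most `cutoff`;
#' runs separated by gaps of at most `gap_tolerance` frames are merged.
#' Events are labelled minor/major groove: geometrically through a
#' [DNTModel-class]'s phase windows when `model` is given (the lipid bead's
#' angular position about the contacted duplex), otherwise by the `groove`
#' label of the nearest DNA particle at the event's first frame. Mean
#' residence times are reported per (bead name, groove) over perturbed
#' lipids, i.e. beads with at least one contact event.
#'
#' @param traj a [Trajectory-class] (apply [analysisWindow()] first)
#' @param lipid_roles lipid roles to analyse
#' @param dna_selection DNA particle indices (default: all DNT roles)
#' @param cutoff contact distance, nm (default 0.5)
#' @param gap_tolerance frames; gaps up to this length are merged
#' @param model optional [DNTModel-class] for geometric groove assignment
#'   (positions must then be in the model frame: tube centred, axis along z)
#' @return data.frame (`bead`, `groove`, `mean_residence_ps`, `events`,
#'   `total_contact_frames`)
#' @export
residenceTimes <- function(traj, lipid_roles = .lipid_roles,
                           dna_selection = NULL, cutoff = 0.5,
                           gap_tolerance = 0L, model = NULL) {
  topo <- topology(traj)
  p <- particleData(topo)
  lip <- selectParticles(topo, role = lipid_roles)
  if (is.null(dna_selection))
    dna_selection <- selectParticles(topo, role = c("DNA_BB", "DNA_BASE", "ETHYL"))
  if (!length(lip) || !length(dna_selection))
    stopf("empty lipid or DNA selection")
  nf <- nFrames(traj)
  dt <- frameInterval(traj)
  if (is.na(dt)) dt <- 1
  contact <- matrix(FALSE, length(lip), nf)
  nearest <- matrix(NA_integer_, length(lip), nf)
  for (f in seq_len(nf)) {
    fr <- getFrame(traj, f)
    d <- min_image_dist(fr$positions[lip, , drop = FALSE],
                        fr$positions[dna_selection, , drop = FALSE], fr$box)
    j <- max.col(-d)
    dmin <- d[cbind(seq_along(lip), j)]
    contact[, f] <- dmin <= cutoff
    nearest[, f] <- dna_selection[j]
  }
  rows <- list()
  for (i in seq_along(lip)) {
    st <- contact[i, ]
    if (!any(st)) next
    r <- rle(st)
    # merge interior FALSE gaps <= gap_tolerance
    if (gap_tolerance > 0L && length(r$lengths) > 2L) {
      vals <- r$values; lens <- r$lengths
      interior <- which(!vals & lens <= gap_tolerance &
                          seq_along(vals) > 1L & seq_along(vals) < length(vals))
      vals[interior] <- TRUE
      r <- rle(inverse.rle(list(lengths = lens, values = vals)))
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- which(r$values)
    for (e in ev) {
      f0 <- starts[e]
      dur <- r$lengths[e] * dt
      gr <- NA_character_
      if (!is.null(model)) {
        gr <- grooveAssignment(model, traj@coords[lip[i], , f0, drop = FALSE])
      } else {
        gr <- p$groove[nearest[i, f0]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        bead = p$name[lip[i]], groove = gr, duration = dur,
        frames = r$lengths[e], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(bead = character(), groove = character(),
                      mean_residence_ps = numeric(), events = integer(),
                      total_contact_frames = integer()))
  ev <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(duration, frames) ~ bead + groove, data = ev,
                          FUN = function(x) c(m = mean(x), s = sum(x)),
                          na.action = stats::na.pass)
  out <- data.frame(bead = agg$bead, groove = agg$groove,
                    mean_residence_ps = agg$duration[, "m"],
                    events = as.integer(
                      stats::aggregate(duration ~ bead + groove, data = ev,
                                       FUN = length,
                                       na.action = stats::na.pass)$duration),
                    total_contact_frames = as.integer(agg$frames[, "s"]))
  out[order(out$bead, out$groove), , drop = FALSE]
}

#' Tilt-angle series of the DNT long axis
#'
#' Per-frame acute angle between the pore axis (see [poreAxis()]) and the
#' bilayer normal (z), with a histogram over stated bins.
#'
#' @param traj a [Trajectory-class]
#' @param tm_region z-range for the axis fit (NULL: all DNT particles)
#' @param breaks histogram breaks, degrees
#' @return list(`angles` degrees per frame, `histogram` data.frame)
#' @export
tiltSeries <- function(traj, tm_region = NULL, breaks = seq(0, 90, by = 2)) {
  nf <- nFrames(traj)
  ang <- vapply(seq_len(nf), function(f) {
    fr <- getFrame(traj, f)
    ax <- poreAxis(fr$positions, topology(traj), tm_region)
    acos(pmin(abs(ax$dir[3]), 1)) * 180 / pi
  }, numeric(1))
  h <- graphics::hist(ang, breaks = breaks, plot = FALSE)
  list(angles = ang,
       histogram = data.frame(angle_lo = utils::head(h$breaks, -1),
                              angle_hi = h$breaks[-1], count = h$counts))
}

#' Classify a COM displacement trace
#'
#' `relaxed`: the trace enters the tolerance band `|dz| <= tol_rel` and stays
#' inside it to the end; the relaxation time is the first frame of that
#' longest terminal in-band run. `exited`: `|dz|` reaches `exit_threshold`
#' and never re-enters the tolerance band afterwards. Otherwise `undecided`.
#'
#' @param time ps
#' @param dz nm
#' @param tol_rel tolerance band, nm (default 0.3)
#' @param exit_threshold nm (default 4.0: bilayer half-thickness + band
#'   half-extent + 1 nm)
#' @return list(`classification`, `relaxation_time_ns` (NA unless relaxed))
#' @export
classifyDisplacement <- function(time, dz, tol_rel = 0.3, exit_threshold = 4.0) {
  stopifnot(length(time) == length(dz), length(time) > 0)
  inband <- abs(dz) <= tol_rel
  n <- length(dz)
  cls <- "undecided"; rt <- NA_real_
  if (inband[n]) {
    k <- n
    while (k > 1L && inband[k - 1L]) k <- k - 1L
    cls <- "relaxed"
    rt <- time[k] / 1000
  } else {
    over <- which(abs(dz) >= exit_threshold)
    if (length(over) && !any(inband[over[1]:n])) cls <- "exited"
  }
  list(classification = cls, relaxation_time_ns = rt)
}

#' COM displacement of a group relative to the bilayer
#'
#' `dz(t)` is the z distance between the COM of `group` (default the
#' hydrophobic-band ETHYL particles) and the COM of the lipid phosphates,
#' classified with [classifyDisplacement()].
#'
#' @param traj a [Trajectory-class]
#' @param group particle indices (default: ETHYL band)
#' @param tol_rel,exit_threshold see [classifyDisplacement()]
#' @return data.frame (`time` ps, `dz` nm) with attributes `classification`
#'   and `relaxation_time_ns`
#' @export
comDisplacement <- function(traj, group = NULL, tol_rel = 0.3,
                            exit_threshold = 4.0) {
  topo <- topology(traj)
  if (is.null(group)) group <- selectParticles(topo, role = "ETHYL")
  if (!length(group)) stopf("empty group selection")
  po4 <- selectParticles(topo, role = "LIPID_PO4")
  if (!length(po4)) stopf("no lipid phosphates to define the bilayer COM")
  nf <- nFrames(traj)
  dz <- vapply(seq_len(nf), function(f)
    mean(traj@coords[group, 3, f]) - mean(traj@coords[po4, 3, f]), numeric(1))
  out <- data.frame(time = frameTimes(traj), dz = dz)
  cl <- classifyDisplacement(out$time, out$dz, tol_rel, exit_threshold)
  attr(out, "classification") <- cl$classification
  attr(out, "relaxation_time_ns") <- cl$relaxation_time_ns
  out
}

# Gaussian-peak refinement around index i0 of a force trace; returns the
# fitted peak height (A + baseline), falling back to `fallback` on failure
.fit_peak <- function(time, force, i0, window_ps, fallback) {
  sel <- which(abs(time - time[i0]) <= window_ps)
  if (length(sel) < 10L) return(fallback)
  d <- data.frame(t = time[sel] - time[i0], f = force[sel])
  base <- unname(stats::quantile(d$f, 0.05))
  amp <- max(d$f) - base
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ c0 + A * exp(-(t - t0)^2 / (2 * s^2)), data = d,
                      start = list(c0 = base, A = amp, t0 = 0,
                                   s = window_ps / 2),
                      lower = c(-Inf, 0, -window_ps, window_ps / 50),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  co <- stats::coef(fit)
  # the fitted centre must lie inside the window for the height to be a peak
  if (abs(co[["t0"]]) > window_ps) return(fallback)
  co[["c0"]] + co[["A"]]
}

#' Extract entry and exit force barriers from an SMD trace
#'
#' The force trace is smoothed with a centred running mean of width
#' `smooth_ns`; the entry barrier is located where the smoothed force is
#' maximal while the pulled COM is on the entry side of the bilayer
#' (`com_z <= bilayer_z[1]`), the exit barrier likewise after the
#' transmembrane plateau (`com_z >= bilayer_z[2]`). With `method = "fit"`
#' (default) the barrier height is refined by a local Gaussian fit to the
#' raw force around the located peak, which is unbiased under noise and
#' exact on noiseless traces; `method = "max"` reports the smoothed maximum
#' directly.
#'
#' @param trace a [ForceTrace-class] spanning entry and exit
#' @param bilayer_z length-2 bilayer boundaries on the COM-z coordinate, nm
#' @param smooth_ns running-mean width, ns
#' @param method `"fit"` or `"max"`
#' @param fit_window_ns half-width of the Gaussian-fit window, ns
#' @return list(`entry_barrier`, `exit_barrier` (kJ mol^-1 nm^-1),
#'   `entry_z`, `exit_z` (nm), `entry_time`, `exit_time` (ps))
#' @export
smdBarriers <- function(trace, bilayer_z = c(-2, 2), smooth_ns = 5,
                        method = c("fit", "max"), fit_window_ns = 50) {
  method <- match.arg(method)
  stopifnot(is(trace, "ForceTrace"))
  z <- trace@com_z
  if (min(z) > bilayer_z[1] || max(z) < bilayer_z[2])
    stopf("trace does not span the bilayer (com_z %g..%g, bilayer %g..%g)",
          min(z), max(z), bilayer_z[1], bilayer_z[2])
  dt <- trace@time[2] - trace@time[1]
  w <- max(1L, round(smooth_ns * 1000 / dt))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- running_mean(trace@force, w)
  pick <- function(win) {
    if (!any(win)) return(list(value = NA_real_, i = NA_integer_))
    i <- which(win)[which.max(sm[win])]
    val <- sm[i]
    if (method == "fit")
      val <- .fit_peak(trace@time, trace@force, i, fit_window_ns * 1000, val)
    list(value = max(val, 0), i = i)
  }
  entry <- pick(z <= bilayer_z[1])
  exitp <- pick(z >= bilayer_z[2])
  list(entry_barrier = entry$value, exit_barrier = exitp$value,
       entry_z = if (is.na(entry$i)) NA_real_ else z[entry$i],
       exit_z = if (is.na(exitp$i)) NA_real_ else z[exitp$i],
       entry_time = if (is.na(entry$i)) NA_real_ else trace@time[entry$i],
       exit_time = if (is.na(exitp$i)) NA_real_ else trace@time[exitp$i])
}

# 1 kJ mol^-1 nm^-1 = 1e3 J / (N_A * 1e-9 m) = 1.66053906717e-12 N
.kj_mol_nm_to_pN <- 1e3 / (6.02214076e23 * 1e-9) * 1e12

#' Convert a molar force to piconewtons
#'
#' `f` kJ mol^-1 nm^-1 corresponds to a single-molecule force of
#' `f * 1.66054` pN (1000 J per mole per nm, divided by Avogadro's number).
#'
#' @param f force in kJ mol^-1 nm^-1
#' @return force in pN
#' @export
forceToPiconewtons <- function(f) f * .kj_mol_nm_to_pN

#' @rdname forceToPiconewtons
#' @param pN force in pN
#' @export
piconewtonsToForce <- function(pN) pN / .kj_mol_nm_to_pN

#' r.m.s.d. partitioned into transmembrane and outside regions
#'
#' Each frame is least-squares superposed onto the reference using all DNA
#' particles (one common fit, not per-partition fits); the r.m.s.d. is then
#' reported separately for particles whose reference z lies inside
#' `tm_region` and for the remainder.
#'
#' @param traj a [Trajectory-class]
#' @param reference reference frame (list as from [getFrame()]), or a frame
#'   index into `traj`
#' @param tm_region length-2 z-range (reference coordinates) delimiting the
#'   transmembrane partition
#' @param fit_roles roles used for superposition and reporting
#' @return data.frame (`time`, `rmsd_tm`, `rmsd_outside`) in nm
#' @export
rmsdPartitioned <- function(traj, reference = 1L, tm_region,
                            fit_roles = c("DNA_BB", "DNA_BASE", "ETHYL")) {
  topo <- topology(traj)
  sel <- selectParticles(topo, role = fit_roles)
  if (length(sel) < 3L) stopf("need >= 3 particles for superposition")
  ref_pos <- if (is.list(reference)) reference$positions else
    getFrame(traj, reference)$positions
  refz <- ref_pos[sel, 3]
  tm <- refz >= tm_region[1] & refz <= tm_region[2]
  if (!any(tm) || all(tm))
    stopf("partition empty: tm_region must split the selection")
  fixed <- as.vector(t(ref_pos[sel, , drop = FALSE]))
  nf <- nFrames(traj)
  mobile <- matrix(0, nf, length(fixed))
  for (f in seq_len(nf))
    mobile[f, ] <- as.vector(t(traj@coords[sel, , f]))
  fitted <- bio3d::fit.xyz(fixed, mobile, fixed.inds = seq_along(fixed),
                           mobile.inds = seq_along(fixed))
  sq <- (fitted - matrix(fixed, nf, length(fixed), byrow = TRUE))^2
  # per-particle squared deviation = sum over x,y,z
  pp <- sq[, seq(1, ncol(sq), by = 3), drop = FALSE] +
    sq[, seq(2, ncol(sq), by = 3), drop = FALSE] +
    sq[, seq(3, ncol(sq), by = 3), drop = FALSE]
  data.frame(time = frameTimes(traj),
             rmsd_tm = sqrt(rowMeans(pp[, tm, drop = FALSE])),
             rmsd_outside = sqrt(rowMeans(pp[, !tm, drop = FALSE])))
}

#' Membrane surface deformation track (xz projection)
#'
#' Per frame (optionally strided to every `sample_every_ns`), lipid
#' particles are binned along x and the COM z per leaflet per bin is
#' reported — the xz-projected membrane surface curve. Empty bins are
#' flagged with `n = 0` and `z = NA`.
#'
#' @param traj a [Trajectory-class]
#' @param lateral_bin bin width along x, nm
#' @param sample_every_ns stride; NULL analyses every frame
#' @param lipid_roles roles forming the surface
#' @return data.frame (`time` ps, `x_mid`, `leaflet`, `z`, `n`)
#' @export
membraneDeformationTrack <- function(traj, lateral_bin = 0.5,
                                     sample_every_ns = NULL,
                                     lipid_roles = .lipid_roles) {
  topo <- topology(traj)
  lip <- selectParticles(topo, role = lipid_roles)
  if (!length(lip)) stopf("no lipid particles present")
  frames <- seq_len(nFrames(traj))
  if (!is.null(sample_every_ns)) {
    dt <- frameInterval(traj)
    stride <- max(1L, round(sample_every_ns * 1000 / dt))
    frames <- frames[seq(1, length(frames), by = stride)]
  }
  box <- traj@box[1, ]
  edges <- seq(0, box[1], by = lateral_bin)
  if (edges[length(edges)] < box[1]) edges <- c(edges, box[1])
  nb <- length(edges) - 1L
  out <- list()
  for (f in frames) {
    pos <- traj@coords[lip, , f]
    mid <- stats::median(pos[, 3])
    xb <- findInterval(pos[, 1] %% box[1], edges, rightmost.closed = TRUE)
    for (leaf in c("upper", "lower")) {
      inleaf <- if (leaf == "upper") pos[, 3] >= mid else pos[, 3] < mid
      zm <- rep(NA_real_, nb); n <- integer(nb)
      for (b in unique(xb[inleaf])) {
        v <- pos[inleaf & xb == b, 3]
        zm[b] <- mean(v); n[b] <- length(v)
      }
      out[[length(out) + 1L]] <- data.frame(
        time = traj@times[f],
        x_mid = (edges[-1] + edges[-length(edges)]) / 2,
        leaflet = leaf, z = zm, n = n)
    }
  }
  do.call(rbind, out)
}
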