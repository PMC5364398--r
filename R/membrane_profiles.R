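#' @include selection.R
NULL

#' Bilayer midplane z (nm) of a frame
#'
#' Median z of the lipid phosphate (PO4) particles; the package's z = 0
#' reference for thickness and leaflet assignment, recomputed per frame.
#'
#' @param positions n x 3 coordinate matrix (nm)
#' @param topology a [ParticleTopology-class]
#' @return z in nm (NA when no PO4 particles)
#' @export
bilayerMidplane <- function(positions, topology) {
  idx <- selectParticles(topology, role = "LIPID_PO4")
  if (!length(idx)) return(NA_real_)
  stats::median(positions[idx, 3])
}

#' Pore axis of the transmembrane DNT domain
#'
#' The axis is the symmetry axis of the covariance (inertia) tensor of the
#' DNA particles inside the transmembrane z-range: the eigenvector whose
#' eigenvalue is best separated from the other two (for a squat tube section
#' the two lateral eigenvalues are nearly equal and the distinct one belongs
#' to the symmetry axis; for an elongated section the distinct eigenvalue is
#' the largest). The direction is anchored at the selection's centre of mass
#' and sign-aligned toward +z.
#'
#' @param positions n x 3 coordinate matrix (nm)
#' @param topology a [ParticleTopology-class]
#' @param tm_region length-2 z-range delimiting the transmembrane section;
#'   NULL uses all DNA particles
#' @return list(`point` = COM, `dir` = unit axis vector)
#' @export
poreAxis <- function(positions, topology, tm_region = NULL) {
  idx <- selectParticles(topology, role = c("DNA_BB", "DNA_BASE", "ETHYL"))
  idx <- idx[idx <= nrow(positions)]
  if (!is.null(tm_region))
    idx <- idx[positions[idx, 3] >= tm_region[1] & positions[idx, 3] <= tm_region[2]]
  if (length(idx) < 3L) stopf("pore axis needs >= 3 DNT particles in tm_region")
  P <- positions[idx, , drop = FALSE]
  ctr <- colMeans(P)
  C <- stats::cov(P)
  e <- eigen(C, symmetric = TRUE)
  l <- e$values
  if (l[3] < 1e-10 * max(l[1], 1e-300))
    stopf("degenerate (planar/collinear) particle set: no unique pore axis")
  axis <- if ((l[1] - l[2]) >= (l[2] - l[3])) e$vectors[, 1] else e$vectors[, 3]
  if (axis[3] < 0) axis <- -axis
  list(point = ctr, dir = axis / sqrt(sum(axis^2)))
}

# orthonormal basis (u, v, w) with w = dir
.axis_basis <- function(dir) {
  w <- dir / sqrt(sum(dir^2))
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}

# per-frame axis with fallback to +z through the box centre
.frame_axis <- function(pos, topo, tm_region, box) {
  ok <- length(selectParticles(topo, role = c("DNA_BB", "DNA_BASE", "ETHYL"))) >= 3L
  if (ok) {
    ax <- tryCatch(poreAxis(pos, topo, tm_region), error = function(e) NULL)
    if (!is.null(ax)) return(ax)
  }
  list(point = c(box[1] / 2, box[2] / 2, box[3] / 2), dir = c(0, 0, 1))
}

#' Radial number-density profile around the pore axis
#'
#' Counts particles of each requested role inside a cylinder of half-length
#' `cylinder_half_length` centred on the bilayer midplane along the pore
#' axis, in concentric shells of width `shell_width`, and averages number
#' densities over frames. Radial distance is measured perpendicular to the
#' per-frame pore axis with the minimum image applied. Shell volumes are
#' `pi (r2^2 - r1^2) L`.
#'
#' @param traj a [Trajectory-class] (apply [analysisWindow()] first)
#' @param roles roles to profile
#' @param shell_width nm
#' @param cylinder_half_length nm (default 2.0, a 4 nm cylinder approximating
#'   the membrane thickness)
#' @param r_max outer radius; default half the smaller lateral box length
#' @param tm_region z-range for the axis fit (NULL: all DNT particles)
#' @return data.frame (`r_lo`, `r_hi`, `r_mid`, one density column per role,
#'   nm^-3) with attributes `mean_count` (per role) and `frames_used`
#' @export
radialDensity <- function(traj, roles = c("DNA_BB", "ETHYL", "LIPID_PO4",
                                          "LIPID_TAIL_SN1", "LIPID_TAIL_SN2",
                                          "WATER", "ION_NA", "ION_CL"),
                          shell_width = 0.1, cylinder_half_length = 2.0,
                          r_max = NULL, tm_region = NULL) {
  nf <- nFrames(traj)
  if (nf == 0L) stopf("trajectory holds no frames")
  topo <- topology(traj)
  if (is.null(r_max)) r_max <- min(traj@box[1, 1:2]) / 2
  edges <- seq(0, r_max, by = shell_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- matrix(0, nb, length(roles), dimnames = list(NULL, roles))
  L <- 2 * cylinder_half_length
  sel <- lapply(roles, function(r) selectParticles(topo, role = r))
  for (f in seq_len(nf)) {
    fr <- getFrame(traj, f)
    ax <- .frame_axis(fr$positions, topo, tm_region, fr$box)
    mid <- bilayerMidplane(fr$positions, topo)
    if (is.na(mid)) mid <- ax$point[3]
    # anchor the cylinder centre on the axis at the midplane z
    lam <- if (abs(ax$dir[3]) > 1e-9) (mid - ax$point[3]) / ax$dir[3] else 0
    origin <- ax$point + lam * ax$dir
    B <- .axis_basis(ax$dir)
    for (k in seq_along(roles)) {
      idx <- sel[[k]]
      if (!length(idx)) next
      d <- sweep(fr$positions[idx, , drop = FALSE], 2, origin)
      for (j in 1:3) d[, j] <- min_image(d[, j], fr$box[j])
      rel <- d %*% B
      inside <- abs(rel[, 3]) <= cylinder_half_length
      if (!any(inside)) next
      r <- sqrt(rel[inside, 1]^2 + rel[inside, 2]^2)
      h <- findInterval(r, edges, rightmost.closed = TRUE)
      h <- h[h >= 1L & h <= nb]
      tb <- tabulate(h, nb)
      counts[, k] <- counts[, k] + tb
    }
  }
  vol <- pi * (edges[-1]^2 - edges[-length(edges)]^2) * L
  dens <- sweep(counts / nf, 1, vol, "/")
  out <- data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
                    r_mid = (edges[-1] + edges[-length(edges)]) / 2)
  for (k in seq_along(roles)) out[[roles[k]]] <- dens[, k]
  attr(out, "mean_count") <- colSums(counts) / nf
  attr(out, "frames_used") <- nf
  attr(out, "cylinder_half_length") <- cylinder_half_length
  out
}

#' Bilayer thickness versus radial distance from the pore axis
#'
#' Thickness is the headgroup phosphate-phosphate distance: per frame the
#' PO4 particles are split into leaflets by the bilayer midplane, and per
#' radial shell the thickness is mean(upper z) - mean(lower z). Shells where
#' either leaflet is empty in every frame are reported NA (flagged missing,
#' not zero).
#'
#' @inheritParams radialDensity
#' @return data.frame (`r_lo`, `r_hi`, `r_mid`, `thickness` nm, `n_upper`,
#'   `n_lower`)
#' @export
thicknessProfile <- function(traj, shell_width = 0.1, r_max = NULL,
                             tm_region = NULL) {
  nf <- nFrames(traj)
  if (nf == 0L) stopf("trajectory holds no frames")
  topo <- topology(traj)
  po4 <- selectParticles(topo, role = "LIPID_PO4")
  if (!length(po4)) stopf("no LIPID_PO4 particles: cannot measure thickness")
  if (is.null(r_max)) r_max <- min(traj@box[1, 1:2]) / 2
  edges <- seq(0, r_max, by = shell_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  sum_th <- numeric(nb); n_th <- integer(nb)
  n_up <- integer(nb); n_lo <- integer(nb)
  for (f in seq_len(nf)) {
    fr <- getFrame(traj, f)
    ax <- .frame_axis(fr$positions, topo, tm_region, fr$box)
    mid <- stats::median(fr$positions[po4, 3])
    d <- sweep(fr$positions[po4, , drop = FALSE], 2, ax$point)
    for (j in 1:2) d[, j] <- min_image(d[, j], fr$box[j])
    B <- .axis_basis(ax$dir)
    rel <- d %*% B
    r <- sqrt(rel[, 1]^2 + rel[, 2]^2)
    zz <- fr$positions[po4, 3]
    upper <- zz >= mid
    h <- findInterval(r, edges, rightmost.closed = TRUE)
    for (b in unique(h[h >= 1 & h <= nb])) {
      zu <- zz[h == b & upper]; zl <- zz[h == b & !upper]
      n_up[b] <- n_up[b] + length(zu); n_lo[b] <- n_lo[b] + length(zl)
      if (length(zu) && length(zl)) {
        sum_th[b] <- sum_th[b] + (mean(zu) - mean(zl))
        n_th[b] <- n_th[b] + 1L
      }
    }
  }
  thickness <- ifelse(n_th > 0, sum_th / n_th, NA_real_)
  data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
             r_mid = (edges[-1] + edges[-length(edges)]) / 2,
             thickness = thickness, n_upper = n_up, n_lower = n_lo)
}

#' Fit the exponential thinning model to a thickness profile
#'
#' Fits `h(r) = h0 - A exp(-(r - r_wall)/lambda)` to the per-shell thickness
#' for `r >= r_wall` by Levenberg-Marquardt least squares.
#'
#' @param profile output of [thicknessProfile()]
#' @param r_wall tube wall radius, nm
#' @return named vector `c(h0, A, lambda)`
#' @export
fitThinningProfile <- function(profile, r_wall) {
  d <- profile[!is.na(profile$thickness) & profile$r_mid >= r_wall, ]
  if (nrow(d) < 5L) stopf("too few occupied shells beyond r_wall to fit")
  h0_init <- max(d$thickness)
  A_init <- max(h0_init - min(d$thickness), 0.1)
  fit <- minpack.lm::nlsLM(
    thickness ~ h0 - A * exp(-(r_mid - r_wall) / lambda),
    data = cbind(d, r_wall = r_wall),
    start = list(h0 = h0_init, A = A_init, lambda = 1),
    lower = c(0, 0, 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  stats::coef(fit)[c("h0", "A", "lambda")]
}

#' Lipid order parameter on an xy grid
#'
#' `S = <(3 cos^2 theta - 1)/2>` over consecutive-tail-bead bond vectors
#' against the bilayer normal (z), accumulated per square xy cell. Bonds are
#' assigned to the cell of their lipid's PO4 xy position. Cells with fewer
#' than `min_samples` bond samples are reported NA (flagged missing, not
#' zero-filled).
#'
#' @param traj a [Trajectory-class]
#' @param grid_cell cell edge, nm (default 1 x 1 nm^2 cells)
#' @param min_samples minimum bond samples per reported cell
#' @return data.frame (`x_lo`, `y_lo`, `x_mid`, `y_mid`, `S`, `n`)
#' @export
orderParameterGrid <- function(traj, grid_cell = 1.0, min_samples = 10L) {
  topo <- topology(traj)
  p <- particleData(topo)
  tails <- which(p$role %in% c("LIPID_TAIL_SN1", "LIPID_TAIL_SN2") &
                   !is.na(p$tail_position))
  if (!length(tails)) stopf("no tail beads with tail_position present")
  po4 <- which(p$role == "LIPID_PO4")
  po4_of_mol <- stats::setNames(po4, p$molecule_id[po4])
  # bond list: consecutive tail_position within (molecule, chain role)
  key <- paste(p$molecule_id[tails], p$role[tails])
  ord <- tails[order(key, p$tail_position[tails])]
  k2 <- paste(p$molecule_id[ord], p$role[ord])
  consec <- k2[-length(k2)] == k2[-1] &
    diff(p$tail_position[ord]) == 1L
  bi <- ord[c(consec, FALSE)]
  bj <- ord[c(FALSE, consec)]
  if (!length(bi)) stopf("no consecutive tail-bead bonds found")
  mol <- p$molecule_id[bi]
  anchor <- po4_of_mol[as.character(mol)]   # may be NA for PO4-less fixtures
  box <- traj@box[1, ]
  nx <- max(1L, ceiling(box[1] / grid_cell))
  ny <- max(1L, ceiling(box[2] / grid_cell))
  sS <- matrix(0, nx, ny); nS <- matrix(0L, nx, ny)
  for (f in seq_len(nFrames(traj))) {
    pos <- traj@coords[, , f]
    v <- pos[bj, , drop = FALSE] - pos[bi, , drop = FALSE]
    c2 <- (v[, 3]^2) / rowSums(v^2)
    s_bond <- (3 * c2 - 1) / 2
    ref <- ifelse(is.na(anchor), bi, anchor)
    gx <- pmin(pmax(floor((pos[ref, 1] %% box[1]) / grid_cell), 0), nx - 1L) + 1L
    gy <- pmin(pmax(floor((pos[ref, 2] %% box[2]) / grid_cell), 0), ny - 1L) + 1L
    for (b in seq_along(s_bond)) {
      sS[gx[b], gy[b]] <- sS[gx[b], gy[b]] + s_bond[b]
      nS[gx[b], gy[b]] <- nS[gx[b], gy[b]] + 1L
    }
  }
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  S <- ifelse(nS[cbind(grid$ix, grid$iy)] >= min_samples,
              sS[cbind(grid$ix, grid$iy)] / nS[cbind(grid$ix, grid$iy)],
              NA_real_)
  data.frame(x_lo = (grid$ix - 1) * grid_cell, y_lo = (grid$iy - 1) * grid_cell,
             x_mid = (grid$ix - 0.5) * grid_cell,
             y_mid = (grid$iy - 0.5) * grid_cell,
             S = S, n = nS[cbind(grid$ix, grid$iy)])
}

#' Radial distribution function between two particle sets
#'
#' Standard minimum-image pair-distance histogram, normalized per frame by
#' the ideal-gas expectation `N_A * rho_B * 4 pi r^2 dr` at the box density
#' of set B. Self-pairs (identical particle indices) are excluded.
#'
#' @param traj a [Trajectory-class]
#' @param set_a,set_b particle index vectors (see [selectParticles()])
#' @param bin_width nm
#' @param r_max nm; default half the smallest box length
#' @return data.frame (`r_lo`, `r_hi`, `r_mid`, `g`) with attribute
#'   `rho_b` (nm^-3)
#' @export
rdfProfile <- function(traj, set_a, set_b, bin_width = 0.02, r_max = NULL) {
  if (!length(set_a) || !length(set_b)) stopf("rdf sets must be non-empty")
  box <- traj@box[1, ]
  if (is.null(r_max)) r_max <- min(box) / 2
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  V <- prod(box)
  rho_b <- length(set_b) / V
  for (f in seq_len(nFrames(traj))) {
    pos <- traj@coords[, , f]
    d <- min_image_dist(pos[set_a, , drop = FALSE],
                        pos[set_b, , drop = FALSE], traj@box[f, ])
    same <- outer(set_a, set_b, "==")
    d[same] <- NA
    h <- findInterval(d[!is.na(d) & d < r_max], edges, rightmost.closed = TRUE)
    counts <- counts + tabulate(h[h >= 1 & h <= nb], nb)
  }
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  expect <- nFrames(traj) * length(set_a) * rho_b * shell
  data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
             r_mid = (edges[-1] + edges[-length(edges)]) / 2,
             g = counts / expect) -> out
  attr(out, "rho_b") <- rho_b
  out
}

#' Lumen ion selectivity (Na+ : Cl- ratio)
#'
#' Time-averaged counts of Na+ and Cl- inside the lumen cylinder (centred on
#' the pore axis, default radius 1.0 nm, axial extent the DNT z-extent), and
#' their ratio with a binomial 95% confidence interval computed from the
#' mean per-frame counts. A zero anion count yields an infinite ratio with
#' the counts attached.
#'
#' @param traj a [Trajectory-class]
#' @param radius lumen cylinder radius, nm (the time-averaged minimum pore
#'   radius is the natural choice; 1.0 nm is the built tube's open radius)
#' @param half_length lumen half-length, nm; NULL uses the DNT axial extent
#' @param tm_region z-range for the axis fit
#' @return list(`ratio`, `ci` (95% on the ratio), `mean_na`, `mean_cl`)
#' @export
ionSelectivity <- function(traj, radius = 1.0, half_length = NULL,
                           tm_region = NULL) {
  topo <- topology(traj)
  na_i <- selectParticles(topo, role = "ION_NA")
  cl_i <- selectParticles(topo, role = "ION_CL")
  if (!length(na_i) && !length(cl_i)) stopf("no ions in trajectory")
  dnt <- selectParticles(topo, role = c("DNA_BB", "DNA_BASE", "ETHYL"))
  cnt_na <- cnt_cl <- numeric(nFrames(traj))
  for (f in seq_len(nFrames(traj))) {
    fr <- getFrame(traj, f)
    ax <- .frame_axis(fr$positions, topo, tm_region, fr$box)
    B <- .axis_basis(ax$dir)
    hl <- half_length
    if (is.null(hl)) {
      if (!length(dnt)) stopf("half_length required when no DNT present")
      relD <- sweep(fr$positions[dnt, , drop = FALSE], 2, ax$point) %*% B
      hl <- max(abs(relD[, 3]))
    }
    inside <- function(idx) {
      if (!length(idx)) return(0L)
      rel <- sweep(fr$positions[idx, , drop = FALSE], 2, ax$point) %*% B
      sum(rel[, 1]^2 + rel[, 2]^2 <= radius^2 & abs(rel[, 3]) <= hl)
    }
    cnt_na[f] <- inside(na_i)
    cnt_cl[f] <- inside(cl_i)
  }
  m_na <- mean(cnt_na); m_cl <- mean(cnt_cl)
  n_tot <- round(m_na + m_cl)
  ci <- c(NA_real_, NA_real_)
  if (n_tot > 0) {
    bt <- stats::binom.test(round(m_na), n_tot)
    ci <- bt$conf.int / pmax(1 - bt$conf.int, .Machine$double.eps)
  }
  ratio <- if (m_cl == 0) Inf else m_na / m_cl
  list(ratio = ratio, ci = ci, mean_na = m_na, mean_cl = m_cl)
}
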