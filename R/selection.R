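#' @include AllClasses.R
NULL

#' Select particles by role / helix / strand / residue / molecule
#'
#' Deterministic, order-preserving conjunction of filters. An empty result is
#' legal; downstream analyses decide whether to reject it. Indices are 1-based
#' row indices into the topology table.
#'
#' @param topology a [ParticleTopology-class] or [Trajectory-class]
#' @param role roles to keep (character vector), or NULL
#' @param helix helix ids to keep, or NULL
#' @param strand strand ids to keep, or NULL
#' @param residue residue indices to keep, or NULL
#' @param molecule molecule ids to keep, or NULL
#' @return integer vector of particle indices
#' @export
selectParticles <- function(topology, role = NULL, helix = NULL, strand = NULL,
                            residue = NULL, molecule = NULL) {
  p <- particleData(topology)
  keep <- rep(TRUE, nrow(p))
  if (!is.null(role)) {
    bad <- setdiff(role, particleRoles())
    if (length(bad)) stopf("unknown role(s): %s", paste(bad, collapse = ", "))
    keep <- keep & p$role %in% role
  }
  if (!is.null(helix)) keep <- keep & !is.na(p$helix_id) & p$helix_id %in% helix
  if (!is.null(strand)) keep <- keep & !is.na(p$strand_id) & p$strand_id %in% strand
  if (!is.null(residue)) keep <- keep & p$residue_index %in% residue
  if (!is.null(molecule)) keep <- keep & p$molecule_id %in% molecule
  which(keep)
}

#' Trailing analysis window
#'
#' Returns the sub-trajectory covering the last `last_t` nanoseconds,
#' including both endpoint frames (so a 300 ns window over 20 ps frames holds
#' 15001 frames). Errors if `last_t` exceeds the trajectory span.
#'
#' @param traj a [Trajectory-class]
#' @param last_t window length in ns
#' @return a [Trajectory-class]
#' @export
analysisWindow <- function(traj, last_t) {
  stopifnot(is(traj, "Trajectory"), last_t > 0)
  t <- frameTimes(traj)
  span_ns <- (t[length(t)] - t[1]) / 1000
  if (last_t > span_ns + 1e-9)
    stopf("last_t = %g ns exceeds trajectory span %g ns", last_t, span_ns)
  t0 <- t[length(t)] - last_t * 1000
  traj[t >= t0 - 1e-9]
}
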