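#' @import methods
NULL

#' Semantic particle roles
#'
#' The fixed vocabulary of semantic roles a particle can carry. Roles drive
#' every selection in the package: DNA backbone/base beads, the hydrophobic
#' ethyl anchors, the four lipid moieties (choline, phosphate, glycerol and
#' the two acyl chains), water and the monovalent ions.
#'
#' @return Character vector of valid role names.
#' @export
particleRoles <- function() {
  c("DNA_BB", "DNA_BASE", "ETHYL",
    "LIPID_NC3", "LIPID_PO4", "LIPID_GLY",
    "LIPID_TAIL_SN1", "LIPID_TAIL_SN2",
    "WATER", "ION_NA", "ION_CL", "OTHER")
}

.dnt_roles <- c("DNA_BB", "DNA_BASE", "ETHYL")
.lipid_roles <- c("LIPID_NC3", "LIPID_PO4", "LIPID_GLY",
                  "LIPID_TAIL_SN1", "LIPID_TAIL_SN2")

#' ParticleTopology: per-particle metadata
#'
#' Holds one row per particle: its semantic role, molecule/residue bookkeeping,
#' optional helix and strand assignment (DNT particles only), the bead radius
#' used by the pore profiler, and the acyl-chain position for tail beads.
#' Lengths are nm throughout.
#'
#' @slot particles data.frame with columns `particle_id` (0-based integer),
#'   `role`, `molecule_id`, `helix_id`, `strand_id`, `residue_index`,
#'   `bead_radius` (nm), `tail_position`, `name`, `resname`, `groove`.
#' @export
setClass("ParticleTopology", representation(particles = "data.frame"))

setValidity("ParticleTopology", function(object) {
  p <- object@particles
  need <- c("particle_id", "role", "molecule_id", "helix_id", "strand_id",
            "residue_index", "bead_radius", "tail_position", "name",
            "resname", "groove")
  miss <- setdiff(need, names(p))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(p$role %in% particleRoles()))
    return(paste("unknown roles:", paste(unique(setdiff(p$role, particleRoles())), collapse = ", ")))
  helix_bad <- xor(!is.na(p$helix_id), p$role %in% .dnt_roles)
  if (any(helix_bad))
    return("helix_id must be set iff role is DNA_BB, DNA_BASE or ETHYL")
  if (any(!is.na(p$helix_id) & (p$helix_id < 0L | p$helix_id > 5L)))
    return("helix_id must lie in 0..5")
  if (any(!is.na(p$bead_radius) & p$bead_radius <= 0))
    return("bead_radius must be > 0 where defined")
  TRUE
})

#' Trajectory: ordered frames of particle positions
#'
#' Positions are stored as an `n x 3 x F` array in nm; times in ps; per-frame
#' orthorhombic box lengths in nm. Coordinates may lie outside the box:
#' analyses apply the minimum-image convention explicitly and never rewrap
#' the stored coordinates.
#'
#' @slot topology A [ParticleTopology-class].
#' @slot coords numeric array `n x 3 x F` (nm).
#' @slot times numeric vector of frame times (ps), strictly increasing.
#' @slot box numeric `F x 3` matrix of box lengths (nm).
#' @export
setClass("Trajectory", representation(
  topology = "ParticleTopology",
  coords = "array",
  times = "numeric",
  box = "matrix"
))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L) return("coords must be an n x 3 x F array")
  n <- nrow(object@topology@particles)
  if (d[1] != n) return(sprintf("coords hold %d particles but topology %d", d[1], n))
  if (d[3] != length(object@times)) return("frame count differs from times length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  if (nrow(object@box) != d[3] || ncol(object@box) != 3L)
    return("box must be an F x 3 matrix")
  if (any(object@box <= 0)) return("box lengths must be > 0")
  TRUE
})

#' RoleDialect: mapping from file naming to semantic roles
#'
#' A dialect maps `(residue name, atom/bead name)` pairs found in a structure
#' file to semantic roles, bead radii (nm) and acyl-chain positions. Two
#' built-ins ship with the package: `"cg-martini"` and `"at-charmm-like"`
#' (see [builtinDialect()]); custom dialects can be loaded from YAML with
#' [readDialect()].
#'
#' @slot name dialect name.
#' @slot mapping data.frame with columns `resname`, `atom`, `role`,
#'   `bead_radius`, `tail_position`. `resname = "*"` is a wildcard.
#' @slot unknown_to_other map unmapped names to role OTHER instead of erroring.
#' @export
setClass("RoleDialect", representation(
  name = "character",
  mapping = "data.frame",
  unknown_to_other = "logical"
))

setValidity("RoleDialect", function(object) {
  need <- c("resname", "atom", "role", "bead_radius", "tail_position")
  miss <- setdiff(need, names(object@mapping))
  if (length(miss)) return(paste("mapping lacks columns:", paste(miss, collapse = ", ")))
  if (!all(object@mapping$role %in% particleRoles())) return("mapping contains unknown roles")
  TRUE
})

#' DNTModel: idealized six-duplex DNA nanotube geometry
#'
#' Built by [buildHexagonalScaffold()]. Stores the parallel helix axes (base
#' points on a regular hexagon for n = 6), one backbone pseudo-particle per
#' nucleotide on ideal B-DNA helical paths, per-residue helical phase, groove
#' assignment and hydrophobic-band membership.
#'
#' @slot n_helices number of duplexes (1..6).
#' @slot spacing_d inter-helix (hexagon side) spacing, nm.
#' @slot helix_radius backbone helix radius, nm.
#' @slot length_bp base pairs per duplex.
#' @slot rise_per_bp nm per bp.
#' @slot twist_per_bp degrees per bp.
#' @slot strand_offset_deg phase offset between the two backbone strands.
#' @slot helix_axes data.frame: `helix_id`, axis base point `x`,`y`,`z` and
#'   unit direction `dx`,`dy`,`dz`.
#' @slot residues data.frame: one row per backbone residue with columns
#'   `helix_id`, `strand_id`, `bp`, `x`,`y`,`z`, `phase` (deg), `groove`
#'   (`"minor"`/`"major"`), `band` (integer band index or NA).
#' @export
setClass("DNTModel", representation(
  n_helices = "integer",
  spacing_d = "numeric",
  helix_radius = "numeric",
  length_bp = "integer",
  rise_per_bp = "numeric",
  twist_per_bp = "numeric",
  strand_offset_deg = "numeric",
  helix_axes = "data.frame",
  residues = "data.frame"
))

setValidity("DNTModel", function(object) {
  if (object@n_helices < 1L || object@n_helices > 6L) return("n_helices must be 1..6")
  ax <- object@helix_axes
  if (nrow(ax) != object@n_helices) return("one axis per helix required")
  dirs <- as.matrix(ax[, c("dx", "dy", "dz")])
  if (nrow(dirs) > 1L) {
    ref <- dirs[1, ]
    if (any(abs(abs(dirs %*% ref) - 1) > 1e-9)) return("helix axes must be parallel")
  }
  if (object@n_helices == 6L) {
    pts <- as.matrix(ax[, c("x", "y")])
    nn <- vapply(seq_len(6L), function(i) {
      d <- sqrt(rowSums((pts[-i, , drop = FALSE] -
                           matrix(pts[i, ], 5, 2, byrow = TRUE))^2))
      min(d)
    }, numeric(1))
    if (any(abs(nn - object@spacing_d) > 1e-9))
      return("hexagon nearest-neighbour spacing must equal spacing_d")
  }
  TRUE
})

#' ENMSpec: elastic network specification
#'
#' Harmonic bonds between backbone residues of a [DNTModel-class]. Rest
#' lengths equal build-time distances exactly; in `"soft"` mode all force
#' constants are 100 kJ mol^-1 nm^-2.
#'
#' @slot bonds data.frame: `i`, `j` (residue row indices), `rest_length` (nm),
#'   `k` (kJ mol^-1 nm^-2), `junction` (logical, inter-helix bond).
#' @slot stiffness_mode `"stiff"` or `"soft"`.
#' @export
setClass("ENMSpec", representation(bonds = "data.frame", stiffness_mode = "character"))

setValidity("ENMSpec", function(object) {
  if (!object@stiffness_mode %in% c("stiff", "soft")) return("mode must be stiff or soft")
  if (object@stiffness_mode == "soft" && nrow(object@bonds) &&
      any(object@bonds$k != 100)) return("soft mode requires k = 100 kJ mol-1 nm-2")
  TRUE
})

#' PoreProfile: pore radius as a function of axial position and time
#'
#' Produced by [poreProfileOverTime()]. `radius` is an `F x nz` matrix of
#' largest-inscribed-sphere radii (nm); radii equal to `r_cap` mark slices
#' with no confining particles ("open" ends) and are excluded from the
#' mean/SD and from conductance.
#'
#' @slot z axial grid (nm, relative to the bilayer/profile origin).
#' @slot radius `F x nz` matrix of radii (nm).
#' @slot center_x,center_y `F x nz` matrices of optimized sphere centres (nm).
#' @slot mean_radius,sd_radius per-z statistics over frames with valid radii.
#' @slot r_cap cap radius (nm).
#' @slot times frame times (ps).
#' @export
setClass("PoreProfile", representation(
  z = "numeric", radius = "matrix",
  center_x = "matrix", center_y = "matrix",
  mean_radius = "numeric", sd_radius = "numeric",
  r_cap = "numeric", times = "numeric"
))

setValidity("PoreProfile", function(object) {
  if (any(object@radius < 0, na.rm = TRUE)) return("radii must be >= 0")
  if (any(object@radius > object@r_cap + 1e-9, na.rm = TRUE))
    return("radii must be capped at r_cap")
  if (ncol(object@radius) != length(object@z)) return("radius columns must match z grid")
  TRUE
})

#' ForceTrace: steered-MD pulling record
#'
#' Time series of the applied pulling force and the pulled group's COM z
#' coordinate, at constant pull velocity. Units: ps, kJ mol^-1 nm^-1, nm.
#'
#' @slot time ps.
#' @slot force kJ mol^-1 nm^-1.
#' @slot com_z nm (COM of the hydrophobic band relative to bilayer COM).
#' @slot pull_velocity nm per microsecond.
#' @slot ground_truth list of generator parameters (empty for real traces).
#' @export
setClass("ForceTrace", representation(
  time = "numeric", force = "numeric", com_z = "numeric",
  pull_velocity = "numeric", ground_truth = "list"
))

setValidity("ForceTrace", function(object) {
  if (length(object@time) != length(object@force) ||
      length(object@time) != length(object@com_z))
    return("time, force and com_z must have equal length")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    return("times must be strictly increasing")
  TRUE
})
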