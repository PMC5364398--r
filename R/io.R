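#' @include dialects.R
NULL

# ---- GRO parsing (fixed-width, nm) ------------------------------------------

# parse one GRO frame starting at line `at`; returns list(frame data, next line)
.parse_gro_frame <- function(lines, at, path) {
  if (at > length(lines)) return(NULL)
  title <- lines[at]
  n <- suppressWarnings(as.integer(trimws(lines[at + 1L])))
  if (is.na(n))
    stopf("%s: malformed atom count at line %d", path, at + 1L)
  if (at + 1L + n + 1L > length(lines))
    stopf("%s: truncated frame starting at line %d", path, at)
  rec <- lines[(at + 2L):(at + 1L + n)]
  resid <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  resname <- trimws(substr(rec, 6, 10))
  atom <- trimws(substr(rec, 11, 15))
  x <- suppressWarnings(as.numeric(substr(rec, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(rec, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(rec, 37, 44)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))
  if (length(bad))
    stopf("%s: malformed atom record at line %d", path, at + 1L + bad[1])
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[at + n + 2L]), "\\s+")[[1]]))
  if (length(boxv) < 3L || any(is.na(boxv[1:3])))
    stopf("%s: malformed box line at line %d", path, at + n + 2L)
  tm <- NA_real_
  if (grepl("t=", title)) {
    tm <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", title)))
  }
  list(resid = resid, resname = resname, atom = atom,
       pos = cbind(x, y, z), box = boxv[1:3], time = tm,
       next_at = at + n + 3L)
}

.read_gro <- function(path, max_frames = Inf) {
  lines <- readLines(path)
  frames <- list()
  at <- 1L
  while (at <= length(lines) && length(frames) < max_frames) {
    if (!nzchar(trimws(lines[at])) && at == length(lines)) break
    fr <- .parse_gro_frame(lines, at, path)
    if (is.null(fr)) break
    frames[[length(frames) + 1L]] <- fr
    at <- fr$next_at
  }
  frames
}

# ---- public readers ---------------------------------------------------------

# orthorhombic box (nm) from a PDB CRYST1 record; NULL when absent
.pdb_box <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  abc <- suppressWarnings(as.numeric(c(substr(ln[1], 7, 15),
                                       substr(ln[1], 16, 24),
                                       substr(ln[1], 25, 33))))
  if (anyNA(abc) || any(abc <= 0)) return(NULL)
  abc / 10
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro")) return("gro")
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("dcd")) return("dcd")
  stopf("cannot infer format from extension '%s'", ext)
}

# build a ParticleTopology from names + dialect. Helix/strand are decoded
# from the package-native naming (resname DNT<h>, atom suffix A/B); generic
# DNA naming carries no helix information and defaults to helix 0, strand 0.
.topology_from_names <- function(resid, resname, atom, dialect) {
  rl <- apply_dialect(dialect, resname, atom)
  n <- length(resid)
  helix <- rep(NA_integer_, n)
  strand <- rep(NA_integer_, n)
  is_dnt <- rl$role %in% .dnt_roles
  helix[is_dnt] <- 0L
  strand[is_dnt] <- 0L
  enc <- grepl("^DNT[0-5]$", resname) & is_dnt
  helix[enc] <- as.integer(substr(resname[enc], 4, 4))
  strand[enc & endsWith(atom, "B")] <- 1L
  # molecule ids: new molecule when resid decreases or resname class changes
  newmol <- c(TRUE, resid[-1] != resid[-n] | resname[-1] != resname[-n])
  molecule <- cumsum(newmol)
  df <- data.frame(
    particle_id = seq_len(n), role = rl$role, molecule_id = molecule,
    helix_id = helix, strand_id = strand, residue_index = resid,
    bead_radius = rl$bead_radius, tail_position = rl$tail_position,
    name = atom, resname = resname, groove = NA_character_,
    stringsAsFactors = FALSE)
  new("ParticleTopology", particles = df)
}

#' Read a structure file (PDB or GRO)
#'
#' Coordinates are converted to nm on read regardless of the source
#' convention (PDB records are Angstrom). Every record is mapped to a
#' semantic role through `dialect`; unmapped names raise an error listing
#' them (or map to `OTHER` when the dialect was built with
#' `unknown_to_other = TRUE`).
#'
#' @param path PDB or GRO file
#' @param dialect a [RoleDialect-class]
#' @param format `"auto"`, `"pdb"` or `"gro"`
#' @return list with elements `topology` ([ParticleTopology-class]) and
#'   `frame` (list with `time` ps, `box` nm, `positions` n x 3 nm)
#' @export
readStructure <- function(path, dialect = builtinDialect("cg-martini"),
                          format = "auto") {
  if (format == "auto") format <- .guess_format(path)
  if (format == "gro") {
    fr <- .read_gro(path, max_frames = 1)[[1]]
    topo <- .topology_from_names(fr$resid, fr$resname, fr$atom, dialect)
    frame <- list(time = if (is.na(fr$time)) 0 else fr$time,
                  box = fr$box, positions = unname(fr$pos))
  } else if (format == "pdb") {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    topo <- .topology_from_names(a$resno, trimws(a$resid), trimws(a$elety), dialect)
    pos <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
    box <- .pdb_box(path) %||% rep(1000, 3)
    frame <- list(time = 0, box = box, positions = unname(pos))
  } else stopf("unsupported structure format '%s'", format)
  list(topology = topo, frame = frame)
}

#' Read a trajectory (multi-frame GRO/PDB, or DCD)
#'
#' Frame counts must match the supplied topology; a mismatch is reported with
#' the offending frame index. Frame times are taken from `t=` markers in GRO
#' titles when present, otherwise generated from `frame_interval`.
#'
#' @param path trajectory file
#' @param topology a [ParticleTopology-class] describing the particles
#' @param dialect dialect used when `topology` is NULL (GRO/PDB only)
#' @param format `"auto"`, `"gro"`, `"pdb"` or `"dcd"`
#' @param frame_interval ps between frames, used when the file stores no times
#' @param first,last,stride frame-range selection (1-based, inclusive)
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(path, topology = NULL,
                           dialect = builtinDialect("cg-martini"),
                           format = "auto", frame_interval = NA,
                           first = 1L, last = Inf, stride = 1L) {
  if (format == "auto") format <- .guess_format(path)
  if (format == "gro" || format == "pdb") {
    if (format == "gro") {
      frames <- .read_gro(path)
      if (!length(frames)) stopf("%s: no frames found", path)
      if (is.null(topology))
        topology <- .topology_from_names(frames[[1]]$resid, frames[[1]]$resname,
                                         frames[[1]]$atom, dialect)
      n <- nParticles(topology)
      for (i in seq_along(frames))
        if (nrow(frames[[i]]$pos) != n)
          stopf("frame %d holds %d particles but topology %d",
                i, nrow(frames[[i]]$pos), n)
      coords <- array(0, c(n, 3, length(frames)))
      box <- matrix(0, length(frames), 3)
      times <- numeric(length(frames))
      for (i in seq_along(frames)) {
        coords[, , i] <- frames[[i]]$pos
        box[i, ] <- frames[[i]]$box
        times[i] <- frames[[i]]$time
      }
      if (anyNA(times))
        times <- (seq_along(frames) - 1) *
          (if (is.na(frame_interval)) 1 else frame_interval)
    } else {
      pdb <- bio3d::read.pdb(path, multi = TRUE)
      a <- pdb$atom
      if (is.null(topology))
        topology <- .topology_from_names(a$resno, trimws(a$resid),
                                         trimws(a$elety), dialect)
      n <- nParticles(topology)
      xyz <- pdb$xyz
      if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
      if (ncol(xyz) != 3 * n)
        stopf("frame 1 holds %d particles but topology %d", ncol(xyz) / 3, n)
      nf <- nrow(xyz)
      coords <- array(0, c(n, 3, nf))
      for (i in seq_len(nf))
        coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
      box <- matrix(.pdb_box(path) %||% rep(1000, 3), nf, 3, byrow = TRUE)
      times <- (seq_len(nf) - 1) * (if (is.na(frame_interval)) 1 else frame_interval)
    }
  } else if (format == "dcd") {
    if (is.null(topology)) stopf("DCD input requires a topology")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    n <- nParticles(topology)
    if (ncol(xyz) != 3 * n)
      stopf("frame 1 holds %d particles but topology %d", ncol(xyz) / 3, n)
    nf <- nrow(xyz)
    coords <- array(0, c(n, 3, nf))
    for (i in seq_len(nf))
      coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    box <- matrix(1000, nf, 3)
    times <- (seq_len(nf) - 1) * (if (is.na(frame_interval)) 1 else frame_interval)
  } else stopf("unsupported trajectory format '%s'", format)

  keep <- seq(from = max(1L, first), to = min(dim(coords)[3], last), by = stride)
  new("Trajectory", topology = topology,
      coords = coords[, , keep, drop = FALSE],
      times = times[keep], box = box[keep, , drop = FALSE])
}

#' Write a structure as GRO
#'
#' Uses the topology's stored residue/atom names when present; DNT particles
#' are written with the package-native helix/strand encoding (resname
#' `DNT<h>`, atom suffix `A`/`B`) so that roles, helix and strand survive a
#' read/write round-trip under the `"cg-martini"` dialect. Serials are
#' written 1-based per GRO convention.
#'
#' @param topology a [ParticleTopology-class]
#' @param frame frame list (`time`, `box`, `positions` in nm)
#' @param path output path
#' @param title title line
#' @return `path`, invisibly
#' @export
writeStructure <- function(topology, frame, path, title = "DNTPore structure") {
  p <- particleData(topology)
  n <- nrow(p)
  pos <- frame$positions
  stopifnot(nrow(pos) == n)
  resname <- p$resname
  atom <- p$name
  fill <- is.na(resname) | !nzchar(resname)
  if (any(fill)) resname[fill] <- "UNK"
  fillA <- is.na(atom) | !nzchar(atom)
  if (any(fillA)) atom[fillA] <- "X"
  lines <- c(sprintf("%s, t= %.3f", title, frame$time %||% 0),
             sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     p$residue_index %% 100000L, substr(resname, 1, 5),
                     substr(atom, 1, 5), seq_len(n) %% 100000L,
                     pos[, 1], pos[, 2], pos[, 3]),
             sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3]))
  writeLines(lines, path)
  invisible(path)
}

# ---- analysis CSV output ----------------------------------------------------

# deterministic md5 of a configuration list (via canonical JSON)
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  unname(tools::md5sum(tf))
}

#' Write an analysis table as CSV with a unit/provenance header
#'
#' The header comment lines name the units of every column and the md5 hash
#' of the configuration that produced the table, so outputs are traceable.
#'
#' @param df data.frame to write
#' @param path output path
#' @param units named character vector, units per column
#' @param config configuration list (hashed into the header)
#' @return `path`, invisibly
#' @export
writeAnalysisCSV <- function(df, path, units = character(), config = list()) {
  hdr <- c(sprintf("# DNTPore %s", as.character(utils::packageVersion("DNTPore"))),
           if (length(units))
             sprintf("# units: %s", paste(names(units), units, sep = "=", collapse = " ")),
           sprintf("# config_hash: %s", config_hash(config)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
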