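#' @include AllClasses.R
NULL

# mapping rows: exact atom names, or regex when atom starts with "~".
# resname "*" is a wildcard. bead_radius NA means "deduce from element letter"
# (atomistic dialects).
.map_row <- function(resname, atom, role, radius = NA_real_, tail = NA_integer_) {
  data.frame(resname = resname, atom = atom, role = role,
             bead_radius = radius, tail_position = tail,
             stringsAsFactors = FALSE)
}

.cg_radius <- 0.26   # regular MARTINI bead
.cg_small <- 0.23    # small/ring bead class

.build_cg_martini <- function() {
  rows <- list()
  # POPC-style CG lipid
  rows <- c(rows, list(
    .map_row("POPC", "NC3", "LIPID_NC3", .cg_radius),
    .map_row("POPC", "PO4", "LIPID_PO4", .cg_radius),
    .map_row("POPC", "GL1", "LIPID_GLY", .cg_radius),
    .map_row("POPC", "GL2", "LIPID_GLY", .cg_radius)
  ))
  # chain A (oleoyl, sn-2) and chain B (palmitoyl, sn-1); D2A is the
  # unsaturated bead in standard MARTINI POPC naming
  snA <- c("C1A", "D2A", "C3A", "C4A")
  snB <- c("C1B", "C2B", "C3B", "C4B")
  for (i in seq_along(snA))
    rows <- c(rows, list(.map_row("POPC", snA[i], "LIPID_TAIL_SN2", .cg_radius, i)))
  for (i in seq_along(snB))
    rows <- c(rows, list(.map_row("POPC", snB[i], "LIPID_TAIL_SN1", .cg_radius, i)))
  # also accept C2A naming (saturated variant)
  rows <- c(rows, list(.map_row("POPC", "C2A", "LIPID_TAIL_SN2", .cg_radius, 2L)))
  # MARTINI DNA
  for (rn in c("DA", "DT", "DG", "DC")) {
    for (a in c("BB1", "BB2", "BB3"))
      rows <- c(rows, list(.map_row(rn, a, "DNA_BB", .cg_radius)))
    for (a in c("SC1", "SC2", "SC3", "SC4"))
      rows <- c(rows, list(.map_row(rn, a, "DNA_BASE", .cg_small)))
  }
  # package-native DNT naming: resname DNT0..DNT5 encodes the helix, atom
  # suffix A/B the strand (see writeStructure())
  for (h in 0:5) {
    rn <- paste0("DNT", h)
    for (a in c("BBA", "BBB", "BB"))
      rows <- c(rows, list(.map_row(rn, a, "DNA_BB", .cg_radius)))
    for (a in c("ETA", "ETB", "ET"))
      rows <- c(rows, list(.map_row(rn, a, "ETHYL", .cg_radius)))
    for (a in c("SCA", "SCB"))
      rows <- c(rows, list(.map_row(rn, a, "DNA_BASE", .cg_small)))
  }
  # water and ions
  rows <- c(rows, list(
    .map_row("W", "W", "WATER", .cg_radius),
    .map_row("ION", "NA+", "ION_NA", .cg_small),
    .map_row("ION", "NA", "ION_NA", .cg_small),
    .map_row("ION", "CL-", "ION_CL", .cg_small),
    .map_row("ION", "CL", "ION_CL", .cg_small),
    .map_row("NA+", "NA+", "ION_NA", .cg_small),
    .map_row("CL-", "CL-", "ION_CL", .cg_small)
  ))
  do.call(rbind, rows)
}

.build_at_charmm <- function() {
  rows <- list()
  dna_bb <- "~^(P$|OP[12]$|O[12]P$|O[35]'|C[12345]'|O4')"
  for (rn in c("DA", "DT", "DG", "DC", "ADE", "THY", "GUA", "CYT")) {
    rows <- c(rows, list(
      .map_row(rn, dna_bb, "DNA_BB"),
      .map_row(rn, "~^H", "OTHER"),
      .map_row(rn, "~.", "DNA_BASE")
    ))
  }
  rows <- c(rows, list(
    .map_row("POPC", "~^(N$|C1[2345]$|H1[2345].?$)", "LIPID_NC3"),
    .map_row("POPC", "~^(P$|O1[1234]$)", "LIPID_PO4"),
    .map_row("POPC", "~^(C[123]$|HA$|HB$|HS$|HX$|HY$|O2[12]$|O3[12]$|C2$|C3$)", "LIPID_GLY"),
    .map_row("POPC", "~^C3[0-9]+$", "LIPID_TAIL_SN1"),
    .map_row("POPC", "~^C2[0-9]+$", "LIPID_TAIL_SN2"),
    .map_row("POPC", "~^H", "OTHER"),
    .map_row("TIP3", "~.", "WATER"),
    .map_row("HOH", "~.", "WATER"),
    .map_row("SOL", "~.", "WATER"),
    .map_row("SOD", "~.", "ION_NA"),
    .map_row("NA", "~.", "ION_NA"),
    .map_row("CLA", "~.", "ION_CL"),
    .map_row("CL", "~.", "ION_CL")
  ))
  do.call(rbind, rows)
}

#' Built-in role dialects
#'
#' `"cg-martini"` covers MARTINI-style coarse-grained naming (POPC beads,
#' MARTINI DNA beads, W water, ION) plus the package's native DNT naming
#' (resname `DNT0`..`DNT5`, atoms `BBA`/`BBB`/`ETA`/`ETB`/`SCA`/`SCB`, which
#' encode helix and strand so structures round-trip losslessly).
#' `"at-charmm-like"` covers common atomistic naming (CHARMM-style DNA and
#' POPC atoms, TIP3 water, SOD/CLA ions); bead radii are assigned from a
#' bundled van der Waals table by element.
#'
#' @param name `"cg-martini"` or `"at-charmm-like"`
#' @param unknown_to_other map unknown (residue, atom) names to role `OTHER`
#'   instead of raising an error listing them
#' @return a [RoleDialect-class]
#' @export
builtinDialect <- function(name = c("cg-martini", "at-charmm-like"),
                           unknown_to_other = FALSE) {
  name <- match.arg(name)
  mapping <- switch(name,
                    "cg-martini" = .build_cg_martini(),
                    "at-charmm-like" = .build_at_charmm())
  new("RoleDialect", name = name, mapping = mapping,
      unknown_to_other = unknown_to_other)
}

# element vdW radii (nm) for atomistic dialects, keyed by leading element letter
.vdw_table <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, P = 0.180,
                S = 0.180, NA. = 0.227, CL = 0.175)

.element_radius <- function(atom) {
  up <- toupper(atom)
  r <- rep(NA_real_, length(atom))
  r[startsWith(up, "CL")] <- .vdw_table[["CL"]]
  r[startsWith(up, "NA")] <- .vdw_table[["NA."]]
  first <- substr(up, 1, 1)
  for (el in c("H", "C", "N", "O", "P", "S")) {
    hit <- is.na(r) & first == el
    r[hit] <- .vdw_table[[el]]
  }
  r[is.na(r)] <- 0.17
  r
}

# map (resname, atom) vectors through a dialect; returns data.frame with
# role, bead_radius, tail_position. Errors listing unknowns unless the
# dialect opts into OTHER-mapping.
apply_dialect <- function(dialect, resname, atom) {
  stopifnot(is(dialect, "RoleDialect"))
  m <- dialect@mapping
  exact <- !startsWith(m$atom, "~")
  key <- paste(resname, atom, sep = "\r")
  mkey <- paste(m$resname, m$atom, sep = "\r")
  hit <- match(key, mkey[exact])
  idx_exact <- which(exact)[hit]
  # wildcard resname, exact atom
  wkey <- paste("*", atom, sep = "\r")
  whit <- match(wkey, mkey[exact])
  idx_exact[is.na(idx_exact)] <- which(exact)[whit][is.na(idx_exact)]
  row_idx <- idx_exact
  todo <- which(is.na(row_idx))
  if (length(todo)) {
    rx <- which(!exact)
    for (i in todo) {
      for (j in rx) {
        if ((m$resname[j] == "*" || m$resname[j] == resname[i]) &&
            grepl(sub("^~", "", m$atom[j]), atom[i])) {
          row_idx[i] <- j
          break
        }
      }
    }
  }
  unknown <- is.na(row_idx)
  if (any(unknown)) {
    if (dialect@unknown_to_other) {
      out <- data.frame(role = rep("OTHER", length(resname)),
                        bead_radius = 0.26, tail_position = NA_integer_,
                        stringsAsFactors = FALSE)
      ok <- !unknown
      out$role[ok] <- m$role[row_idx[ok]]
      out$bead_radius[ok] <- m$bead_radius[row_idx[ok]]
      out$tail_position[ok] <- m$tail_position[row_idx[ok]]
      out$bead_radius[is.na(out$bead_radius)] <- .element_radius(atom[is.na(out$bead_radius) | FALSE])
      return(out)
    }
    bad <- unique(paste0(resname[unknown], "/", atom[unknown]))
    stopf("dialect '%s' does not map %d name(s): %s",
          dialect@name, length(bad), paste(bad, collapse = ", "))
  }
  out <- data.frame(role = m$role[row_idx],
                    bead_radius = m$bead_radius[row_idx],
                    tail_position = m$tail_position[row_idx],
                    stringsAsFactors = FALSE)
  na_r <- is.na(out$bead_radius)
  if (any(na_r)) out$bead_radius[na_r] <- .element_radius(atom[na_r])
  out
}

#' Read a role dialect from a YAML file
#'
#' The file holds `name`, optional `unknown_to_other`, and a `mapping` list of
#' records with fields `resname`, `atom`, `role` and optional `bead_radius`
#' (nm) and `tail_position`. Atom entries starting with `~` are regular
#' expressions; resname `*` is a wildcard.
#'
#' @param path YAML file path
#' @return a [RoleDialect-class]
#' @export
readDialect <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(y$mapping, function(r) {
    .map_row(r$resname, r$atom, r$role,
             if (is.null(r$bead_radius)) NA_real_ else as.numeric(r$bead_radius),
             if (is.null(r$tail_position)) NA_integer_ else as.integer(r$tail_position))
  })
  new("RoleDialect", name = y$name %||% "custom",
      mapping = do.call(rbind, rows),
      unknown_to_other = isTRUE(y$unknown_to_other))
}

#' Write a role dialect to YAML
#' @param dialect a [RoleDialect-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeDialect <- function(dialect, path) {
  m <- dialect@mapping
  recs <- lapply(seq_len(nrow(m)), function(i) {
    r <- list(resname = m$resname[i], atom = m$atom[i], role = m$role[i])
    if (!is.na(m$bead_radius[i])) r$bead_radius <- m$bead_radius[i]
    if (!is.na(m$tail_position[i])) r$tail_position <- m$tail_position[i]
    r
  })
  yaml::write_yaml(list(name = dialect@name,
                        unknown_to_other = dialect@unknown_to_other,
                        mapping = recs), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
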