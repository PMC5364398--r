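#' @include AllClasses.R
NULL

#' Number of particles
#' @param x a ParticleTopology or Trajectory
#' @return integer count
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' @rdname nParticles
#' @export
setMethod("nParticles", "ParticleTopology", function(x) nrow(x@particles))

#' @rdname nParticles
#' @export
setMethod("nParticles", "Trajectory", function(x) dim(x@coords)[1])

#' Number of frames in a trajectory
#' @param x a Trajectory
#' @return integer count
#' @export
nFrames <- function(x) {
  stopifnot(is(x, "Trajectory"))
  dim(x@coords)[3]
}

#' Frame times (ps)
#' @param x a Trajectory
#' @return numeric vector
#' @export
frameTimes <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@times
}

#' Frame interval (ps)
#'
#' The constant spacing between consecutive frame times. `NA` for
#' single-frame trajectories; an error if spacing is not constant within
#' `tol` (relative).
#'
#' @param x a Trajectory
#' @param tol relative tolerance on spacing constancy
#' @return interval in ps, or NA
#' @export
frameInterval <- function(x, tol = 1e-6) {
  t <- frameTimes(x)
  if (length(t) < 2L) return(NA_real_)
  dt <- diff(t)
  if (diff(range(dt)) > tol * max(abs(dt)))
    stop("frame spacing is not constant (range ",
         min(dt), " .. ", max(dt), " ps)")
  mean(dt)
}

#' Per-particle metadata table
#' @param x a ParticleTopology or Trajectory
#' @return data.frame, one row per particle
#' @export
particleData <- function(x) {
  if (is(x, "Trajectory")) x <- x@topology
  stopifnot(is(x, "ParticleTopology"))
  x@particles
}

#' Topology of a trajectory
#' @param x a Trajectory
#' @return the ParticleTopology
#' @export
topology <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@topology
}

#' Extract one frame
#'
#' @param x a Trajectory
#' @param i frame index (1-based)
#' @return list with `time` (ps), `box` (nm, length 3) and `positions`
#'   (n x 3 matrix, nm)
#' @export
getFrame <- function(x, i) {
  stopifnot(is(x, "Trajectory"), i >= 1L, i <= nFrames(x))
  list(time = x@times[i], box = x@box[i, ],
       positions = x@coords[, , i, drop = TRUE])
}

#' Subset frames of a trajectory
#'
#' @param x a Trajectory
#' @param i frame indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "Trajectory", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(nFrames(x))[i]
  new("Trajectory", topology = x@topology,
      coords = x@coords[, , i, drop = FALSE],
      times = x@times[i], box = x@box[i, , drop = FALSE])
})

setMethod("show", "ParticleTopology", function(object) {
  tab <- table(object@particles$role)
  cat("ParticleTopology with", nrow(object@particles), "particles\n")
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nParticles(object), "particles x", nFrames(object), "frames\n")
  if (nFrames(object) > 0) {
    cat(sprintf("  time %g .. %g ps; box %s nm\n",
                object@times[1], object@times[nFrames(object)],
                paste(signif(object@box[1, ], 4), collapse = " x ")))
  }
})

setMethod("show", "RoleDialect", function(object) {
  cat("RoleDialect '", object@name, "': ", nrow(object@mapping),
      " name mappings\n", sep = "")
})

setMethod("show", "DNTModel", function(object) {
  cat(sprintf("DNTModel: %d helices, d = %g nm, %d bp (rise %g nm, twist %g deg)\n",
              object@n_helices, object@spacing_d, object@length_bp,
              object@rise_per_bp, object@twist_per_bp))
  nb <- sum(!is.na(object@residues$band))
  if (nb) cat("  hydrophobic band residues:", nb, "\n")
})

setMethod("show", "ENMSpec", function(object) {
  cat("ENMSpec (", object@stiffness_mode, "): ", nrow(object@bonds), " bonds\n", sep = "")
})

setMethod("show", "PoreProfile", function(object) {
  cat(sprintf("PoreProfile: %d frames x %d z-slices, z in [%g, %g] nm\n",
              nrow(object@radius), length(object@z), min(object@z), max(object@z)))
  ok <- is.finite(object@mean_radius)
  if (any(ok))
    cat(sprintf("  mean radius %g nm (min %g at z = %g)\n",
                signif(mean(object@mean_radius[ok]), 4),
                signif(min(object@mean_radius[ok]), 4),
                object@z[ok][which.min(object@mean_radius[ok])]))
})

setMethod("show", "ForceTrace", function(object) {
  cat(sprintf("ForceTrace: %d samples, %g .. %g ps, v = %g nm/us\n",
              length(object@time), object@time[1],
              object@time[length(object@time)], object@pull_velocity))
})
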