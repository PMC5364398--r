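#' @include dynamics.R pore_profile.R synthetic_membrane.R synthetic_traces.R io.R
NULL

.known_config_keys <- c("seed", "output_dir", "stages", "synth", "input",
                        "window_ns", "profile", "order", "rdf", "ions",
                        "pore", "tilt", "com", "residence", "rmsd",
                        "deform", "smd")

.known_stages <- c("profile", "order", "rdf", "ions", "pore", "tilt", "com",
                   "residence", "rmsd", "deform", "smd")

# shallow schema validation: unknown keys are rejected before any work
.validate_config <- function(config) {
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  stages <- config$stages %||% character()
  bad <- setdiff(stages, .known_stages)
  if (length(bad))
    stopf("unknown stage(s): %s (known: %s)", paste(bad, collapse = ", "),
          paste(.known_stages, collapse = ", "))
  if (is.null(config$synth) && is.null(config$input) && length(stages))
    stopf("config needs either a 'synth' block or an 'input' block")
  config
}

#' Run the configuration-driven analysis pipeline
#'
#' Executes the requested stages in dependency order on either a synthetic
#' system (config block `synth`, passed to [membraneSystemParams()] /
#' [generateMembraneSystem()]) or files read from disk (config block `input`
#' with `structure`, optional `trajectory`, `dialect`). Outputs are CSV/JSON
#' files in `output_dir` plus a run manifest (`manifest.json`) holding the
#' config, its hash, package/R versions, the seed and per-stage wall times.
#' A stage failure aborts with the stage name and cause; outputs written so
#' far are retained next to a `FAILED` marker file. Identical config + seed
#' reproduce bit-identical numeric outputs.
#'
#' @param config configuration list, or path to a YAML file
#' @return invisibly, a list with the manifest and in-memory stage results
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% character()
  hash <- config_hash(config)
  manifest <- list(config = config, config_hash = hash,
                   package_version = as.character(utils::packageVersion("DNTPore")),
                   r_version = R.version.string, seed = seed,
                   stages = list(), warnings = list())
  results <- list()
  warn_log <- character()

  traj <- NULL
  gt <- NULL
  if (length(stages)) {
    if (!is.null(config$synth)) {
      sp <- config$synth
      pargs <- sp[setdiff(names(sp), c("n_frames", "frame_interval", "band_layout"))]
      pargs$seed <- seed
      if (!is.null(sp$band_layout))
        pargs$tube <- placeHydrophobicBands(buildHexagonalScaffold(), sp$band_layout)
      params <- do.call(membraneSystemParams, pargs)
      sys <- generateMembraneSystem(params,
                                    n_frames = sp$n_frames %||% 20L,
                                    frame_interval = sp$frame_interval %||% 50)
      traj <- sys$trajectory
      gt <- sys$ground_truth
    } else {
      inp <- config$input
      dia <- builtinDialect(inp$dialect %||% "cg-martini")
      st <- readStructure(inp$structure, dia)
      traj <- if (!is.null(inp$trajectory))
        readTrajectory(inp$trajectory, st$topology,
                       frame_interval = inp$frame_interval %||% NA)
      else new("Trajectory", topology = st$topology,
               coords = array(st$frame$positions,
                              c(nrow(st$frame$positions), 3, 1)),
               times = st$frame$time, box = matrix(st$frame$box, 1, 3))
    }
    if (!is.null(config$window_ns)) traj <- analysisWindow(traj, config$window_ns)
  }

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
        stopf("stage '%s' failed: %s", name, conditionMessage(e))
      }),
      warning = function(w) {
        warn_log <<- c(warn_log, sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(elapsed_s = proc.time()[["elapsed"]] - t0)
    results[[name]] <<- res
    res
  }

  csv <- function(df, file, units = character())
    writeAnalysisCSV(df, file.path(out_dir, file), units, config)

  # dependency order: axis-based profiles and pore first, then dynamics
  order_of <- match(stages, .known_stages)
  for (st in .known_stages[sort(unique(order_of))]) {
    cfg <- config[[st]] %||% list()
    switch(st,
      profile = run_stage("profile", function() {
        rd <- radialDensity(traj, shell_width = cfg$shell_width %||% 0.1)
        th <- thicknessProfile(traj, shell_width = cfg$shell_width %||% 0.1)
        csv(rd, "radial_density.csv", c(r_mid = "nm", density = "nm^-3"))
        csv(th, "thickness.csv", c(r_mid = "nm", thickness = "nm"))
        list(radial_density = rd, thickness = th)
      }),
      order = run_stage("order", function() {
        og <- orderParameterGrid(traj, grid_cell = cfg$grid_cell %||% 1.0)
        csv(og, "order_parameter.csv", c(x_mid = "nm", S = "1"))
        og
      }),
      rdf = run_stage("rdf", function() {
        topo <- topology(traj)
        a <- selectParticles(topo, role = cfg$role_a %||% "DNA_BB")
        b <- selectParticles(topo, role = cfg$role_b %||% "LIPID_PO4")
        g <- rdfProfile(traj, a, b, bin_width = cfg$bin_width %||% 0.02)
        csv(g, "rdf.csv", c(r_mid = "nm", g = "1"))
        g
      }),
      ions = run_stage("ions", function() {
        res <- ionSelectivity(traj, radius = cfg$radius %||% 1.0)
        jsonlite::write_json(res, file.path(out_dir, "ion_selectivity.json"),
                             auto_unbox = TRUE, digits = NA)
        res
      }),
      pore = run_stage("pore", function() {
        pp <- poreProfileOverTime(traj,
                                  z_range = unlist(cfg$z_range) %||% c(-2, 2),
                                  dz = cfg$dz %||% 0.1, seed = seed)
        long <- data.frame(
          time = rep(pp@times, times = length(pp@z)),
          z = rep(pp@z, each = length(pp@times)),
          radius = as.vector(pp@radius))
        csv(long, "pore_profile_frames.csv", c(z = "nm", radius = "nm"))
        csv(data.frame(z = pp@z, mean_radius = pp@mean_radius,
                       sd_radius = pp@sd_radius),
            "pore_profile_mean.csv", c(z = "nm", mean_radius = "nm"))
        g <- conductanceEstimate(pp, cfg$resistivity %||%
                                   resistivityTable()[["KCl_1.0M"]])
        jsonlite::write_json(g, file.path(out_dir, "conductance.json"),
                             auto_unbox = TRUE, digits = NA)
        list(profile = pp, conductance = g)
      }),
      tilt = run_stage("tilt", function() {
        ts <- tiltSeries(traj)
        csv(data.frame(time = frameTimes(traj), angle = ts$angles),
            "tilt.csv", c(angle = "deg"))
        ts
      }),
      com = run_stage("com", function() {
        cd <- comDisplacement(traj)
        csv(cd, "com_displacement.csv", c(time = "ps", dz = "nm"))
        cd
      }),
      residence = run_stage("residence", function() {
        rt <- residenceTimes(traj, cutoff = cfg$cutoff %||% 0.5,
                             gap_tolerance = cfg$gap_tolerance %||% 0L)
        csv(rt, "residence_times.csv", c(mean_residence_ps = "ps"))
        rt
      }),
      rmsd = run_stage("rmsd", function() {
        mid <- bilayerMidplane(getFrame(traj, 1)$positions, topology(traj))
        tm <- unlist(cfg$tm_region) %||% (mid + c(-2, 2))
        rp <- rmsdPartitioned(traj, 1L, tm)
        csv(rp, "rmsd.csv", c(rmsd_tm = "nm"))
        rp
      }),
      deform = run_stage("deform", function() {
        md <- membraneDeformationTrack(traj,
                                       lateral_bin = cfg$lateral_bin %||% 0.5,
                                       sample_every_ns = cfg$sample_every_ns)
        csv(md, "deformation.csv", c(x_mid = "nm", z = "nm"))
        md
      }),
      smd = run_stage("smd", function() {
        pargs <- cfg[setdiff(names(cfg), c("duration", "dt"))]
        pargs$seed <- seed
        tp <- do.call(smdTraceParams, pargs)
        tr <- generateSMDTrace(tp, duration = cfg$duration %||% 2,
                               dt = cfg$dt %||% 10)
        br <- smdBarriers(tr, bilayer_z = c(-tp$bilayer_half, tp$bilayer_half))
        stridx <- seq(1, length(tr@time), by = 100)
        csv(data.frame(time = tr@time[stridx], force = tr@force[stridx],
                       com_z = tr@com_z[stridx]),
            "smd_force.csv", c(force = "kJ/mol/nm", com_z = "nm"))
        jsonlite::write_json(br, file.path(out_dir, "smd_barriers.json"),
                             auto_unbox = TRUE, digits = NA)
        list(trace = tr, barriers = br)
      }))
  }
  manifest$warnings <- as.list(warn_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(manifest = manifest, results = results,
                 ground_truth = gt))
}
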