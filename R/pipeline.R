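## Run configuration, validation and the stage dispatcher.

.stageRequired <- list(
  simulate_sphere  = character(0),
  simulate_planar  = character(0),
  simulate_trace   = c("n_molecules", "Mn_Da", "Mw_Da"),
  simulate_biofilm = c("density_per_um2"),
  profile_sphere   = c("input"),
  profile_planar   = c("input"),
  nanopore         = c("input", "calibration"),
  biofilm          = c("input"),
  physics          = c("Mn_Da", "Mw_Da", "dry_height_nm"))

#' Validate a run configuration
#'
#' Checks that the stage is known and that every required field is
#' present, collecting all problems before failing, so a bad config is
#' reported in one pass rather than one error at a time.
#'
#' @param config named list with at least `stage`; stage parameters as
#'   further named entries
#' @return the config, invisibly; errors with the full list of missing
#'   fields otherwise
#' @export
validateRunConfig <- function(config) {
  problems <- character(0)
  if (is.null(config$stage)) {
    problems <- c(problems, "missing field 'stage'")
  } else if (!config$stage %in% names(.stageRequired)) {
    problems <- c(problems, sprintf(
      "unknown stage '%s' (available: %s)", config$stage,
      paste(names(.stageRequired), collapse = ", ")))
  } else {
    miss <- setdiff(.stageRequired[[config$stage]], names(config))
    if (length(miss))
      problems <- c(problems,
                    sprintf("stage '%s' missing field(s): %s", config$stage,
                            paste(miss, collapse = ", ")))
  }
  if (length(problems))
    stop(paste(c("invalid run configuration:", problems), collapse = "\n  "))
  invisible(config)
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.cfg <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

#' Run one pipeline stage from a configuration
#'
#' Executes a named stage (`simulate_sphere`, `simulate_planar`,
#' `simulate_trace`, `simulate_biofilm`, `profile_sphere`,
#' `profile_planar`, `nanopore`, `biofilm`, `physics`) with the
#' parameters in `config`, writes its outputs under `config$outdir`, and
#' returns a run report carrying a machine-readable provenance record
#' (config hash, seed, package version). Identical config + seed gives
#' identical outputs. Defaults follow the standard analysis settings:
#' 30 degree cone aperture, 50 tail bins, 5 sigma detection with a
#' 25 us - 2.5 s duration gate, 5 kHz low-pass, 5 um near-surface band.
#'
#' @param config named list or path to a JSON config file; see
#'   [validateRunConfig()]
#' @return list with `stage`, `result` (stage-specific), `outputs`
#'   (paths written) and `provenance`
#' @export
runPipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  validateRunConfig(config)
  outdir <- .cfg(config, "outdir", tempfile("habrush_run_"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- .cfg(config, "seed", NULL)
  outputs <- character(0)
  result <- switch(config$stage,
    simulate_sphere = {
      stack <- simulateSphericalBrushStack(
        heightNm = .cfg(config, "height_nm", 3750),
        lambdaNm = .cfg(config, "lambda_nm", 1500),
        I0 = .cfg(config, "I0", 100),
        noiseSd = .cfg(config, "noise_sd", 5),
        sphereRadiusNm = .cfg(config, "sphere_radius_nm", 4000),
        seed = seed)
      p <- file.path(outdir, "sphere_stack.tiff")
      writeStack(stack, p)
      outputs <- c(outputs, p, paste0(p, ".json"))
      list(stack = p, truth = stackMetadata(stack)$truth)
    },
    simulate_planar = {
      stack <- simulatePlanarBrushStack(
        heightNm = .cfg(config, "height_nm", 2620),
        lambdaNm = .cfg(config, "lambda_nm", 1000),
        I0 = .cfg(config, "I0", 100),
        noiseSd = .cfg(config, "noise_sd", 5),
        seed = seed)
      p <- file.path(outdir, "planar_stack.tiff")
      writeStack(stack, p)
      outputs <- c(outputs, p, paste0(p, ".json"))
      list(stack = p, truth = stackMetadata(stack)$truth)
    },
    simulate_trace = {
      d <- sampleMW(config$n_molecules, Mn = config$Mn_Da, Mw = config$Mw_Da,
                    seed = seed)
      sim <- simulateNanoporeTrace(d, seed = seed)
      p <- file.path(outdir, "trace.csv")
      writeTrace(sim$trace, p)
      pe <- file.path(outdir, "trace_truth.csv")
      utils::write.csv(sim$events, pe, row.names = FALSE)
      outputs <- c(outputs, p, paste0(p, ".json"), pe)
      list(trace = p, nEvents = nrow(sim$events))
    },
    simulate_biofilm = {
      sim <- simulateBiofilmStack(config$density_per_um2, seed = seed)
      p <- file.path(outdir, "biofilm_stack.tiff")
      writeStack(sim$stack, p)
      outputs <- c(outputs, p, paste0(p, ".json"))
      list(stack = p, trueBiovolumeUm3 = sim$biovolumeUm3,
           nCells = sim$nCells)
    },
    profile_sphere = {
      stack <- readStack(config$input)
      res <- sphericalBrushHeights(stack,
        apertureDeg = .cfg(config, "aperture_deg", 30),
        nTail = .cfg(config, "n_tail", 50),
        kSustain = .cfg(config, "k_sustain", 3),
        hMaxNm = .cfg(config, "h_max_nm", 6000),
        sphereRadiusNm = .cfg(config, "sphere_radius_nm", NULL))
      p <- file.path(outdir, "sphere_heights.csv")
      utils::write.csv(res$perSphere, p, row.names = FALSE)
      pc <- file.path(outdir, "sphere_cones.csv")
      utils::write.csv(res$perCone, pc, row.names = FALSE)
      outputs <- c(outputs, p, pc)
      res$summary
    },
    profile_planar = {
      stack <- readStack(config$input)
      res <- planarExclusionHeight(stack)
      p <- file.path(outdir, "planar_height.json")
      jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      outputs <- c(outputs, p)
      res
    },
    nanopore = {
      trace <- readTrace(config$input)
      cal <- fitECDCalibration(readCalibrationStandards(config$calibration))
      d <- nanoporeMWPipeline(trace, cal,
        cutoffHz = .cfg(config, "cutoff_hz", 5000),
        kSigma = .cfg(config, "k_sigma", 5),
        dminS = .cfg(config, "dmin_s", 25e-6),
        dmaxS = .cfg(config, "dmax_s", 2.5))
      p <- file.path(outdir, "events.csv")
      utils::write.csv(d@metadata$events, p, row.names = FALSE)
      pm <- file.path(outdir, "mw_moments.json")
      mom <- if (length(d) > 0) mwStats(d)
             else list(Mn = NA, Mw = NA, PDI = NA)
      jsonlite::write_json(mom, pm, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      outputs <- c(outputs, p, pm)
      mom
    },
    biofilm = {
      stack <- readStack(config$input)
      res <- biofilmBiovolume(stack,
        sigmaNm = .cfg(config, "sigma_nm", 2000),
        bandNm = .cfg(config, "band_nm", c(0, 5000)),
        perCellVolumeUm3 = .cfg(config, "per_cell_volume_um3", 1.0))
      p <- file.path(outdir, "biovolume.json")
      jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      outputs <- c(outputs, p)
      res
    },
    physics = {
      rep <- brushPhysicsReport(config$Mn_Da, config$Mw_Da,
        config$dry_height_nm,
        enzymeDensityPerUm2 = .cfg(config, "enzyme_density_per_um2", NULL))
      p <- file.path(outdir, "physics_report.json")
      jsonlite::write_json(as.list(rep), p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      outputs <- c(outputs, p)
      rep
    })
  report <- list(stage = config$stage, result = result, outputs = outputs,
                 provenance = list(
                   configHash = .configHash(config), seed = seed,
                   package = as.character(utils::packageVersion("HAbrush")),
                   timestamp = format(Sys.time(), tz = "UTC")))
  jsonlite::write_json(report["provenance"],
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
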