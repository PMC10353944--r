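## Configuration-driven end-to-end driver: chains the synthetic generators
## through the analysis stages and emits a reproducibility report whose
## numeric fields are byte-stable under a fixed configuration.

.known_keys <- list(
  top = c("seed", "stages", "output_dir", "fret", "tracking", "detachment"),
  fret = c("n_cells", "adhesions_per_cell", "force_threshold", "min_area",
           "image_shape", "sensor_photons", "background_photons",
           "resting_efficiency", "pixel_size", "noise"),
  tracking = c("n_cells", "mean_speed", "persistence_time", "dt", "duration",
               "positional_noise", "max_displacement", "min_frames"),
  detachment = c("n_before", "p_retain"))

#' Default demonstration configuration
#'
#' @return nested list accepted by [runPipeline()].
#' @export
defaultRunConfig <- function() {
  list(seed = 1L,
       stages = c("fret", "tracking", "detachment"),
       fret = list(n_cells = 4L, adhesions_per_cell = 2L,
                   force_threshold = NULL, min_area = 0.5,
                   image_shape = c(256L, 256L), sensor_photons = 2000,
                   background_photons = 100, resting_efficiency = 0.9,
                   pixel_size = 0.16, noise = TRUE),
       tracking = list(n_cells = 60L, mean_speed = 20, persistence_time = 1,
                       dt = 0.5, duration = 20, positional_noise = 0.5,
                       max_displacement = 40, min_frames = 5L),
       detachment = list(n_before = 500L, p_retain = 0.6))
}

#' Validate a pipeline configuration
#'
#' Schema and range checks; unknown keys yield a warning naming the nearest
#' valid key.  Errors are aggregated into one message.
#'
#' @param config nested list, or path to a YAML file.
#' @return the validated config, invisibly; stops with all errors otherwise.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character()
  warn_unknown <- function(keys, known, where) {
    for (k in setdiff(keys, known)) {
      near <- known[which.min(utils::adist(k, known))]
      warning(sprintf("unknown key '%s' in %s; did you mean '%s'?",
                      k, where, near))
    }
  }
  warn_unknown(names(config), .known_keys$top, "config")
  if (is.null(config$seed) || !is.finite(config$seed))
    errs <- c(errs, "seed must be a finite integer")
  stages <- config$stages
  bad <- setdiff(stages, c("fret", "tracking", "detachment"))
  if (length(bad))
    errs <- c(errs, paste("unknown stage(s):", paste(bad, collapse = ", ")))
  for (st in intersect(stages, names(.known_keys)[-1L])) {
    sc <- config[[st]]
    if (is.null(sc)) { errs <- c(errs, paste("missing section:", st)); next }
    warn_unknown(names(sc), .known_keys[[st]], st)
  }
  f <- config$fret
  if (!is.null(f)) {
    if (!is.null(f$min_area) && f$min_area <= 0)
      errs <- c(errs, "fret.min_area must be > 0")
    if (!is.null(f$resting_efficiency) &&
        (f$resting_efficiency <= 0 || f$resting_efficiency >= 1))
      errs <- c(errs, "fret.resting_efficiency must lie in (0, 1)")
    if (!is.null(f$pixel_size) && f$pixel_size <= 0)
      errs <- c(errs, "fret.pixel_size must be > 0")
  }
  tr <- config$tracking
  if (!is.null(tr)) {
    for (k in c("dt", "duration", "persistence_time", "max_displacement"))
      if (!is.null(tr[[k]]) && tr[[k]] <= 0)
        errs <- c(errs, sprintf("tracking.%s must be > 0", k))
  }
  de <- config$detachment
  if (!is.null(de) && !is.null(de$p_retain) &&
      (de$p_retain < 0 || de$p_retain > 1))
    errs <- c(errs, "detachment.p_retain must lie in [0, 1]")
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  invisible(config)
}

#' Run the demonstration pipeline
#'
#' Generates synthetic data for the selected stages and runs the matching
#' analyses end to end: tension-sensor images through efficiency, force,
#' segmentation and per-cell profiles; migration tracks through linking and
#' speed summaries; a detachment assay through percent remaining.  The
#' report records every seed and parameter; rerunning with the same config
#' reproduces every numeric field exactly.
#'
#' @param config nested list (see [defaultRunConfig()]) or YAML path.
#' @return list of class \code{"RunReport"} with one entry per stage
#'   (parameters + statistics) plus \code{seed} and \code{config}.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  config <- validateConfig(config)
  seed <- as.integer(config$seed)
  report <- list(seed = seed, stages = list())

  if ("fret" %in% config$stages) {
    f <- config$fret
    cal <- defaultCalibration()
    cfg <- simConfig(seed = seed, imageShape = f$image_shape,
                     pixelSize = f$pixel_size,
                     backgroundPhotons = f$background_photons,
                     sensorPhotons = f$sensor_photons,
                     restingEfficiency = f$resting_efficiency,
                     calibration = cal)
    sim <- simulateTensionImages(cfg, nCells = f$n_cells,
                                 adhesionsPerCell = f$adhesions_per_cell,
                                 noise = isTRUE(f$noise))
    E <- computeEfficiency(sim$donor, sim$acceptor,
                           bgDonor = f$background_photons,
                           bgAcceptor = f$background_photons,
                           intensityFloor = f$sensor_photons / 4,
                           pixelSize = f$pixel_size)
    thr <- f$force_threshold
    if (is.null(thr))  # default: force where E drops 0.1 below resting
      thr <- approx(rev(cal@efficiency), rev(cal@force),
                    xout = f$resting_efficiency - 0.1, rule = 2)$y
    Fm <- forceFromEfficiency(E, cal)
    ad <- segmentAdhesions(Fm, sim$cellMask, forceThreshold = thr,
                           minArea = f$min_area, efficiencyMap = E)
    prof <- profileCells(ad, seq_len(f$n_cells))
    report$stages$fret <- list(
      parameters = f[!vapply(f, is.null, logical(1))],
      force_threshold_pN = thr,
      n_adhesions_detected = length(ad),
      n_adhesions_truth = nrow(sim$truth),
      mean_adhesion_force_pN = if (length(ad)) mean(adhesionStats(ad)$mean_force_pN) else NA_real_,
      prop_force_producing = mean(prof$force_producing))
  }

  if ("tracking" %in% config$stages) {
    tr <- config$tracking
    det <- simulateTracks(tr$n_cells, tr$mean_speed, tr$persistence_time,
                          tr$dt, tr$duration, tr$positional_noise,
                          seed = seed + 1L)
    linked <- linkDetections(det[, c("frame", "t", "x", "y")],
                             maxDisplacement = tr$max_displacement)
    st <- trackSpeeds(linked, minFrames = tr$min_frames)
    report$stages$tracking <- list(
      parameters = tr,
      n_tracks = nrow(st),
      mean_speed_um_h = mean(st$mean_speed_um_h))
  }

  if ("detachment" %in% config$stages) {
    de <- config$detachment
    sim <- simulateDetachment(de$n_before, de$p_retain, seed = seed + 2L)
    report$stages$detachment <- list(
      parameters = de,
      percent_remaining = percentRemaining(nrow(sim$before), nrow(sim$after)))
  }

  report$config <- config
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport (seed %d): stages %s\n", x$seed,
              paste(names(x$stages), collapse = ", ")))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    stat <- st[setdiff(names(st), "parameters")]
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s = %.6g", names(stat),
                              vapply(stat, function(v) as.numeric(v)[1], 0)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' @param config nested list.
#' @param path file path.
#' @return [writeRunConfig()] the path; [readRunConfig()] the validated
#'   config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) validateConfig(yaml::read_yaml(path))
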