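# Orchestration: run configuration, per-condition analysis, and
# two-condition comparison, each reproducible from (config, seed).

#' Default run configuration
#'
#' A nested list mirroring the analysis stages: \code{geometry} (acquisition
#' constants), \code{tracking} (detection/linking parameters),
#' \code{kinetics} (lags, fit range, distribution lag and tail threshold)
#' and \code{conditions} (generative models). All values can be overridden
#' by a YAML config file via [readRunConfig()].
#'
#' @param seed integer master seed.
#' @param outputDir optional directory for artifacts (NULL = in-memory only).
#' @return named list.
#' @export
defaultRunConfig <- function(seed = 1L, outputDir = NULL) {
  list(
    geometry = list(
      peak_energy_keV = 15.8,
      fractional_bandwidth = 0.08,
      camera_length_mm = 50,
      pixel_pitch_mm = 0.08,
      detector_shape_px = c(512L, 512L),
      beam_center_px = NULL, # default: detector centre
      frame_interval_ms = 0.1,
      # acquisition metadata: 36 positions, 10 ms/record, 100 us resolution
      positions = 36L, record_ms = 10),
    tracking = list(min_separation = 5, threshold_k = 5,
                    max_displacement = 10, min_length = 2),
    kinetics = list(max_lag_frames = 7L, fit_lag_range = c(0.1, 0.7),
                    dt_ms = 0.7, tail_threshold_mrad = 10,
                    n_bins = 60L, edge_range_mrad = c(1e-2, 1e3),
                    suppression_factor = 4),
    conditions = list(CCh = cchModel(), BGT = bgtModel()),
    mode = "angular",
    seed = as.integer(seed),
    outputDir = outputDir)
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file whose keys override the defaults of
#' [defaultRunConfig()]; condition models may be given as nested lists with
#' fields \code{label}, \code{ligand}, \code{n_trajectories},
#' \code{mean_lifetime_ms} and a \code{populations} list.
#'
#' @param path YAML file path.
#' @return named list as from [defaultRunConfig()].
#' @export
readRunConfig <- function(path) {
  cfg <- defaultRunConfig()
  y <- yaml::read_yaml(path)
  for (block in intersect(names(y), c("geometry", "tracking", "kinetics"))) {
    for (k in names(y[[block]])) cfg[[block]][[k]] <- y[[block]][[k]]
  }
  for (k in intersect(names(y), c("mode", "seed", "outputDir")))
    cfg[[k]] <- y[[k]]
  if (!is.null(y$conditions)) {
    cfg$conditions <- lapply(y$conditions, function(cm) {
      pops <- lapply(cm$populations, function(p)
        populationParams(p$weight %||% 1, dTheta = p$d_theta,
                         dChi = p$d_chi, sigmaTheta = p$sigma_theta,
                         sigmaChi = p$sigma_chi))
      conditionModel(cm$label, ligand = cm$ligand %||% "",
                     populations = pops,
                     nTrajectories = cm$n_trajectories,
                     meanLifetime = cm$mean_lifetime_ms %||% 0.7,
                     frameInterval = cm$frame_interval_ms %||% 0.1,
                     maxDuration = cm$max_duration_ms %||% 10)
    })
    names(cfg$conditions) <- vapply(cfg$conditions, function(m) m@label,
                                    character(1))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

configGeometry <- function(config) {
  g <- config$geometry
  shape <- as.integer(g$detector_shape_px)
  beamlineGeometry(
    peakEnergy = g$peak_energy_keV,
    fractionalBandwidth = g$fractional_bandwidth,
    cameraLength = g$camera_length_mm,
    pixelPitch = g$pixel_pitch_mm,
    detectorShape = shape,
    beamCenter = if (is.null(g$beam_center_px)) (shape + 1) / 2
                 else as.numeric(g$beam_center_px),
    frameInterval = g$frame_interval_ms)
}

configEdges <- function(config) {
  k <- config$kinetics
  defaultLogEdges(k$n_bins, k$edge_range_mrad[1], k$edge_range_mrad[2])
}

#' Analyze one ligand condition
#'
#' Runs the full chain for one condition: simulate angular trajectories (or,
#' in movie mode, simulate, render, detect, link, filter and convert back to
#' angles), then compute per-axis ensemble MSD curves, weighted linear fits,
#' the displacement distribution at the configured lag, the tail fraction
#' beyond the configured threshold, and the two-axis density map. Idempotent
#' for a fixed (config, seed); artifacts are written under
#' \code{config$outputDir} when set.
#'
#' @param config list from [defaultRunConfig()] or [readRunConfig()].
#' @param conditionLabel label of the condition to run.
#' @return list with elements \code{trajectories}
#'   ([AngularTrajectorySet-class]), \code{msd} (per-axis [MSDCurve-class]),
#'   \code{fits} (per-axis [MSDFit-class]), \code{distributions},
#'   \code{tailFractions}, \code{map} ([DensityMap2D-class]),
#'   \code{nTrajectories}, \code{meanTrackMs} and, in movie mode,
#'   \code{trackingLog}.
#' @export
runCondition <- function(config, conditionLabel) {
  model <- config$conditions[[conditionLabel]]
  if (is.null(model))
    stop("[config] condition not in config: ", conditionLabel)
  geom <- configGeometry(config)
  trackingLog <- NULL
  ats <- simulateAngularTrajectories(model, seed = config$seed)
  if (identical(config$mode, "movie")) {
    rc <- renderConfig(geometry = geom,
                       seed = deriveSeed(config$seed, conditionLabel, 0L))
    rendered <- renderMovie(ats, rc)
    spots <- detectMovieSpots(rendered$movie,
                              minSeparation = config$tracking$min_separation,
                              thresholdK = config$tracking$threshold_k)
    linked <- linkSpots(spots, config$tracking$max_displacement)
    tracks <- filterTrajectories(linked, geom,
                                 minLength = config$tracking$min_length,
                                 verbose = FALSE)
    trackingLog <- attr(tracks, "trackingLog")
    if (!nrow(tracks))
      stop("[tracking] no trajectories survived filtering for ",
           conditionLabel)
    ats <- toAngular(tracks, geom, conditionLabel = conditionLabel)
  }
  k <- config$kinetics
  edges <- configEdges(config)
  axes <- c("theta", "chi")
  msd <- lapply(axes, function(a) ensembleMSD(ats, a, k$max_lag_frames))
  names(msd) <- axes
  fits <- lapply(msd, fitMSDLinear, lagRange = k$fit_lag_range)
  dists <- lapply(axes, function(a)
    displacementDistribution(ats, a, dt = k$dt_ms, edges = edges))
  names(dists) <- axes
  tails <- vapply(axes, function(a)
    tailFraction(ats, a, dt = k$dt_ms, threshold = k$tail_threshold_mrad),
    numeric(1))
  map <- densityMap2D(ats, dt = k$dt_ms, thetaEdges = edges,
                      chiEdges = edges)
  lens <- table(ats@data$trajectory_id)
  res <- list(
    conditionLabel = conditionLabel,
    trajectories = ats, msd = msd, fits = fits,
    distributions = dists, tailFractions = tails, map = map,
    nTrajectories = nTrajectories(ats),
    meanTrackMs = mean(lens) * ats@frameInterval,
    trackingLog = trackingLog)
  if (!is.null(config$outputDir))
    writeConditionArtifacts(res, config)
  res
}

fitAsList <- function(fit) {
  list(slope = fit@slope, slope_se = fit@slopeSE,
       intercept = fit@intercept, intercept_se = fit@interceptSE,
       lag_range_ms = fit@lagRange)
}

conditionReport <- function(res) {
  list(
    condition = res$conditionLabel,
    n_trajectories = res$nTrajectories,
    mean_track_ms = res$meanTrackMs,
    n_pairs_per_lag = as.list(stats::setNames(
      res$msd$theta@nPairs, sprintf("lag_%g", res$msd$theta@lags))),
    fits = lapply(res$fits, fitAsList),
    tail_fractions = as.list(res$tailFractions))
}

writeConditionArtifacts <- function(res, config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(config$outputDir, res$conditionLabel)
  writeAngularCSV(res$trajectories, paste0(base, "_angular.csv"))
  for (a in names(res$msd))
    utils::write.csv(msdTable(res$msd[[a]]),
                     paste0(base, "_msd_", a, ".csv"), row.names = FALSE)
  writeDensityMapCSV(res$map, paste0(base, "_map.csv"))
  writeReportJSON(conditionReport(res), paste0(base, "_report.json"))
  grDevices::png(paste0(base, "_msd.png"), width = 700, height = 500)
  plotMSD(res$msd, res$fits)
  grDevices::dev.off()
  invisible(base)
}

#' Write a density map as a CSV matrix with edge headers
#'
#' @param map a [DensityMap2D-class].
#' @param path CSV file path.
#' @export
writeDensityMapCSV <- function(map, path) {
  m <- map@mass
  rownames(m) <- sprintf("theta_%.6g", map@thetaEdges[-length(map@thetaEdges)])
  colnames(m) <- sprintf("chi_%.6g", map@chiEdges[-length(map@chiEdges)])
  utils::write.csv(m, path)
  invisible(path)
}

#' Compare two ligand conditions
#'
#' Runs both conditions on identical binning and lags, then assembles the
#' cross-condition summary: per-axis slope ratios, twist/tilt suppression
#' flags (ratio beyond \code{suppression_factor} with non-overlapping 3 SE
#' intervals), tail fractions past the configured threshold, and the
#' difference density map with its net mass in the 10-50 mrad twist band.
#'
#' @param config list from [defaultRunConfig()] or [readRunConfig()].
#' @param labelA,labelB condition labels; the difference map is A - B.
#' @return list with \code{conditions} (the two [runCondition()] results),
#'   \code{report} (the serializable comparison report) and \code{diffMap}.
#' @export
compareConditions <- function(config, labelA = "CCh", labelB = "BGT") {
  resA <- runCondition(config, labelA)
  resB <- runCondition(config, labelB)
  sf <- config$kinetics$suppression_factor %||% 4
  axes <- c("theta", "chi")
  perAxis <- lapply(axes, function(a) {
    fa <- resA$fits[[a]]; fb <- resB$fits[[a]]
    ratio <- fa@slope / fb@slope
    sep <- (fa@slope - 3 * fa@slopeSE) > (fb@slope + 3 * fb@slopeSE) ||
      (fb@slope - 3 * fb@slopeSE) > (fa@slope + 3 * fa@slopeSE)
    list(slope_ratio = ratio,
         intervals_separated_3se = sep,
         suppressed = ratio > sf && sep)
  })
  names(perAxis) <- axes
  diff <- differenceMap(resA$map, resB$map)
  cfgJson <- jsonlite::toJSON(config[c("geometry", "tracking", "kinetics",
                                       "mode", "seed")],
                              auto_unbox = TRUE, force = TRUE)
  report <- list(
    condition_a = conditionReport(resA),
    condition_b = conditionReport(resB),
    slope_ratios = lapply(perAxis, `[[`, "slope_ratio"),
    chi_suppressed = perAxis$chi$suppressed,
    theta_suppressed = perAxis$theta$suppressed,
    per_axis = perAxis,
    tail_fraction_a = as.list(resA$tailFractions),
    tail_fraction_b = as.list(resB$tailFractions),
    diff_band_mass_10_50 = bandMass(diff, 10, 50),
    provenance = list(config_hash = fnv1aHash(as.character(cfgJson)),
                      seed = config$seed,
                      version = as.character(utils::packageVersion("DXTracker"))))
  if (!is.null(config$outputDir)) {
    writeDensityMapCSV(diff, file.path(config$outputDir,
                                       paste0(labelA, "_minus_", labelB,
                                              "_map.csv")))
    writeReportJSON(report, file.path(config$outputDir, "comparison.json"))
  }
  list(conditions = list(a = resA, b = resB), report = report,
       diffMap = diff)
}

#' Plot MSD curves with their linear fits
#'
#' Base-graphics plot of per-axis ensemble MSD versus lag (mrad^2 vs ms)
#' with the weighted linear fits overlaid.
#'
#' @param msd named list of [MSDCurve-class] (theta, chi).
#' @param fits matching named list of [MSDFit-class].
#' @export
plotMSD <- function(msd, fits = NULL) {
  cols <- c(theta = "forestgreen", chi = "purple")
  ylim <- range(0, unlist(lapply(msd, function(c) c@msd)))
  xlim <- range(0, unlist(lapply(msd, function(c) c@lags)))
  plot(NA, xlim = xlim, ylim = ylim, xlab = "lag (ms)",
       ylab = expression(MSD ~ (mrad^2)),
       main = msd[[1]]@conditionLabel)
  for (a in names(msd)) {
    graphics::points(msd[[a]]@lags, msd[[a]]@msd, col = cols[[a]], pch = 16)
    if (!is.null(fits))
      graphics::abline(fits[[a]]@intercept, fits[[a]]@slope,
                       col = cols[[a]], lty = 2)
  }
  graphics::legend("topleft", legend = names(msd), col = cols[names(msd)],
                   pch = 16, bty = "n")
}
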