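# Forward model: render angular trajectories into synthetic detector movies.
# Each crystal sits on one ring at a random initial azimuth with its lattice
# tilted to the peak-energy Bragg angle; tilt moves the spot radially, twist
# azimuthally, and the spot disappears whenever its Bragg-matched wavelength
# leaves the energy band (natural track termination).

#' Construct a render configuration
#'
#' @param geometry a [BeamlineGeometry-class].
#' @param psfSigma Gaussian spot width, px.
#' @param photonsPerSpot mean integrated photon count per spot per frame.
#' @param background mean background, counts/px.
#' @param shotNoise apply Poisson statistics; FALSE gives a deterministic
#'   noise-free render.
#' @param seed integer seed for the render stream.
#' @return a [RenderConfig-class].
#' @export
renderConfig <- function(geometry = beamlineGeometry(), psfSigma = 1.5,
                         photonsPerSpot = 2000, background = 2,
                         shotNoise = TRUE, seed = 1L) {
  new("RenderConfig", geometry = geometry, psfSigma = psfSigma,
      photonsPerSpot = photonsPerSpot, background = background,
      shotNoise = shotNoise, seed = as.integer(seed))
}

# add one Gaussian spot of integrated intensity `photons` at (row, col)
addSpot <- function(frame, row, col, photons, psfSigma, shotNoise) {
  w <- ceiling(4 * psfSigma)
  nr <- nrow(frame); nc <- ncol(frame)
  rr <- max(1, floor(row - w)):min(nr, ceiling(row + w))
  cc <- max(1, floor(col - w)):min(nc, ceiling(col + w))
  if (!length(rr) || !length(cc)) return(frame)
  pr <- exp(-(rr - row)^2 / (2 * psfSigma^2))
  pc <- exp(-(cc - col)^2 / (2 * psfSigma^2))
  prof <- photons * outer(pr, pc) / (2 * pi * psfSigma^2)
  if (shotNoise) prof[] <- stats::rpois(length(prof), prof)
  frame[rr, cc] <- frame[rr, cc] + prof
  frame
}

#' Render angular trajectories into a detector movie
#'
#' Crystals are assigned alternately to the Au(111)/Au(200) rings (or keep
#' the trajectory's \code{ring} labels) with a uniformly random initial
#' azimuth. At each frame the spot centre is the detector position implied by
#' the trajectory's (tilt, twist) through the beamline geometry; the spot is
#' drawn as a 2D Gaussian with Poisson-sampled photons over Poisson
#' background (or deterministically when \code{shotNoise = FALSE}), and is
#' omitted from frames where its tilt-implied Bragg wavelength leaves the
#' energy band.
#'
#' @param object an [AngularTrajectorySet-class].
#' @param render a [RenderConfig-class].
#' @param initialAzimuth optional vector of initial azimuths (radians), one
#'   per trajectory; by default drawn uniformly from the render stream.
#' @return list with \code{movie} (a [DetectorMovie-class]) and \code{truth}
#'   (data.frame of true spot centres per visible frame: trajectory_id,
#'   frame, t_ms, row_px, col_px, theta_mrad, chi_mrad, ring).
#' @export
renderMovie <- function(object, render = renderConfig(),
                        initialAzimuth = NULL) {
  stopifnot(is(object, "AngularTrajectorySet"), is(render, "RenderConfig"))
  geom <- render@geometry
  tau <- geom@frameInterval
  planes <- list(Au111 = au111(), Au200 = au200())
  eHi <- geom@peakEnergy * (1 + geom@fractionalBandwidth / 2)
  eLo <- geom@peakEnergy * (1 - geom@fractionalBandwidth / 2)
  df <- object@data
  ids <- unique(df$trajectory_id)
  nT <- max(round(df$t_ms / tau)) + 1L
  shape <- geom@detectorShape
  frames <- array(0, dim = c(shape[1], shape[2], nT))
  set.seed(deriveSeed(render@seed, "render", 0L))
  chi0 <- if (is.null(initialAzimuth)) stats::runif(length(ids), -pi, pi)
          else rep_len(initialAzimuth, length(ids))
  truth <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    tr <- df[df$trajectory_id == ids[j], , drop = FALSE]
    ring <- tr$ring[1]
    plane <- planes[[ring]]
    if (is.null(plane)) stop("unknown ring label: ", ring)
    thB0 <- braggAngle(plane, geom@peakEnergy)
    thC <- thB0 + tr$theta_mrad / 1000 # instantaneous crystal tilt
    lam <- 2 * plane@dSpacing * sin(thC) # Bragg-matched wavelength, A
    visible <- lam >= HC_KEV_A / eHi & lam <= HC_KEV_A / eLo
    # once the crystal leaves the band the track ends physically
    if (any(!visible)) {
      cut <- which(!visible)[1]
      visible[cut:length(visible)] <- FALSE
    }
    pos <- polarToDetector(2 * thC, chi0[j] + tr$chi_mrad / 1000, geom)
    fr <- round(tr$t_ms / tau) + 1L
    onDet <- pos$row >= 1 & pos$row <= shape[1] &
      pos$col >= 1 & pos$col <= shape[2]
    visible <- visible & onDet
    for (k in which(visible)) {
      photons <- if (render@shotNoise)
        stats::rpois(1, render@photonsPerSpot) else render@photonsPerSpot
      frames[, , fr[k]] <- addSpot(frames[, , fr[k]], pos$row[k], pos$col[k],
                                   photons, render@psfSigma,
                                   render@shotNoise)
    }
    if (any(visible))
      truth[[j]] <- data.frame(
        trajectory_id = ids[j], frame = fr[visible],
        t_ms = tr$t_ms[visible],
        row_px = pos$row[visible], col_px = pos$col[visible],
        theta_mrad = tr$theta_mrad[visible], chi_mrad = tr$chi_mrad[visible],
        ring = ring)
  }
  if (render@background > 0) {
    if (render@shotNoise) {
      frames[] <- frames + stats::rpois(length(frames), render@background)
    } else {
      frames[] <- frames + render@background
    }
  }
  frames[] <- pmin(round(frames), 65535)
  movie <- new("DetectorMovie", frames = frames, geometry = geom,
               conditionLabel = object@conditionLabel)
  truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  rownames(truth) <- NULL
  list(movie = movie, truth = truth)
}

#' Generate a reproducible multi-condition dataset on disk
#'
#' Angular mode writes one trajectory CSV per condition; movie mode also
#' renders and writes a multi-page 16-bit TIFF movie plus a ground-truth CSV
#' per condition. A manifest JSON records every parameter and derived seed,
#' so the dataset is fully determined by \code{seed}.
#'
#' @param conditions list of [ConditionModel-class] with distinct labels.
#' @param outDir output directory (created if missing).
#' @param mode \code{"angular"} or \code{"movie"}.
#' @param seed integer master seed.
#' @param render a [RenderConfig-class] (movie mode).
#' @return invisibly, the manifest list.
#' @export
makeDataset <- function(conditions, outDir, mode = c("angular", "movie"),
                        seed = 1L, render = renderConfig()) {
  mode <- match.arg(mode)
  if (!length(conditions)) stop("empty condition list")
  labels <- vapply(conditions, function(m) m@label, character(1))
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(mode = mode, seed = seed, conditions = list())
  for (m in conditions) {
    condSeed <- deriveSeed(seed, m@label, 0L)
    sim <- simulateAngularTrajectories(m, seed = seed, returnTruth = TRUE)
    ats <- sim$trajectories
    base <- file.path(outDir, m@label)
    writeAngularCSV(ats, paste0(base, "_angular.csv"))
    utils::write.csv(sim$truth, paste0(base, "_truth.csv"),
                     row.names = FALSE)
    files <- list(angular = paste0(base, "_angular.csv"),
                  truth = paste0(base, "_truth.csv"))
    if (mode == "movie") {
      rc <- render
      rc@seed <- condSeed
      rm <- renderMovie(ats, rc)
      writeMovieTIFF(rm$movie, paste0(base, "_movie.tif"))
      utils::write.csv(rm$truth, paste0(base, "_movie_truth.csv"),
                       row.names = FALSE)
      files$movie <- paste0(base, "_movie.tif")
      files$movieTruth <- paste0(base, "_movie_truth.csv")
    }
    manifest$conditions[[m@label]] <- list(
      label = m@label, ligand = m@ligand,
      nTrajectories = m@nTrajectories, meanLifetime = m@meanLifetime,
      frameInterval = m@frameInterval, maxDuration = m@maxDuration,
      populations = lapply(m@populations, function(p) list(
        weight = p@weight, dTheta = p@dTheta, dChi = p@dChi,
        sigmaTheta = p@sigmaTheta, sigmaChi = p@sigmaChi)),
      seed = condSeed, files = files)
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
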