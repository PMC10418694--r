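#' @import methods
NULL

#' Beamline and detector geometry for a DXT experiment
#'
#' Holds the acquisition geometry through which every conversion between
#' detector pixels and scattering angles flows: the quasi-monochromatic beam
#' (peak energy and fractional energy bandwidth), the flat-detector camera
#' length, the pixel grid, and the frame interval of the time-resolved
#' recording.
#'
#' @slot peakEnergy photon energy at the bandwidth centre, keV.
#' @slot fractionalBandwidth full energy width \eqn{\Delta E/E} (dimensionless).
#' @slot cameraLength sample-to-detector distance, mm.
#' @slot pixelPitch detector pixel size, mm per pixel.
#' @slot beamCenter direct-beam position, (row, col) in pixels.
#' @slot detectorShape detector grid, (rows, cols) in pixels.
#' @slot frameInterval time per frame, ms.
#' @slot beamDiameter beam size at the sample, mm (metadata only).
#'
#' @seealso [beamlineGeometry()] for the user-facing constructor with the
#'   packaged acquisition defaults.
#' @exportClass BeamlineGeometry
setClass("BeamlineGeometry",
  representation(
    peakEnergy = "numeric",
    fractionalBandwidth = "numeric",
    cameraLength = "numeric",
    pixelPitch = "numeric",
    beamCenter = "numeric",
    detectorShape = "integer",
    frameInterval = "numeric",
    beamDiameter = "numeric"
  )
)

setValidity("BeamlineGeometry", function(object) {
  msg <- character()
  if (length(object@peakEnergy) != 1 || object@peakEnergy <= 0)
    msg <- c(msg, "peakEnergy must be a single positive value (keV)")
  if (length(object@fractionalBandwidth) != 1 ||
      object@fractionalBandwidth <= 0 || object@fractionalBandwidth >= 1)
    msg <- c(msg, "fractionalBandwidth must lie in (0, 1)")
  if (length(object@cameraLength) != 1 || object@cameraLength <= 0)
    msg <- c(msg, "cameraLength must be positive (mm)")
  if (length(object@pixelPitch) != 1 || object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be positive (mm/px)")
  if (length(object@detectorShape) != 2 || any(object@detectorShape < 1))
    msg <- c(msg, "detectorShape must be two positive integers (rows, cols)")
  if (length(object@beamCenter) != 2 ||
      any(object@beamCenter < 1) || any(object@beamCenter > object@detectorShape))
    msg <- c(msg, "beamCenter must lie inside detectorShape")
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be positive (ms)")
  if (length(msg)) msg else TRUE
})

#' Gold lattice plane producing a diffraction ring
#'
#' @slot name plane label, \code{"Au111"} or \code{"Au200"}.
#' @slot dSpacing lattice plane spacing, Angstrom.
#' @exportClass CrystalPlane
setClass("CrystalPlane",
  representation(name = "character", dSpacing = "numeric")
)

setValidity("CrystalPlane", function(object) {
  if (length(object@dSpacing) != 1 || object@dSpacing <= 0)
    return("dSpacing must be a single positive value (Angstrom)")
  TRUE
})

#' Radial acceptance band of a diffraction ring
#'
#' The range of detector radii over which spots from one lattice plane can
#' appear, set by the beam's energy bandwidth: the high band-edge energy maps
#' to the inner radius, the low edge to the outer radius.
#'
#' @slot plane the [CrystalPlane-class] generating the ring.
#' @slot rMin,rMax inner and outer radius, mm from the beam centre.
#' @exportClass RingBand
setClass("RingBand",
  representation(plane = "CrystalPlane", rMin = "numeric", rMax = "numeric")
)

setValidity("RingBand", function(object) {
  if (!(object@rMin > 0 && object@rMax > object@rMin))
    return("require 0 < rMin < rMax")
  TRUE
})

#' Time-resolved detector movie
#'
#' A stack of non-negative detector frames plus the geometry and condition
#' metadata needed to interpret spot positions.
#'
#' @slot frames numeric array \code{[rows, cols, T]} of intensities (counts).
#' @slot geometry the [BeamlineGeometry-class] of the acquisition.
#' @slot conditionLabel free-text ligand condition (e.g. "CCh", "BGT").
#' @exportClass DetectorMovie
setClass("DetectorMovie",
  representation(
    frames = "array",
    geometry = "BeamlineGeometry",
    conditionLabel = "character"
  )
)

setValidity("DetectorMovie", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3) return("frames must be a [rows, cols, T] array")
  if (d[3] < 2) return("movie must have at least 2 frames")
  if (any(!is.finite(object@frames)) || any(object@frames < 0))
    return("all intensities must be finite and non-negative")
  if (!all(d[1:2] == object@geometry@detectorShape))
    return("frame shape must match geometry detectorShape")
  TRUE
})

#' Set of angular trajectories for one condition
#'
#' The unit of all kinetic analysis: per-trajectory time series of tilting
#' (theta) and twisting (chi) angles in mrad, relative to each trajectory's
#' first observed sample. Stored long-format with one row per sample.
#'
#' @slot data data.frame with columns \code{trajectory_id}, \code{t_ms},
#'   \code{theta_mrad}, \code{chi_mrad}, \code{ring}.
#' @slot frameInterval frame interval, ms.
#' @slot conditionLabel ligand condition label.
#' @exportClass AngularTrajectorySet
setClass("AngularTrajectorySet",
  representation(
    data = "data.frame",
    frameInterval = "numeric",
    conditionLabel = "character"
  )
)

setValidity("AngularTrajectorySet", function(object) {
  df <- object@data
  need <- c("trajectory_id", "t_ms", "theta_mrad", "chi_mrad", "ring")
  if (!all(need %in% names(df)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (nrow(df)) {
    tau <- object@frameInterval
    bad <- vapply(split(df, df$trajectory_id), function(tr) {
      n <- nrow(tr)
      n < 2 ||
        abs(tr$t_ms[1]) > 1e-9 ||
        abs(tr$theta_mrad[1]) > 1e-9 || abs(tr$chi_mrad[1]) > 1e-9 ||
        (n > 1 && any(abs(diff(tr$t_ms) - tau) > 1e-6 * tau))
    }, logical(1))
    if (any(bad))
      return(paste0("trajectories must start at (t,theta,chi) = (0,0,0), have ",
                    "length >= 2 and uniform t steps of frameInterval; ",
                    "offending ids: ",
                    paste(names(bad)[bad][seq_len(min(3, sum(bad)))],
                          collapse = ", ")))
  }
  TRUE
})

#' Ensemble mean-square-displacement curve
#'
#' Per-axis ensemble MSD versus time lag, pooled over all ordered in-trajectory
#' sample pairs across all trajectories, with the contributing pair count per
#' lag.
#'
#' @slot axis \code{"theta"} or \code{"chi"}.
#' @slot lags time lags, ms.
#' @slot msd mean square displacement per lag, mrad^2.
#' @slot nPairs contributing displacement-pair count per lag.
#' @slot conditionLabel ligand condition label.
#' @exportClass MSDCurve
setClass("MSDCurve",
  representation(
    axis = "character",
    lags = "numeric",
    msd = "numeric",
    nPairs = "numeric",
    conditionLabel = "character"
  )
)

setValidity("MSDCurve", function(object) {
  if (!object@axis %in% c("theta", "chi"))
    return("axis must be 'theta' or 'chi'")
  if (length(object@lags) != length(object@msd) ||
      length(object@lags) != length(object@nPairs))
    return("lags, msd and nPairs must have equal length")
  if (any(object@msd < 0)) return("msd must be non-negative")
  if (any(object@lags <= 0) || is.unsorted(object@lags, strictly = TRUE))
    return("lags must be positive and strictly increasing")
  if (is.unsorted(rev(object@nPairs)))
    return("nPairs must be non-increasing in lag")
  TRUE
})

#' Weighted linear fit to an MSD curve
#'
#' Slope (MSD growth rate, \eqn{2D} for simple rotational diffusion) and
#' intercept (static-noise offset, \eqn{2\sigma^2}) with standard errors from
#' a pair-count-weighted least-squares fit.
#'
#' @slot slope,slopeSE slope and its SE, mrad^2/ms.
#' @slot intercept,interceptSE intercept and its SE, mrad^2.
#' @slot lagRange fitted lag range (min, max), ms.
#' @slot axis \code{"theta"} or \code{"chi"}.
#' @slot conditionLabel ligand condition label.
#' @exportClass MSDFit
setClass("MSDFit",
  representation(
    slope = "numeric", slopeSE = "numeric",
    intercept = "numeric", interceptSE = "numeric",
    lagRange = "numeric", axis = "character",
    conditionLabel = "character"
  )
)

setValidity("MSDFit", function(object) {
  if (object@slopeSE < 0 || object@interceptSE < 0)
    return("standard errors must be non-negative")
  TRUE
})

#' Distribution of absolute angular displacements at a fixed lag
#'
#' @slot axis \code{"theta"} or \code{"chi"}.
#' @slot dt time lag, ms.
#' @slot binEdges log-spaced |displacement| bin edges, mrad.
#' @slot mass probability mass per bin.
#' @slot underflow,overflow mass below the first / above the last edge.
#' @slot conditionLabel ligand condition label.
#' @exportClass DisplacementDistribution
setClass("DisplacementDistribution",
  representation(
    axis = "character", dt = "numeric",
    binEdges = "numeric", mass = "numeric",
    underflow = "numeric", overflow = "numeric",
    conditionLabel = "character"
  )
)

setValidity("DisplacementDistribution", function(object) {
  if (length(object@mass) != length(object@binEdges) - 1)
    return("mass must have length(binEdges) - 1")
  tot <- sum(object@mass) + object@underflow + object@overflow
  if (abs(tot - 1) > 1e-12)
    return("mass + underflow + overflow must sum to 1")
  TRUE
})

#' Two-axis probability-density map (or two-condition difference map)
#'
#' Joint histogram of (|dtheta|, |dchi|) displacement pairs at a fixed lag on
#' log-spaced edges. A single-condition map sums to 1; a difference map
#' (conditionLabel of the form "A - B") sums to 0.
#'
#' @slot dt time lag, ms.
#' @slot thetaEdges,chiEdges log-spaced bin edges, mrad.
#' @slot mass matrix of probability mass, rows = theta bins, cols = chi bins.
#' @slot conditionLabel condition label, or "A - B" for a difference map.
#' @slot isDifference logical flag.
#' @exportClass DensityMap2D
setClass("DensityMap2D",
  representation(
    dt = "numeric",
    thetaEdges = "numeric", chiEdges = "numeric",
    mass = "matrix",
    conditionLabel = "character",
    isDifference = "logical"
  )
)

setValidity("DensityMap2D", function(object) {
  if (!all(dim(object@mass) ==
           c(length(object@thetaEdges) - 1, length(object@chiEdges) - 1)))
    return("mass dimensions must match bin edges")
  tot <- sum(object@mass)
  if (object@isDifference) {
    if (abs(tot) > 1e-12) return("difference map must sum to 0")
  } else {
    if (abs(tot - 1) > 1e-12) return("single-condition map must sum to 1")
  }
  TRUE
})

#' Parameters of one motional population
#'
#' One component of a condition's generative mixture: independent rotational
#' Brownian motion per axis plus static Gaussian measurement noise.
#'
#' @slot weight mixture fraction in \[0, 1\].
#' @slot dTheta,dChi rotational diffusion coefficients, mrad^2/ms.
#' @slot sigmaTheta,sigmaChi static noise SD per axis, mrad.
#' @exportClass PopulationParams
setClass("PopulationParams",
  representation(
    weight = "numeric",
    dTheta = "numeric", dChi = "numeric",
    sigmaTheta = "numeric", sigmaChi = "numeric"
  )
)

setValidity("PopulationParams", function(object) {
  if (object@weight < 0 || object@weight > 1)
    return("weight must lie in [0, 1]")
  if (object@dTheta < 0 || object@dChi < 0)
    return("diffusion coefficients must be non-negative")
  if (object@sigmaTheta < 0 || object@sigmaChi < 0)
    return("noise SDs must be non-negative")
  TRUE
})

#' Generative model for one ligand condition
#'
#' Everything needed to simulate the angular trajectories of one condition:
#' the mixture of motional populations, the trajectory count, the mean
#' trackable lifetime, and the sampling clock.
#'
#' @slot label condition label (e.g. "CCh").
#' @slot ligand ligand description (metadata, e.g. "carbamylcholine 2 uM").
#' @slot populations list of [PopulationParams-class]; weights sum to 1.
#' @slot nTrajectories number of trajectories to simulate.
#' @slot meanLifetime mean trackable span, ms.
#' @slot frameInterval frame interval, ms.
#' @slot maxDuration maximum record length, ms.
#' @exportClass ConditionModel
setClass("ConditionModel",
  representation(
    label = "character",
    ligand = "character",
    populations = "list",
    nTrajectories = "integer",
    meanLifetime = "numeric",
    frameInterval = "numeric",
    maxDuration = "numeric"
  )
)

setValidity("ConditionModel", function(object) {
  if (!length(object@populations))
    return("need at least one population")
  if (!all(vapply(object@populations, is, logical(1), "PopulationParams")))
    return("populations must all be PopulationParams")
  w <- sum(vapply(object@populations, function(p) p@weight, numeric(1)))
  if (abs(w - 1) > 1e-9)
    return("population weights must sum to 1")
  if (object@nTrajectories < 1L)
    return("nTrajectories must be >= 1")
  if (!(object@meanLifetime > 0 && object@meanLifetime <= object@maxDuration))
    return("require 0 < meanLifetime <= maxDuration")
  k <- object@maxDuration / object@frameInterval
  if (abs(k - round(k)) > 1e-9)
    return("frameInterval must divide maxDuration")
  TRUE
})

#' Rendering configuration for synthetic detector movies
#'
#' @slot geometry the [BeamlineGeometry-class] used for the forward model.
#' @slot psfSigma Gaussian point-spread width of a spot, px.
#' @slot photonsPerSpot mean integrated photon count per spot per frame.
#' @slot background mean background level, counts/px.
#' @slot shotNoise apply Poisson statistics to spots and background; when
#'   FALSE the render is deterministic (noise-free ground-truth mode).
#' @slot seed integer seed for the render stream.
#' @exportClass RenderConfig
setClass("RenderConfig",
  representation(
    geometry = "BeamlineGeometry",
    psfSigma = "numeric",
    photonsPerSpot = "numeric",
    background = "numeric",
    shotNoise = "logical",
    seed = "integer"
  )
)

setValidity("RenderConfig", function(object) {
  if (object@psfSigma <= 0) return("psfSigma must be positive")
  if (object@photonsPerSpot <= 0) return("photonsPerSpot must be positive")
  if (object@background < 0) return("background must be non-negative")
  TRUE
})
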