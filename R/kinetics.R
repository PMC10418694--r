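# Angular-trajectory kinetics: ensemble MSD with weighted linear fits,
# displacement distributions at fixed lag, 2D probability-density maps and
# two-condition difference maps.

#' Construct an angular-trajectory set
#'
#' @param data data.frame with columns \code{trajectory_id}, \code{t_ms},
#'   \code{theta_mrad}, \code{chi_mrad}, \code{ring}.
#' @param frameInterval frame interval, ms.
#' @param conditionLabel ligand condition label.
#' @return an [AngularTrajectorySet-class].
#' @export
angularTrajectorySet <- function(data, frameInterval = 0.1,
                                 conditionLabel = "unknown") {
  new("AngularTrajectorySet", data = data, frameInterval = frameInterval,
      conditionLabel = conditionLabel)
}

#' @describeIn angularTrajectorySet number of trajectories.
#' @param object an \code{AngularTrajectorySet}.
#' @export
nTrajectories <- function(object) length(unique(object@data$trajectory_id))

#' @describeIn angularTrajectorySet long-format sample table.
#' @export
trajectoryData <- function(object) object@data

#' @describeIn angularTrajectorySet condition label.
#' @export
conditionLabel <- function(object) object@conditionLabel

setMethod("show", "AngularTrajectorySet", function(object) {
  n <- nTrajectories(object)
  len <- if (n) table(object@data$trajectory_id) else integer(0)
  cat(sprintf(
    "AngularTrajectorySet '%s': %d trajectories, mean span %.3g ms (tau = %g ms)\n",
    object@conditionLabel, n,
    if (n) mean(len) * object@frameInterval else NA, object@frameInterval))
})

#' Convert a linked spot trajectory table to angular trajectories
#'
#' Each spot is mapped through the detector geometry to
#' (scattering angle, azimuth); tilt is half the change in scattering angle
#' relative to the trajectory's first spot, twist is the unwrapped cumulative
#' azimuth change, both in mrad. Time is measured from the first spot in
#' steps of the frame interval.
#'
#' @param tracks data.frame from [filterTrajectories()] (columns
#'   \code{trajectory_id}, \code{frame}, \code{x_px}, \code{y_px},
#'   \code{ring}).
#' @param geometry a [BeamlineGeometry-class].
#' @param conditionLabel condition label for the result.
#' @return an [AngularTrajectorySet-class].
#' @export
toAngular <- function(tracks, geometry, conditionLabel = "unknown") {
  need <- c("trajectory_id", "frame", "x_px", "y_px", "ring")
  if (!all(need %in% names(tracks)))
    stop("tracks must have columns: ", paste(need, collapse = ", "))
  pol <- detectorToPolar(tracks$y_px, tracks$x_px, geometry)
  tau <- geometry@frameInterval
  pieces <- lapply(split(seq_len(nrow(tracks)), tracks$trajectory_id),
    function(ix) {
      ix <- ix[order(tracks$frame[ix])]
      tt <- pol$twoTheta[ix]
      ch <- pol$chi[ix]
      data.frame(
        trajectory_id = tracks$trajectory_id[ix],
        t_ms = (tracks$frame[ix] - tracks$frame[ix][1]) * tau,
        theta_mrad = 1000 * (tt - tt[1]) / 2,
        chi_mrad = 1000 * cumsum(c(0, wrapAngle(diff(ch)))),
        ring = tracks$ring[ix])
    })
  df <- do.call(rbind, pieces)
  rownames(df) <- NULL
  angularTrajectorySet(df, frameInterval = tau,
                       conditionLabel = conditionLabel)
}

axisColumn <- function(axis) {
  switch(match.arg(axis, c("theta", "chi")),
         theta = "theta_mrad", chi = "chi_mrad")
}

# pooled axis displacements at lag k frames, over all ordered in-trajectory
# pairs (i, i+k) across all trajectories
pooledDisplacements <- function(object, axis, k) {
  col <- axisColumn(axis)
  x <- split(object@data[[col]], object@data$trajectory_id)
  unlist(lapply(x, function(v) {
    n <- length(v)
    if (n > k) v[(1 + k):n] - v[seq_len(n - k)] else numeric(0)
  }), use.names = FALSE)
}

#' Ensemble mean-square displacement
#'
#' Time-and-ensemble-averaged MSD: at each lag \eqn{k\tau} the squared axis
#' displacement is pooled over all ordered in-trajectory sample pairs
#' \eqn{(i, i+k)} across all trajectories. Lags with no contributing pair are
#' omitted.
#'
#' @param object an [AngularTrajectorySet-class].
#' @param axis \code{"theta"} or \code{"chi"}.
#' @param maxLagFrames largest lag in frames.
#' @return an [MSDCurve-class].
#' @export
ensembleMSD <- function(object, axis = c("theta", "chi"), maxLagFrames = 7) {
  axis <- match.arg(axis)
  if (!nTrajectories(object)) stop("no trajectories")
  tau <- object@frameInterval
  res <- lapply(seq_len(maxLagFrames), function(k) {
    d <- pooledDisplacements(object, axis, k)
    c(lag = k * tau, msd = if (length(d)) mean(d^2) else NA_real_,
      n = length(d))
  })
  res <- do.call(rbind, res)
  res <- res[res[, "n"] > 0, , drop = FALSE]
  if (!nrow(res)) stop("no displacement pairs at any lag")
  new("MSDCurve", axis = axis, lags = res[, "lag"], msd = res[, "msd"],
      nPairs = res[, "n"], conditionLabel = object@conditionLabel)
}

#' @describeIn ensembleMSD MSD curve as a data.frame (lag_ms, msd, n_pairs).
#' @param curve an \code{MSDCurve}.
#' @export
msdTable <- function(curve) {
  data.frame(lag_ms = curve@lags, msd = curve@msd, n_pairs = curve@nPairs)
}

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve '%s' (%s): %d lags, %g-%g ms\n",
              object@conditionLabel, object@axis, length(object@lags),
              min(object@lags), max(object@lags)))
})

#' Weighted linear fit of an MSD curve
#'
#' Weighted least squares of MSD on lag with weights proportional to the
#' per-lag pair counts. The slope is the MSD growth rate (\eqn{2D} for simple
#' rotational diffusion, mrad^2/ms); the intercept is the static-noise offset
#' (\eqn{2\sigma^2}, mrad^2). Standard errors come from the weighted-fit
#' covariance scaled by the residual variance; an exactly linear curve yields
#' zero SEs.
#'
#' @param curve an [MSDCurve-class].
#' @param lagRange (min, max) lag range to fit, ms.
#' @return an [MSDFit-class].
#' @export
fitMSDLinear <- function(curve, lagRange = c(0.1, 0.7)) {
  sel <- curve@lags >= lagRange[1] - 1e-9 & curve@lags <= lagRange[2] + 1e-9
  if (sum(sel) < 2) stop("need at least 2 lags inside lagRange")
  df <- data.frame(lag = curve@lags[sel], msd = curve@msd[sel],
                   w = curve@nPairs[sel])
  fit <- stats::lm(msd ~ lag, data = df, weights = w)
  co <- summary(fit)$coefficients
  se <- co[, "Std. Error"]
  se[!is.finite(se)] <- 0
  new("MSDFit",
      slope = unname(co["lag", "Estimate"]),
      slopeSE = unname(se["lag"]),
      intercept = unname(co["(Intercept)", "Estimate"]),
      interceptSE = unname(se["(Intercept)"]),
      lagRange = range(df$lag), axis = curve@axis,
      conditionLabel = curve@conditionLabel)
}

#' @describeIn fitMSDLinear slope accessor, mrad^2/ms.
#' @param fit an \code{MSDFit}.
#' @export
msdSlope <- function(fit) fit@slope

#' @describeIn fitMSDLinear intercept accessor, mrad^2.
#' @export
msdIntercept <- function(fit) fit@intercept

setMethod("show", "MSDFit", function(object) {
  cat(sprintf(
    "MSDFit '%s' (%s): slope %.4g +/- %.3g mrad^2/ms, intercept %.4g +/- %.3g mrad^2 (lags %g-%g ms)\n",
    object@conditionLabel, object@axis, object@slope, object@slopeSE,
    object@intercept, object@interceptSE,
    object@lagRange[1], object@lagRange[2]))
})

#' Default log-spaced displacement bin edges
#'
#' 60 log-spaced bins spanning 0.01-1000 mrad, the range used for the
#' displacement distributions and density maps.
#'
#' @param n number of bins.
#' @param lo,hi range, mrad.
#' @return numeric vector of n + 1 edges.
#' @export
defaultLogEdges <- function(n = 60, lo = 1e-2, hi = 1e3) {
  exp(seq(log(lo), log(hi), length.out = n + 1))
}

#' Distribution of absolute angular displacements at a fixed lag
#'
#' Histogram of pooled |axis displacement| at lag \code{dt}, normalised to
#' unit mass over the bins plus an explicit underflow/overflow pair.
#'
#' @param object an [AngularTrajectorySet-class].
#' @param axis \code{"theta"} or \code{"chi"}.
#' @param dt time lag, ms; must be an integer multiple of the frame interval.
#' @param edges bin edges in mrad, see [defaultLogEdges()].
#' @return a [DisplacementDistribution-class].
#' @export
displacementDistribution <- function(object, axis = c("theta", "chi"),
                                     dt = 0.7, edges = defaultLogEdges()) {
  axis <- match.arg(axis)
  k <- dt / object@frameInterval
  if (abs(k - round(k)) > 1e-9)
    stop("dt must be an integer multiple of the frame interval")
  d <- abs(pooledDisplacements(object, axis, as.integer(round(k))))
  if (!length(d)) stop("no displacement pairs at dt = ", dt, " ms")
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  counts <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  new("DisplacementDistribution", axis = axis, dt = dt, binEdges = edges,
      mass = counts / length(d),
      underflow = sum(idx < 1) / length(d),
      overflow = sum(idx > nb) / length(d),
      conditionLabel = object@conditionLabel)
}

setMethod("show", "DisplacementDistribution", function(object) {
  cat(sprintf(
    "DisplacementDistribution '%s' (%s) at dt = %g ms: %d bins, under/overflow %.3g/%.3g\n",
    object@conditionLabel, object@axis, object@dt, length(object@mass),
    object@underflow, object@overflow))
})

#' Fraction of large displacements at a fixed lag
#'
#' The fraction of pooled absolute displacements at lag \code{dt} strictly
#' exceeding \code{threshold} — the motion population the analysis contrasts
#' across ligand conditions (e.g. twist excursions beyond 10 mrad).
#'
#' @param object an [AngularTrajectorySet-class].
#' @param axis \code{"theta"} or \code{"chi"}.
#' @param dt time lag, ms.
#' @param threshold displacement threshold, mrad.
#' @return fraction in \[0, 1\].
#' @export
tailFraction <- function(object, axis = c("theta", "chi"), dt = 0.7,
                         threshold = 10) {
  axis <- match.arg(axis)
  k <- dt / object@frameInterval
  if (abs(k - round(k)) > 1e-9)
    stop("dt must be an integer multiple of the frame interval")
  d <- abs(pooledDisplacements(object, axis, as.integer(round(k))))
  if (!length(d)) stop("no displacement pairs at dt = ", dt, " ms")
  mean(d > threshold)
}

#' Two-axis displacement probability-density map
#'
#' Joint histogram of (|tilt|, |twist|) displacement pairs at lag \code{dt}
#' on log-spaced edges, normalised to unit total mass. Displacements outside
#' the edge range are clamped into the first/last bin so the map always sums
#' to 1.
#'
#' @param object an [AngularTrajectorySet-class].
#' @param dt time lag, ms.
#' @param thetaEdges,chiEdges bin edges, mrad.
#' @return a [DensityMap2D-class].
#' @export
densityMap2D <- function(object, dt = 0.7,
                         thetaEdges = defaultLogEdges(),
                         chiEdges = defaultLogEdges()) {
  k <- dt / object@frameInterval
  if (abs(k - round(k)) > 1e-9)
    stop("dt must be an integer multiple of the frame interval")
  k <- as.integer(round(k))
  dth <- abs(pooledDisplacements(object, "theta", k))
  dch <- abs(pooledDisplacements(object, "chi", k))
  if (!length(dth)) stop("no displacement pairs at dt = ", dt, " ms")
  nt <- length(thetaEdges) - 1
  nc <- length(chiEdges) - 1
  it <- pmin(pmax(findInterval(dth, thetaEdges, rightmost.closed = TRUE), 1), nt)
  ic <- pmin(pmax(findInterval(dch, chiEdges, rightmost.closed = TRUE), 1), nc)
  mass <- matrix(0, nt, nc)
  tab <- table(factor(it, levels = seq_len(nt)),
               factor(ic, levels = seq_len(nc)))
  mass[] <- as.numeric(tab) / length(dth)
  new("DensityMap2D", dt = dt, thetaEdges = thetaEdges, chiEdges = chiEdges,
      mass = mass, conditionLabel = object@conditionLabel,
      isDifference = FALSE)
}

#' Two-condition difference map
#'
#' Cellwise difference \code{mapA - mapB} of two density maps on identical
#' binning; positive cells mark motion enriched in condition A. Sums to 0.
#'
#' @param mapA,mapB [DensityMap2D-class] objects with identical edges and dt.
#' @return a difference [DensityMap2D-class].
#' @export
differenceMap <- function(mapA, mapB) {
  if (!isTRUE(all.equal(mapA@thetaEdges, mapB@thetaEdges)) ||
      !isTRUE(all.equal(mapA@chiEdges, mapB@chiEdges)) ||
      mapA@dt != mapB@dt)
    stop("maps must share identical bin edges and dt")
  if (mapA@isDifference || mapB@isDifference)
    stop("inputs must be single-condition maps")
  new("DensityMap2D", dt = mapA@dt, thetaEdges = mapA@thetaEdges,
      chiEdges = mapA@chiEdges, mass = mapA@mass - mapB@mass,
      conditionLabel = paste(mapA@conditionLabel, "-", mapB@conditionLabel),
      isDifference = TRUE)
}

#' Net mass of a difference map inside a twist band
#'
#' Sums difference-map mass over cells whose twist-bin centres (geometric
#' mean of the edges) fall inside \code{[chiLo, chiHi]} mrad — the summary
#' used to quantify the agonist-enriched large-twist population.
#'
#' @param map a difference [DensityMap2D-class].
#' @param chiLo,chiHi twist band, mrad.
#' @return net probability mass (can be negative).
#' @export
bandMass <- function(map, chiLo = 10, chiHi = 50) {
  centers <- sqrt(map@chiEdges[-length(map@chiEdges)] * map@chiEdges[-1])
  sel <- centers >= chiLo & centers <= chiHi
  sum(map@mass[, sel])
}

setMethod("show", "DensityMap2D", function(object) {
  cat(sprintf("DensityMap2D '%s' at dt = %g ms: %d x %d cells, total %.3g\n",
              object@conditionLabel, object@dt, nrow(object@mass),
              ncol(object@mass), sum(object@mass)))
})
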