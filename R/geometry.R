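# Bragg-condition mathematics and detector <-> angle transforms.
# Conventions: angles in radians internally, reported in mrad; lengths in mm
# (lattice spacings in Angstrom); energies in keV; time in ms.

# hc in keV * Angstrom, so lambda[A] = HC_KEV_A / E[keV]
HC_KEV_A <- 12.3984

# Gold lattice constant, Angstrom
AU_LATTICE_A <- 4.0782

#' Construct a beamline geometry
#'
#' Defaults describe the packaged acquisition: 15.8 keV peak energy with a
#' fractional energy bandwidth of 0.08, 50 mm camera length, 100 us frames,
#' and a 512 x 512 px detector at 0.08 mm/px centred on the beam (the
#' image-intensifier + CMOS chain is modelled as an ideal flat detector; all
#' physics is carried in mm, pixels enter only at I/O).
#'
#' @param peakEnergy photon energy, keV.
#' @param fractionalBandwidth full energy width \eqn{\Delta E/E}.
#' @param cameraLength sample-to-detector distance, mm.
#' @param pixelPitch pixel size, mm/px.
#' @param detectorShape detector grid (rows, cols), px.
#' @param beamCenter direct-beam position (row, col), px; default the
#'   detector centre.
#' @param frameInterval time per frame, ms.
#' @param beamDiameter beam size at the sample, mm (metadata).
#' @return a [BeamlineGeometry-class] object.
#' @examples
#' geom <- beamlineGeometry()
#' ringRadius(braggAngle(au111(), 15.8), geom)
#' @export
beamlineGeometry <- function(peakEnergy = 15.8,
                             fractionalBandwidth = 0.08,
                             cameraLength = 50,
                             pixelPitch = 0.08,
                             detectorShape = c(512L, 512L),
                             beamCenter = (detectorShape + 1) / 2,
                             frameInterval = 0.1,
                             beamDiameter = 0.05) {
  new("BeamlineGeometry",
    peakEnergy = peakEnergy,
    fractionalBandwidth = fractionalBandwidth,
    cameraLength = cameraLength,
    pixelPitch = pixelPitch,
    beamCenter = as.numeric(beamCenter),
    detectorShape = as.integer(detectorShape),
    frameInterval = frameInterval,
    beamDiameter = beamDiameter)
}

#' @describeIn beamlineGeometry frame interval accessor, ms.
#' @param object a \code{BeamlineGeometry}.
#' @export
frameInterval <- function(object) object@frameInterval

setMethod("show", "BeamlineGeometry", function(object) {
  cat("BeamlineGeometry:",
      sprintf("%.6g keV (dE/E = %.3g), L = %g mm,", object@peakEnergy,
              object@fractionalBandwidth, object@cameraLength),
      sprintf("%d x %d px @ %g mm/px, %g ms/frame\n",
              object@detectorShape[1], object@detectorShape[2],
              object@pixelPitch, object@frameInterval))
})

#' Gold lattice planes
#'
#' The two ring-producing plane families of the gold nanocrystal label.
#' Spacings derive from the gold lattice constant 4.0782 Angstrom:
#' d(111) = a/sqrt(3) = 2.3546, d(200) = a/2 = 2.0391, so
#' d(111)/d(200) = sqrt(4/3).
#'
#' @return a [CrystalPlane-class] object.
#' @export
au111 <- function() new("CrystalPlane", name = "Au111",
                        dSpacing = AU_LATTICE_A / sqrt(3))

#' @rdname au111
#' @export
au200 <- function() new("CrystalPlane", name = "Au200",
                        dSpacing = AU_LATTICE_A / 2)

setMethod("show", "CrystalPlane", function(object) {
  cat(sprintf("CrystalPlane %s: d = %.4f A\n", object@name, object@dSpacing))
})

setMethod("show", "RingBand", function(object) {
  cat(sprintf("RingBand %s: [%.3f, %.3f] mm\n",
              object@plane@name, object@rMin, object@rMax))
})

#' Bragg angle of a lattice plane
#'
#' First-order Bragg condition \eqn{\lambda = 2 d \sin\theta_B} with
#' \eqn{\lambda = 12.3984 / E} Angstrom.
#'
#' @param plane a [CrystalPlane-class].
#' @param energy photon energy, keV.
#' @return Bragg angle \eqn{\theta_B}, radians. Strictly decreasing in energy.
#' @examples
#' braggAngle(au111(), 15.8)  # 0.16742 rad
#' @export
braggAngle <- function(plane, energy) {
  stopifnot(is(plane, "CrystalPlane"), energy > 0)
  lambda <- HC_KEV_A / energy
  s <- lambda / (2 * plane@dSpacing)
  if (s > 1)
    stop(sprintf(
      "no diffraction: lambda = %.4f A exceeds 2d = %.4f A for %s at %.4g keV",
      lambda, 2 * plane@dSpacing, plane@name, energy))
  asin(s)
}

#' Ring radius on a flat detector
#'
#' Projects the Bragg cone of half-opening \eqn{2\theta_B} onto the detector:
#' \eqn{r = L \tan(2\theta_B)}.
#'
#' @param thetaB Bragg angle, radians.
#' @param geometry a [BeamlineGeometry-class].
#' @return radial distance from the beam centre, mm.
#' @export
ringRadius <- function(thetaB, geometry) {
  stopifnot(thetaB >= 0)
  if (2 * thetaB >= pi / 2)
    stop("2 theta_B >= 90 degrees: back-scattering outside the flat-detector model")
  geometry@cameraLength * tan(2 * thetaB)
}

#' Radial acceptance band of a ring
#'
#' The energy bandwidth makes each ring a radial band rather than a line: a
#' crystal diffracts wherever its Bragg-matched wavelength falls inside the
#' rectangular band \eqn{[E(1 - w/2), E(1 + w/2)]}. The high band-edge energy
#' gives the inner radius, the low edge the outer radius.
#'
#' @param plane a [CrystalPlane-class].
#' @param geometry a [BeamlineGeometry-class].
#' @return a [RingBand-class].
#' @examples
#' ringBand(au111(), beamlineGeometry())  # [16.672, 18.191] mm
#' @export
ringBand <- function(plane, geometry) {
  w <- geometry@fractionalBandwidth
  eHigh <- geometry@peakEnergy * (1 + w / 2)
  eLow <- geometry@peakEnergy * (1 - w / 2)
  new("RingBand", plane = plane,
      rMin = ringRadius(braggAngle(plane, eHigh), geometry),
      rMax = ringRadius(braggAngle(plane, eLow), geometry))
}

#' Default ring bands for the packaged planes
#'
#' @param geometry a [BeamlineGeometry-class].
#' @return list of two non-overlapping [RingBand-class] objects
#'   (Au111, Au200).
#' @export
defaultRingBands <- function(geometry = beamlineGeometry()) {
  list(ringBand(au111(), geometry), ringBand(au200(), geometry))
}

#' Detector pixel to polar scattering coordinates
#'
#' Converts a detector position to the scattering angle
#' \eqn{2\theta = \arctan(r / L)} and azimuth \eqn{\chi \in (-\pi, \pi]},
#' measured counter-clockwise from the +column axis (+row axis maps to
#' \eqn{\chi = \pi/2}).
#'
#' @param row,col detector position, px (subpixel allowed).
#' @param geometry a [BeamlineGeometry-class].
#' @return list with \code{twoTheta} (rad), \code{chi} (rad) and \code{r}
#'   (mm from the beam centre).
#' @export
detectorToPolar <- function(row, col, geometry) {
  dr <- (row - geometry@beamCenter[1]) * geometry@pixelPitch
  dc <- (col - geometry@beamCenter[2]) * geometry@pixelPitch
  r <- sqrt(dr^2 + dc^2)
  if (any(r == 0))
    stop("point at the beam centre: azimuth undefined")
  list(twoTheta = atan(r / geometry@cameraLength),
       chi = atan2(dr, dc),
       r = r)
}

#' Polar scattering coordinates to detector pixel
#'
#' Inverse of [detectorToPolar()].
#'
#' @param twoTheta scattering angle, radians.
#' @param chi azimuth, radians.
#' @param geometry a [BeamlineGeometry-class].
#' @return list with \code{row}, \code{col} in px.
#' @export
polarToDetector <- function(twoTheta, chi, geometry) {
  r <- geometry@cameraLength * tan(twoTheta)
  list(row = geometry@beamCenter[1] + r * sin(chi) / geometry@pixelPitch,
       col = geometry@beamCenter[2] + r * cos(chi) / geometry@pixelPitch)
}

#' Classify a radial position into a ring band
#'
#' @param r radial distance(s) from the beam centre, mm.
#' @param bands list of non-overlapping [RingBand-class] objects.
#' @return character vector of plane labels, \code{"none"} where r falls in
#'   no band.
#' @export
classifyRing <- function(r, bands = defaultRingBands()) {
  lo <- vapply(bands, function(b) b@rMin, numeric(1))
  hi <- vapply(bands, function(b) b@rMax, numeric(1))
  o <- order(lo)
  if (any(lo[o][-1] < hi[o][-length(o)]))
    stop("configuration error: ring bands overlap")
  labels <- vapply(bands, function(b) b@plane@name, character(1))
  out <- rep("none", length(r))
  for (i in seq_along(bands)) {
    out[r >= lo[i] & r <= hi[i]] <- labels[i]
  }
  out
}

# wrap an angle (rad) into (-pi, pi]
wrapAngle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Angular displacement between two spot positions on the same ring
#'
#' Decomposes spot motion into crystal tilt and twist. Radial motion maps to
#' tilt as half the change in scattering angle,
#' \eqn{\Delta\theta = \Delta(2\theta)/2}; azimuthal motion maps 1:1 to twist,
#' wrapped into \eqn{(-\pi, \pi]}. Cross-talk between the axes is neglected
#' (small-angle regime).
#'
#' @param p1,p2 polar positions as returned by [detectorToPolar()].
#' @param ring1,ring2 optional ring labels; if both given they must agree.
#' @return named numeric: \code{dtheta}, \code{dchi} in mrad.
#' @export
angularDisplacement <- function(p1, p2, ring1 = NULL, ring2 = NULL) {
  if (!is.null(ring1) && !is.null(ring2) && !identical(ring1, ring2))
    stop("points lie on different rings: ", ring1, " vs ", ring2)
  c(dtheta = 1000 * (p2$twoTheta - p1$twoTheta) / 2,
    dchi = 1000 * wrapAngle(p2$chi - p1$chi))
}

#' Convert milliradians to degrees
#'
#' @param mrad angle(s) in mrad.
#' @return angle(s) in degrees.
#' @examples
#' mradToDegrees(10)  # 0.573, i.e. ~0.6 degrees
#' @export
mradToDegrees <- function(mrad) mrad * 180 / (1000 * pi)

#' Absorbed X-ray dose for an exposure time
#'
#' Linear dose arithmetic at the beamline's dose rate (default 1.13 kGy/ms,
#' i.e. 113 kGy per 100 ms exposure).
#'
#' @param exposure exposure time, ms.
#' @param doseRate dose rate, kGy/ms.
#' @return absorbed dose, kGy.
#' @examples
#' xrayDose(100)  # 113 kGy
#' xrayDose(10)   # 11.3 kGy
#' @export
xrayDose <- function(exposure, doseRate = 1.13) {
  if (any(exposure < 0)) stop("exposure must be non-negative")
  stopifnot(doseRate > 0)
  exposure * doseRate
}
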