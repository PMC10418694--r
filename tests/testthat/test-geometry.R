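# Bragg geometry, coordinate transforms, and the unit/dose helpers.

test_that("Bragg angles and ring radii match the closed-form oracle", {
  expect_equal(braggAngle(au111(), 15.8), oracleBragg(D111, 15.8),
               tolerance = 1e-12)
  expect_equal(braggAngle(au111(), 15.8), 0.16742, tolerance = 1e-4)
  expect_equal(braggAngle(au200(), 15.8), 0.19362, tolerance = 1e-4)
  geom <- beamlineGeometry()
  expect_equal(ringRadius(braggAngle(au111(), 15.8), geom), 17.397,
               tolerance = 1e-4)
  expect_equal(ringRadius(braggAngle(au200(), 15.8), geom), 20.392,
               tolerance = 1e-4)
  expect_equal(ringRadius(0, geom), 0)
  # sin(theta_B) = 1 boundary: d = lambda / 2
  lam <- 12.3984 / 15.8
  edge <- new("CrystalPlane", name = "edge", dSpacing = lam / 2)
  expect_equal(braggAngle(edge, 15.8), pi / 2)
  # below the boundary there is no diffraction, and the error names the plane
  tooSmall <- new("CrystalPlane", name = "tiny", dSpacing = lam / 2 - 0.01)
  expect_error(braggAngle(tooSmall, 15.8), "no diffraction.*tiny")
})

test_that("braggAngle decreases and ringRadius increases monotonically", {
  energies <- seq(10, 40, by = 0.5)
  th <- vapply(energies, function(e) braggAngle(au111(), e), numeric(1))
  expect_true(all(diff(th) < 0))
  geom <- beamlineGeometry()
  angles <- seq(0.01, pi / 4 - 0.01, length.out = 50)
  r <- vapply(angles / 2, ringRadius, numeric(1), geometry = geom)
  expect_true(all(diff(r) > 0))
  expect_error(ringRadius(pi / 4, geom), "back-scattering")
})

test_that("ring bands match the band-edge oracle and do not overlap", {
  geom <- beamlineGeometry()
  b111 <- ringBand(au111(), geom)
  b200 <- ringBand(au200(), geom)
  expect_equal(b111@rMin, oracleRadius(D111, 15.8 * 1.04), tolerance = 1e-9)
  expect_equal(b111@rMax, oracleRadius(D111, 15.8 * 0.96), tolerance = 1e-9)
  expect_equal(b111@rMin, 16.672, tolerance = 1e-3)
  expect_equal(b111@rMax, 18.191, tolerance = 1e-3)
  expect_equal(b200@rMin, 19.518, tolerance = 1e-3)
  expect_equal(b200@rMax, 21.352, tolerance = 1e-3)
  expect_lt(b111@rMax, b200@rMin)
  # degenerate band: bandwidth -> 0 collapses to the peak-energy radius
  g0 <- beamlineGeometry(fractionalBandwidth = 1e-12)
  b0 <- ringBand(au111(), g0)
  expect_equal(b0@rMin, b0@rMax, tolerance = 1e-6)
  expect_equal(b0@rMin, oracleRadius(D111, 15.8), tolerance = 1e-6)
})

test_that("classifyRing assigns band members and rejects the gap", {
  expect_equal(classifyRing(17.40), "Au111")
  expect_equal(classifyRing(19.00), "none")
  expect_equal(classifyRing(20.40), "Au200")
  # every radius inside a band classifies to that band; the midpoint of the
  # gap classifies to none
  b <- defaultRingBands()
  rIn <- seq(b[[1]]@rMin, b[[1]]@rMax, length.out = 25)
  expect_true(all(classifyRing(rIn) == "Au111"))
  mid <- (b[[1]]@rMax + b[[2]]@rMin) / 2
  expect_equal(classifyRing(mid), "none")
  overlapping <- list(
    new("RingBand", plane = au111(), rMin = 1, rMax = 3),
    new("RingBand", plane = au200(), rMin = 2, rMax = 4))
  expect_error(classifyRing(2.5, overlapping), "overlap")
})

test_that("detector <-> polar round trip is exact to < 1e-9 mm", {
  geom <- beamlineGeometry()
  set.seed(11)
  rows <- runif(200, 1, 512)
  cols <- runif(200, 1, 512)
  off <- abs(rows - geom@beamCenter[1]) + abs(cols - geom@beamCenter[2]) > 1e-6
  rows <- rows[off]; cols <- cols[off]
  pol <- detectorToPolar(rows, cols, geom)
  back <- polarToDetector(pol$twoTheta, pol$chi, geom)
  expect_lt(max(abs(back$row - rows)) * geom@pixelPitch, 1e-9)
  expect_lt(max(abs(back$col - cols)) * geom@pixelPitch, 1e-9)
  expect_error(detectorToPolar(geom@beamCenter[1], geom@beamCenter[2], geom),
               "azimuth undefined")
})

test_that("polar axis conventions hold", {
  geom <- beamlineGeometry()
  bc <- geom@beamCenter
  # 17.397 mm along +column: twoTheta = 2 * braggAngle(Au111), chi = 0
  p <- detectorToPolar(bc[1], bc[2] + 17.39683 / geom@pixelPitch, geom)
  expect_equal(p$twoTheta, 2 * oracleBragg(D111, 15.8), tolerance = 1e-5)
  expect_equal(p$chi, 0)
  # +row axis: chi = pi/2
  p2 <- detectorToPolar(bc[1] + 10, bc[2], geom)
  expect_equal(p2$chi, pi / 2)
  # small-angle limit: twoTheta -> 0 as r -> 0+
  p3 <- detectorToPolar(bc[1], bc[2] + 1e-6, geom)
  expect_lt(p3$twoTheta, 1e-8)
})

test_that("angularDisplacement decomposes tilt and twist with wrapping", {
  geom <- beamlineGeometry()
  bc <- geom@beamCenter
  p <- detectorToPolar(bc[1] + 30, bc[2] + 40, geom)
  expect_equal(unname(angularDisplacement(p, p)), c(0, 0))
  # wrap rule: 179 deg -> -179 deg is +2 deg = +34.907 mrad, not -358 deg
  mk <- function(chiDeg, r = 17.4) {
    ang <- chiDeg * pi / 180
    detectorToPolar(bc[1] + r * sin(ang) / geom@pixelPitch,
                    bc[2] + r * cos(ang) / geom@pixelPitch, geom)
  }
  d <- angularDisplacement(mk(179), mk(-179))
  expect_equal(unname(d["dchi"]), 34.90659, tolerance = 1e-4)
  # radial move 17.40 -> 17.58 mm: dtheta = (atan(17.58/50) - atan(17.40/50))/2
  pa <- detectorToPolar(bc[1], bc[2] + 17.40 / geom@pixelPitch, geom)
  pb <- detectorToPolar(bc[1], bc[2] + 17.58 / geom@pixelPitch, geom)
  d2 <- angularDisplacement(pa, pb)
  expect_equal(unname(d2["dtheta"]),
               1000 * (atan(17.58 / 50) - atan(17.40 / 50)) / 2,
               tolerance = 1e-9)
  expect_equal(unname(d2["dtheta"]), 1.6038, tolerance = 1e-3)
  expect_error(angularDisplacement(pa, pb, "Au111", "Au200"),
               "different rings")
})

test_that("dchi stays in (-1000 pi, 1000 pi] and is antisymmetric", {
  geom <- beamlineGeometry()
  bc <- geom@beamCenter
  set.seed(21)
  for (i in 1:50) {
    ang <- runif(2, -pi, pi)
    r <- runif(2, 5, 20)
    p1 <- detectorToPolar(bc[1] + r[1] * sin(ang[1]) / geom@pixelPitch,
                          bc[2] + r[1] * cos(ang[1]) / geom@pixelPitch, geom)
    p2 <- detectorToPolar(bc[1] + r[2] * sin(ang[2]) / geom@pixelPitch,
                          bc[2] + r[2] * cos(ang[2]) / geom@pixelPitch, geom)
    fwd <- angularDisplacement(p1, p2)
    bwd <- angularDisplacement(p2, p1)
    expect_true(fwd["dchi"] > -1000 * pi && fwd["dchi"] <= 1000 * pi)
    # componentwise antisymmetry after wrapping
    expect_equal(unname(fwd["dtheta"]), -unname(bwd["dtheta"]),
                 tolerance = 1e-12)
    wrapBack <- function(x) {
      y <- (x / 1000 + pi) %% (2 * pi) - pi
      1000 * ifelse(y == -pi, pi, y)
    }
    expect_equal(unname(wrapBack(fwd["dchi"] + bwd["dchi"])), 0,
                 tolerance = 1e-9)
  }
})

test_that("unit conversion and dose arithmetic are exact", {
  expect_equal(mradToDegrees(10), 0.5729578, tolerance = 1e-6)
  expect_equal(mradToDegrees(0), 0)
  expect_equal(mradToDegrees(1000 * pi), 180)
  expect_equal(xrayDose(100), 113)
  expect_equal(xrayDose(10), 11.3)
  expect_equal(xrayDose(0), 0)
  expect_error(xrayDose(-1), "non-negative")
  # linear in exposure
  expect_equal(xrayDose(37), 37 * xrayDose(1))
})
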