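# MSD estimation, weighted fits, displacement distributions and maps.

test_that("toAngular reproduces pure azimuthal and pure radial motion", {
  geom <- beamlineGeometry()
  bc <- geom@beamCenter
  # stationary spot: all samples (t, 0, 0)
  still <- data.frame(trajectory_id = 1, frame = 1:5,
                      x_px = bc[2] + 17.4 / geom@pixelPitch, y_px = bc[1],
                      intensity = 1, ring = "Au111")
  a <- trajectoryData(toAngular(still, geom))
  expect_equal(a$theta_mrad, rep(0, 5))
  expect_equal(a$chi_mrad, rep(0, 5))
  expect_equal(a$t_ms, (0:4) * 0.1)
  # purely azimuthal, 1 degree per frame: theta = 0, chi = 17.453 k mrad
  rPx <- 17.4 / geom@pixelPitch
  ang <- (0:4) * pi / 180
  az <- data.frame(trajectory_id = 1, frame = 1:5,
                   x_px = bc[2] + rPx * cos(ang),
                   y_px = bc[1] + rPx * sin(ang),
                   intensity = 1, ring = "Au111")
  aa <- trajectoryData(toAngular(az, geom))
  expect_equal(aa$theta_mrad, rep(0, 5), tolerance = 1e-9)
  expect_equal(aa$chi_mrad, (0:4) * 1000 * pi / 180, tolerance = 1e-9)
  # purely radial 17.40 -> 17.58 mm in one frame
  rad <- data.frame(trajectory_id = 1, frame = 1:2,
                    x_px = bc[2] + c(17.40, 17.58) / geom@pixelPitch,
                    y_px = bc[1], intensity = 1, ring = "Au111")
  ar <- trajectoryData(toAngular(rad, geom))
  expect_equal(ar$chi_mrad, c(0, 0))
  expect_equal(ar$theta_mrad[2],
               1000 * (atan(17.58 / 50) - atan(17.40 / 50)) / 2,
               tolerance = 1e-9)
})

test_that("ensembleMSD is exact for drift and constant trajectories", {
  # constant drift theta_k = 3k mrad over 8 frames: MSD(k tau) = (3k)^2
  drift <- atsFromList(list(cbind(3 * (0:7), 0)))
  m <- ensembleMSD(drift, "theta", maxLagFrames = 7)
  expect_equal(m@msd, (3 * (1:7))^2)
  expect_equal(m@nPairs, 7:1)
  # constant trajectories: MSD = 0 at all lags
  flat <- atsFromList(list(cbind(rep(0, 6), rep(0, 6))))
  expect_equal(ensembleMSD(flat, "chi", 5)@msd, rep(0, 5))
  empty <- angularTrajectorySet(data.frame(
    trajectory_id = integer(0), t_ms = numeric(0), theta_mrad = numeric(0),
    chi_mrad = numeric(0), ring = character(0)))
  expect_error(ensembleMSD(empty), "no trajectories")
})

test_that("ensembleMSD equals the brute-force pooled-pair double loop", {
  set.seed(5)
  mats <- lapply(1:20, function(i) {
    n <- sample(2:12, 1)
    cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
  })
  mats <- lapply(mats, function(m) sweep(m, 2, m[1, ]))
  ats <- atsFromList(mats)
  for (axis in c("theta", "chi")) {
    col <- if (axis == "theta") 1 else 2
    m <- ensembleMSD(ats, axis, maxLagFrames = 7)
    trajList <- lapply(mats, function(x) x[, col])
    for (i in seq_along(m@lags)) {
      k <- round(m@lags[i] / 0.1)
      expect_identical(m@nPairs[i], brutePairCount(trajList, k))
      expect_equal(m@msd[i], bruteMSD(trajList, k), tolerance = 1e-12)
    }
  }
})

test_that("fitMSDLinear recovers exact lines and honours weights", {
  lags <- (1:7) * 0.1
  curve <- new("MSDCurve", axis = "theta", lags = lags,
               msd = 2 + 3 * lags, nPairs = rep(100, 7),
               conditionLabel = "x")
  f <- fitMSDLinear(curve)
  expect_equal(f@slope, 3, tolerance = 1e-12)
  expect_equal(f@intercept, 2, tolerance = 1e-12)
  expect_equal(f@slopeSE, 0, tolerance = 1e-9)
  expect_equal(f@interceptSE, 0, tolerance = 1e-9)
  # one point with 1e6-fold weight pins the fitted line to it
  msd <- c(5, 4.2, 7.8, 9.5, 11, 12, 16)
  w <- c(1e6, 1, 1, 1, 1, 1, 1)
  heavy <- new("MSDCurve", axis = "theta", lags = lags, msd = msd,
               nPairs = w, conditionLabel = "x")
  fh <- fitMSDLinear(heavy)
  expect_lt(abs(fh@intercept + fh@slope * lags[1] - msd[1]), 1e-3)
  # direct normal-equation cross-check of the weighted solution
  X <- cbind(1, lags)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * msd))
  expect_equal(fh@intercept, beta[1], tolerance = 1e-9)
  expect_equal(fh@slope, beta[2], tolerance = 1e-9)
  expect_error(fitMSDLinear(curve, lagRange = c(0.65, 0.7)), "at least 2")
})

test_that("slope and intercept recover the generative diffusion parameters", {
  # pure Brownian rotation + static noise, no mixture: slope ~ 2D,
  # intercept ~ 2 sigma^2. Replicate-based SEs across 5 fixed seeds.
  for (D in c(1, 10)) for (s2 in c(2.5, 7.5)) {
    model <- conditionModel(
      sprintf("D%g_s%g", D, s2),
      populations = list(populationParams(
        1, dTheta = D, dChi = D, sigmaTheta = sqrt(s2),
        sigmaChi = sqrt(s2))),
      nTrajectories = 150L)
    fits <- lapply(0:4, function(sd) protocolSlope(model, "theta", sd))
    slopes <- vapply(fits, function(f) f@slope, numeric(1))
    ints <- vapply(fits, function(f) f@intercept, numeric(1))
    # 3-sigma-equivalent bound with the small-sample t correction
    # (5 replicates give the SE only 4 degrees of freedom)
    q <- qt(pnorm(3), df = 4)
    seS <- sd(slopes) / sqrt(5)
    seI <- sd(ints) / sqrt(5)
    expect_lt(abs(mean(slopes) - 2 * D), q * seS)
    expect_lt(abs(mean(ints) - 2 * s2), q * seI)
  }
})

test_that("MSD is unchanged by trajectories straddling the azimuth seam", {
  geom <- beamlineGeometry()
  bc <- geom@beamCenter
  rPx <- 17.4 / geom@pixelPitch
  set.seed(31)
  mkSpots <- function(angles) {
    data.frame(trajectory_id = 1, frame = seq_along(angles),
               x_px = bc[2] + rPx * cos(angles),
               y_px = bc[1] + rPx * sin(angles),
               intensity = 1, ring = "Au111")
  }
  # random walk in azimuth that crosses chi = pi repeatedly
  steps <- rnorm(30, 0, 0.02)
  seam <- pi + cumsum(c(0, steps))
  away <- seam - pi / 2
  mSeam <- ensembleMSD(toAngular(mkSpots(seam), geom), "chi", 7)
  mAway <- ensembleMSD(toAngular(mkSpots(away), geom), "chi", 7)
  expect_equal(mSeam@msd, mAway@msd, tolerance = 1e-9)
})

test_that("displacement distributions normalise and match Gaussian tails", {
  # all displacements identical (drift): unit mass in one bin
  drift <- atsFromList(lapply(1:5, function(i) cbind(0, 5 * (0:9))))
  d <- displacementDistribution(drift, "chi", dt = 0.1)
  expect_equal(sum(d@mass) + d@underflow + d@overflow, 1, tolerance = 1e-12)
  expect_equal(max(d@mass), 1)
  expect_equal(sum(d@mass > 0), 1)
  # Gaussian displacements of known sigma: mass above x matches the
  # complementary error function within binomial 3 sigma
  sigma <- 4
  set.seed(9)
  mats <- lapply(1:400, function(i)
    cbind(0, cumsum(c(0, rnorm(9, 0, sigma)))))
  g <- atsFromList(mats)
  x <- 8
  frac <- tailFraction(g, "chi", dt = 0.1, threshold = x)
  pTrue <- 2 * pnorm(-x / sigma)
  nPairs <- 400 * 9
  expect_lt(abs(frac - pTrue), 3 * sqrt(pTrue * (1 - pTrue) / nPairs))
  expect_error(displacementDistribution(g, "chi", dt = 0.15),
               "integer multiple")
})

test_that("tailFraction boundary thresholds behave", {
  drift <- atsFromList(list(cbind(0, 5 * (0:9))))
  expect_equal(tailFraction(drift, "chi", dt = 0.1, threshold = 0), 1)
  expect_equal(tailFraction(drift, "chi", dt = 0.1, threshold = 1e6), 0)
})

test_that("density maps normalise, factorise for independent axes, and subtract", {
  # single drift trajectory: all mass in one cell
  drift <- atsFromList(list(cbind(3 * (0:9), 5 * (0:9))))
  m <- densityMap2D(drift, dt = 0.1)
  expect_equal(sum(m@mass), 1, tolerance = 1e-12)
  expect_equal(sum(m@mass > 0), 1)
  # independence of the generative axes: joint ~ outer product of marginals
  set.seed(17)
  big <- simulateAngularTrajectories(
    conditionModel("big", populations = list(populationParams(
      1, dTheta = 5, dChi = 5, sigmaTheta = 1, sigmaChi = 1)),
      nTrajectories = 1500L), seed = 17)
  edges <- defaultLogEdges(10, 0.05, 100)
  jm <- densityMap2D(big, dt = 0.1, thetaEdges = edges, chiEdges = edges)
  n <- sum(table(trajectoryData(big)$trajectory_id) - 1)
  obs <- jm@mass * n
  expected <- outer(rowSums(jm@mass), colSums(jm@mass)) * n
  sel <- expected > 5
  chi2 <- sum((obs[sel] - expected[sel])^2 / expected[sel])
  df <- sum(sel) - 1
  expect_lt(chi2, qchisq(0.999, df))
  # difference maps: self-difference zero; mismatched binning errors
  diff <- differenceMap(jm, jm)
  expect_true(diff@isDifference)
  expect_equal(max(abs(diff@mass)), 0)
  expect_equal(sum(diff@mass), 0, tolerance = 1e-12)
  other <- densityMap2D(drift, dt = 0.1)
  expect_error(differenceMap(jm, other), "identical bin edges")
})
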