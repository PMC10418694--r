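# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms evaluated directly, brute-force
# enumeration, and literal double loops.

# closed-form Bragg/ring arithmetic (independent of R/geometry.R internals)
oracleBragg <- function(d, keV) asin((12.3984 / keV) / (2 * d))
oracleRadius <- function(d, keV, L = 50) L * tan(2 * oracleBragg(d, keV))
D111 <- 4.0782 / sqrt(3)
D200 <- 4.0782 / 2

# literal double-loop pooled-pair MSD
bruteMSD <- function(trajList, k) {
  acc <- c()
  for (x in trajList) {
    n <- length(x)
    if (n > k) for (i in 1:(n - k)) acc <- c(acc, (x[i + k] - x[i])^2)
  }
  if (length(acc)) mean(acc) else NA_real_
}

brutePairCount <- function(trajList, k) {
  sum(vapply(trajList, function(x) max(length(x) - k, 0), numeric(1)))
}

# exhaustive minimum-cost matching between two frames of spots under the
# linking objective: sum of squared displacements of matched pairs plus
# maxDisp^2 per unmatched spot, pairs farther than maxDisp forbidden.
# Returns the assignment vector (index into frame b per spot of frame a,
# NA = unmatched) of minimal cost; ties broken toward low (i, j).
bruteMatch <- function(x1, y1, x2, y2, maxDisp) {
  na <- length(x1); nb <- length(x2)
  pen <- maxDisp^2
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  best <- NULL; bestCost <- Inf
  # enumerate all injective partial mappings a -> b
  recur <- function(i, assign, used, cost) {
    if (cost >= bestCost + 1e-12) return()
    if (i > na) {
      total <- cost + pen * sum(is.na(assign)) + pen * (nb - sum(!is.na(assign)))
      if (total < bestCost - 1e-12) {
        bestCost <<- total; best <<- assign
      }
      return()
    }
    for (j in seq_len(nb)) {
      if (!used[j] && d2[i, j] <= pen) {
        used[j] <- TRUE
        assign[i] <- j
        recur(i + 1, assign, used, cost + d2[i, j])
        used[j] <- FALSE
        assign[i] <- NA_integer_
      }
    }
    recur(i + 1, assign, used, cost)
  }
  recur(1L, rep(NA_integer_, na), rep(FALSE, nb), 0)
  list(assign = best, cost = bestCost)
}

# matching cost of a linkSpots result between two specific frames
linkCost <- function(linked, f1, f2, maxDisp) {
  a <- linked[linked$frame == f1, ]
  b <- linked[linked$frame == f2, ]
  matched <- intersect(a$trajectory_id, b$trajectory_id)
  cost <- 0
  for (id in matched) {
    pa <- a[a$trajectory_id == id, ]
    pb <- b[b$trajectory_id == id, ]
    cost <- cost + (pa$x_px - pb$x_px)^2 + (pa$y_px - pb$y_px)^2
  }
  cost + maxDisp^2 * (nrow(a) - length(matched)) +
    maxDisp^2 * (nrow(b) - length(matched))
}

# render an ideal Gaussian spot onto a frame (independent of R/render.R)
paintSpot <- function(frame, r0, c0, photons = 2000, sigma = 1.5) {
  rr <- seq_len(nrow(frame)); cc <- seq_len(ncol(frame))
  frame + photons *
    outer(exp(-(rr - r0)^2 / (2 * sigma^2)),
          exp(-(cc - c0)^2 / (2 * sigma^2))) / (2 * pi * sigma^2)
}

# build an AngularTrajectorySet from a list of (theta, chi) matrices
atsFromList <- function(mats, tau = 0.1, label = "test") {
  df <- do.call(rbind, lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    data.frame(trajectory_id = i, t_ms = (seq_len(nrow(m)) - 1) * tau,
               theta_mrad = m[, 1] - m[1, 1], chi_mrad = m[, 2] - m[1, 2],
               ring = "Au111")
  }))
  angularTrajectorySet(df, frameInterval = tau, conditionLabel = label)
}

# reference slope/intercept pairs used for generator calibration (mrad^2/ms,
# mrad^2)
REF <- list(
  CCh = list(theta = c(20.70, 7.143), chi = c(18.45, 14.796)),
  BGT = list(theta = c(14.77, 5.147), chi = c(2.311, 6.206)))

# fitted slope for one condition/axis/seed under the standard protocol
protocolSlope <- function(model, axis, seed) {
  fitMSDLinear(ensembleMSD(simulateAngularTrajectories(model, seed = seed),
                           axis, maxLagFrames = 7),
               lagRange = c(0.1, 0.7))
}
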