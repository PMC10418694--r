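# Spot detection and trajectory linking: a Crocker-Grier-style pipeline
# (band-pass filter -> thresholded local maxima -> intensity-weighted
# centroid) followed by optimal per-frame bipartite linking with no gap
# closing. Replaces the external tracker named in the original workflow so
# the computation is owned here.

#' Detect diffraction spots in one detector frame
#'
#' Candidate pixels are local maxima of the band-pass-filtered frame (Gaussian
#' low-pass minus boxcar background) exceeding \code{median + thresholdK * MAD}
#' of the filtered image. Each candidate becomes a spot with an
#' intensity-weighted centroid over a window of radius \code{minSeparation};
#' candidates closer than \code{minSeparation} are pruned keeping the
#' brighter.
#'
#' @param frame numeric matrix (rows x cols) of non-negative intensities.
#' @param minSeparation minimum spot separation and centroid window radius,
#'   px.
#' @param thresholdK detection threshold in multiples of the robust noise
#'   scale (MAD, scaled to estimate sigma).
#' @param smoothSigma Gaussian low-pass width, px.
#' @return data.frame with one row per spot: \code{x_px}, \code{y_px}
#'   (subpixel centroid; x = column, y = row), \code{intensity} (summed
#'   background-subtracted counts) and \code{sigma} (RMS spot width, px).
#' @export
detectSpots <- function(frame, minSeparation = 5, thresholdK = 5,
                        smoothSigma = 1) {
  if (!length(frame)) stop("frame is empty")
  if (any(!is.finite(frame))) stop("frame contains non-finite pixel values")
  lp <- EBImage::gblur(frame, sigma = smoothSigma)
  side <- 2L * as.integer(ceiling(minSeparation)) + 1L
  box <- matrix(1 / side^2, side, side)
  bg <- EBImage::filter2(frame, box)
  bpRaw <- lp - bg # unclipped: keeps the noise distribution two-sided so
  bp <- pmax(bpRaw, 0) # the MAD below is a meaningful noise scale
  # relative floor guards against FFT numerical dust on noise-free frames
  thr <- max(stats::median(bpRaw) + thresholdK * stats::mad(bpRaw),
             1e-6 * max(bp))
  dil <- EBImage::dilate(bp, EBImage::makeBrush(side, shape = "box"))
  cand <- which(bp >= dil & bpRaw > thr & bp > 0, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), sigma = numeric(0)))
  vals <- bp[cand]
  o <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  vals <- vals[o]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- cand[keep, , drop = FALSE]
      d2 <- (kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2
      ok <- all(d2 >= minSeparation^2)
    }
    keep[i] <- ok
  }
  cand <- cand[keep, , drop = FALSE]
  # centroid on the low-pass image minus the frame's flat background level:
  # the boxcar term of the band-pass subtracts part of the spot's own mass
  # asymmetrically and would bias sub-pixel centroids
  flat <- pmax(lp - stats::median(lp), 0)
  w <- as.integer(ceiling(minSeparation))
  nr <- nrow(frame); nc <- ncol(frame)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    rr <- max(1, r0 - w):min(nr, r0 + w)
    cc <- max(1, c0 - w):min(nc, c0 + w)
    win <- flat[rr, cc, drop = FALSE]
    tot <- sum(win)
    if (tot <= 0) return(NULL)
    rw <- rowSums(win); cw <- colSums(win)
    yc <- sum(rr * rw) / tot
    xc <- sum(cc * cw) / tot
    var2 <- (sum((rr - yc)^2 * rw) + sum((cc - xc)^2 * cw)) / tot
    data.frame(x_px = xc, y_px = yc, intensity = tot,
               sigma = sqrt(var2 / 2))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), sigma = numeric(0))
  rownames(out) <- NULL
  out
}

#' Detect spots in every frame of a movie
#'
#' @param movie a [DetectorMovie-class].
#' @param ... passed to [detectSpots()].
#' @return data.frame of spots with a \code{frame} column (1-based).
#' @export
detectMovieSpots <- function(movie, ...) {
  stopifnot(is(movie, "DetectorMovie"))
  nT <- dim(movie@frames)[3]
  res <- lapply(seq_len(nT), function(t) {
    s <- detectSpots(movie@frames[, , t], ...)
    if (nrow(s)) cbind(frame = t, s) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), intensity = numeric(0),
                      sigma = numeric(0))
  res
}

# Assignment between two frames' spots, trackpy-like objective: minimise the
# sum of squared displacements of matched pairs plus maxDisplacement^2 per
# unmatched spot; pairs farther than maxDisplacement are forbidden. Returns
# integer vector m with m[i] = index in (x2, y2) matched to spot i, NA if
# unmatched. Equal-cost solutions are broken toward low (i, j) index pairs
# via an infinitesimal cost perturbation.
matchFrames <- function(x1, y1, x2, y2, maxDisplacement) {
  na <- length(x1); nb <- length(x2)
  if (na == 0L || nb == 0L) return(rep(NA_integer_, na))
  pen <- maxDisplacement^2
  big <- 4 * pen * (na + nb + 1)
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  d2[d2 > pen] <- big
  eps <- pen * 1e-9
  tie <- outer(seq_len(na), seq_len(nb), function(i, j) (i - 1) * nb + j)
  n <- na + nb
  cost <- matrix(0, n, n)
  cost[seq_len(na), seq_len(nb)] <- d2 + eps * tie / (na * nb + 1)
  cost[seq_len(na), nb + seq_len(na)] <- big
  cost[na + seq_len(nb), seq_len(nb)] <- big
  cost[cbind(seq_len(na), nb + seq_len(na))] <- pen
  cost[cbind(na + seq_len(nb), seq_len(nb))] <- pen
  a <- solveAssignment(cost)
  m <- a[seq_len(na)]
  m[m > nb] <- NA_integer_
  sel <- !is.na(m)
  bad <- sel & d2[cbind(seq_len(na), ifelse(sel, m, 1L))] >= big
  m[bad] <- NA_integer_
  m
}

#' Link per-frame spots into trajectories
#'
#' Between each pair of consecutive frames, solves the
#' minimum-total-squared-displacement bipartite assignment among spot pairs
#' closer than \code{maxDisplacement} (unmatched spots pay
#' \code{maxDisplacement^2}, the standard non-link penalty). Unmatched spots
#' terminate or start trajectories; there is no gap closing (memory = 0), so
#' a spot missing for one frame splits its track. Every spot belongs to
#' exactly one trajectory.
#'
#' @param spots data.frame with columns \code{frame}, \code{x_px},
#'   \code{y_px} and optionally \code{intensity}, \code{sigma}.
#' @param maxDisplacement linking radius, px.
#' @return data.frame of the input spots plus a \code{trajectory_id} column,
#'   ordered by (trajectory_id, frame). Singleton trajectories (length 1) are
#'   retained here and dropped by [filterTrajectories()].
#' @export
linkSpots <- function(spots, maxDisplacement = 10) {
  if (maxDisplacement <= 0) stop("maxDisplacement must be positive")
  need <- c("frame", "x_px", "y_px")
  if (!all(need %in% names(spots)))
    stop("spots must have columns: ", paste(need, collapse = ", "))
  if (!nrow(spots)) return(cbind(spots, trajectory_id = integer(0)))
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  byFrame <- split(seq_len(nrow(spots)), spots$frame)
  traj <- integer(nrow(spots))
  nextId <- 1L
  # open trajectory id per spot of the previous frame
  prevIdx <- byFrame[[as.character(frames[1])]]
  traj[prevIdx] <- seq.int(nextId, length.out = length(prevIdx))
  nextId <- nextId + length(prevIdx)
  if (length(frames) > 1) {
    for (fi in seq_along(frames)[-1]) {
      curIdx <- byFrame[[as.character(frames[fi])]]
      consecutive <- (frames[fi] - frames[fi - 1]) == 1
      if (consecutive && length(prevIdx)) {
        m <- matchFrames(spots$x_px[prevIdx], spots$y_px[prevIdx],
                         spots$x_px[curIdx], spots$y_px[curIdx],
                         maxDisplacement)
        for (i in seq_along(prevIdx)) {
          if (!is.na(m[i])) traj[curIdx[m[i]]] <- traj[prevIdx[i]]
        }
      }
      newIdx <- curIdx[traj[curIdx] == 0L]
      traj[newIdx] <- seq.int(nextId, length.out = length(newIdx))
      nextId <- nextId + length(newIdx)
      prevIdx <- curIdx
    }
  }
  out <- cbind(spots, trajectory_id = traj)
  out <- out[order(out$trajectory_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter linked trajectories by length and ring membership
#'
#' Keeps trajectories of at least \code{minLength} spots whose majority ring
#' label is a real ring: a trajectory is assigned the plane whose band
#' contains at least \code{minRingFraction} of its spots, else \code{"none"}
#' and it is discarded. Kept/discarded counts and the mean trackable span
#' are recorded on the result as the \code{"trackingLog"} attribute and
#' reported via [message()].
#'
#' @param linked data.frame from [linkSpots()].
#' @param geometry a [BeamlineGeometry-class].
#' @param minLength minimum trajectory length, frames.
#' @param bands ring bands, see [defaultRingBands()].
#' @param minRingFraction fraction of spots that must fall inside the
#'   assigned band.
#' @param verbose emit the run-log message.
#' @return data.frame of kept spots with a \code{ring} column, plus the
#'   \code{"trackingLog"} attribute (list: nTotal, nKept, nDiscarded,
#'   meanTrackMs).
#' @export
filterTrajectories <- function(linked, geometry, minLength = 2,
                               bands = defaultRingBands(geometry),
                               minRingFraction = 0.8, verbose = TRUE) {
  if (!nrow(linked)) {
    out <- cbind(linked, ring = character(0))
    attr(out, "trackingLog") <- list(nTotal = 0L, nKept = 0L,
                                     nDiscarded = 0L, meanTrackMs = NA_real_)
    return(out)
  }
  dr <- (linked$y_px - geometry@beamCenter[1]) * geometry@pixelPitch
  dc <- (linked$x_px - geometry@beamCenter[2]) * geometry@pixelPitch
  ringEach <- classifyRing(sqrt(dr^2 + dc^2), bands)
  ids <- split(seq_len(nrow(linked)), linked$trajectory_id)
  lab <- vapply(ids, function(ix) {
    tab <- table(ringEach[ix])
    top <- names(tab)[which.max(tab)]
    if (top != "none" && tab[top] / length(ix) >= minRingFraction) top
    else "none"
  }, character(1))
  len <- lengths(ids)
  keep <- len >= minLength & lab != "none"
  keptIdx <- unlist(ids[keep], use.names = FALSE)
  out <- linked[keptIdx, , drop = FALSE]
  out$ring <- rep(lab[keep], len[keep])
  rownames(out) <- NULL
  log <- list(
    nTotal = length(ids),
    nKept = sum(keep),
    nDiscarded = sum(!keep),
    meanTrackMs = if (any(keep))
      mean(len[keep]) * geometry@frameInterval else NA_real_)
  attr(out, "trackingLog") <- log
  if (verbose)
    message(sprintf(
      "filterTrajectories: kept %d / %d trajectories (mean track %.3g ms)",
      log$nKept, log$nTotal, log$meanTrackMs))
  out
}
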