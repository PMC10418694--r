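# File formats: trajectory tables as CSV (UTF-8, '.' decimal), movies as
# multi-page 16-bit grayscale TIFF, reports and manifests as JSON. Floating
# values survive a write -> read round trip to 15 significant digits.

trajectorySchema <- c("trajectory_id", "frame", "t_ms", "x_px", "y_px",
                      "intensity", "ring")

checkSchema <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Read and write linked spot-trajectory tables
#'
#' One row per spot with columns \code{trajectory_id}, \code{frame},
#' \code{t_ms}, \code{x_px}, \code{y_px}, \code{intensity}, \code{ring}.
#'
#' @param tracks data.frame of linked, ring-labelled spots (see
#'   [filterTrajectories()]); a \code{t_ms} column is added from
#'   \code{geometry} if absent.
#' @param path CSV file path.
#' @param geometry optional [BeamlineGeometry-class] used to fill
#'   \code{t_ms} from \code{frame}.
#' @return \code{readTrajectoryCSV}: the validated data.frame.
#' @export
writeTrajectoryCSV <- function(tracks, path, geometry = NULL) {
  if (!"t_ms" %in% names(tracks) && !is.null(geometry))
    tracks$t_ms <- (tracks$frame - 1) * geometry@frameInterval
  if (!"intensity" %in% names(tracks)) tracks$intensity <- NA_real_
  checkSchema(tracks, trajectorySchema, "trajectory table")
  utils::write.csv(format(tracks[, trajectorySchema], digits = 15,
                          trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  checkSchema(df, trajectorySchema, basename(path))
  df
}

#' Read and write angular-trajectory tables
#'
#' Long-format CSV with columns \code{trajectory_id}, \code{t_ms},
#' \code{theta_mrad}, \code{chi_mrad}, \code{ring}.
#'
#' @param object an [AngularTrajectorySet-class].
#' @param path CSV file path.
#' @param frameInterval,conditionLabel metadata for the reconstructed set.
#' @return \code{readAngularCSV}: an [AngularTrajectorySet-class].
#' @export
writeAngularCSV <- function(object, path) {
  utils::write.csv(format(object@data, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeAngularCSV
#' @export
readAngularCSV <- function(path, frameInterval = 0.1,
                           conditionLabel = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  checkSchema(df, c("trajectory_id", "t_ms", "theta_mrad", "chi_mrad",
                    "ring"), basename(path))
  angularTrajectorySet(df, frameInterval = frameInterval,
                       conditionLabel = conditionLabel)
}

#' Read and write detector movies as multi-page 16-bit TIFF
#'
#' Intensities are stored as 16-bit counts (0-65535); pixel values round-trip
#' exactly.
#'
#' @param movie a [DetectorMovie-class].
#' @param path TIFF file path.
#' @param geometry a [BeamlineGeometry-class] for the reconstructed movie.
#' @param conditionLabel condition label for the reconstructed movie.
#' @return \code{readMovieTIFF}: a [DetectorMovie-class].
#' @export
writeMovieTIFF <- function(movie, path) {
  nT <- dim(movie@frames)[3]
  pages <- lapply(seq_len(nT), function(t)
    pmin(pmax(round(movie@frames[, , t]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeMovieTIFF
#' @export
readMovieTIFF <- function(path, geometry = beamlineGeometry(),
                          conditionLabel = "unknown") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- round(pages[[t]] * 65535)
  new("DetectorMovie", frames = frames, geometry = geometry,
      conditionLabel = conditionLabel)
}

#' Write an analysis report as JSON
#'
#' @param report named list.
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeReportJSON
#' @export
readReportJSON <- function(path) jsonlite::read_json(path)

# 64-bit-ish FNV-1a over a string, reported as hex; used for config
# provenance hashes (stable across sessions, no external dependency)
fnv1aHash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
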