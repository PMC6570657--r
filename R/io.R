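# File interchange: trajectory CSV (dialect: track_id,frame,x_um,y_um[,state])
# and 16-bit multi-page TIFF movies.

#' Read trajectories from CSV
#'
#' Expects the header \code{track_id,frame,x_um,y_um} with optional
#' \code{state}, \code{true_x_um}, \code{true_y_um} columns; one row per
#' localization, frames 0-based and consecutive within a track. Malformed
#' rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param acq an \linkS4class{AcquisitionParams} to attach.
#' @return a \linkS4class{TrajectorySet}.
#' @export
readTrajectories <- function(path, acq = AcquisitionParams()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no trajectory rows in ", path)
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$x_um))) |
               !is.finite(suppressWarnings(as.numeric(df$y_um))))
  if (length(bad))
    stop("non-numeric coordinates at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  if (anyDuplicated(df[c("track_id", "frame")])) {
    d <- which(duplicated(df[c("track_id", "frame")]))
    stop("duplicate (track, frame) pairs at line(s) ",
         paste(utils::head(d + 1L, 10), collapse = ", "))
  }
  TrajectorySet(df, acquisition = acq)
}

#' Write trajectories to CSV
#'
#' Writes the trajectory table in the interchange dialect. Coordinates are
#' written with full precision, so \code{readTrajectories(writeTrajectories(x))}
#' round-trips exactly.
#'
#' @param set a \linkS4class{TrajectorySet}.
#' @param path output CSV path.
#' @param keepTruth keep ground-truth columns (\code{state},
#'   \code{true_x_um}, \code{true_y_um}) when present.
#' @return \code{path}, invisibly.
#' @export
writeTrajectories <- function(set, path, keepTruth = TRUE) {
  tr <- set@tracks
  cols <- c("track_id", "frame", "x_um", "y_um")
  if (keepTruth)
    cols <- c(cols, intersect(c("state", "true_x_um", "true_y_um"), names(tr)))
  out <- tr[cols]
  for (cl in setdiff(cols, c("track_id", "frame", "state")))
    out[[cl]] <- sprintf("%.17g", out[[cl]])  # exact double round-trip
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a movie as 16-bit multi-page TIFF
#'
#' @param movie a \linkS4class{MovieStack} (counts in 0..65535).
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeMovie <- function(movie, path) {
  frames <- lapply(seq_len(dim(movie@data)[3]),
                   function(f) movie@data[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF path.
#' @param pixelSize,frameInterval acquisition metadata (not stored in the
#'   TIFF; supplied from configuration).
#' @return a \linkS4class{MovieStack}.
#' @export
readMovie <- function(path, pixelSize = 0.076, frameInterval = 1 / 30) {
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- round(frames[[f]] * 65535)
  new("MovieStack", data = arr, pixelSize = pixelSize,
      frameInterval = frameInterval)
}

#' Write cluster tracks to CSV
#'
#' @param tracks a \linkS4class{ClusterTrackSet}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeClusterTracks <- function(tracks, path) {
  utils::write.csv(tracks@tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
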