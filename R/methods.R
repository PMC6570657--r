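# Accessor and show methods.

#' @describeIn TrajectorySet-class number of trajectories.
#' @param x a TrajectorySet.
#' @export
setMethod("nTracks", "TrajectorySet", function(x) length(unique(x@tracks$track_id)))

#' @describeIn TrajectorySet-class frames per trajectory (named vector).
#' @export
setMethod("trackLengths", "TrajectorySet", function(x) {
  tab <- table(x@tracks$track_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
})

#' @describeIn TrajectorySet-class the localization table as a data.frame.
#' @param row.names,optional,... passed on (unused).
#' @export
setMethod("as.data.frame", "TrajectorySet",
          function(x, row.names = NULL, optional = FALSE, ...) x@tracks)

setMethod("show", "TrajectorySet", function(object) {
  n <- nTracks(object)
  len <- trackLengths(object)
  cat("TrajectorySet with", n, "trajectories,",
      nrow(object@tracks), "localizations\n")
  if (n > 0)
    cat(sprintf("  length: mean %.1f, range %d-%d frames\n",
                mean(len), min(len), max(len)))
  cat(sprintf("  acquisition: %.1f fps, %.0f nm px, sigma %.0f nm\n",
              1 / object@acquisition@frameInterval,
              1000 * object@acquisition@pixelSize,
              1000 * object@acquisition@localizationSigma))
})

#' @describeIn StepSeries-class number of trajectories.
#' @param x a StepSeries.
#' @export
setMethod("nTracks", "StepSeries", function(x) length(x@trajStart))

#' @describeIn StepSeries-class steps per trajectory.
#' @export
setMethod("trackLengths", "StepSeries", function(x) x@trajLength)

setMethod("show", "StepSeries", function(object) {
  cat("StepSeries:", nrow(object@steps), "displacement steps over",
      length(object@trajStart), "trajectories, dt =",
      signif(object@dt, 4), "s\n")
})

#' @describeIn DiffusiveStateModel-class diffusion coefficients.
#' @param x a DiffusiveStateModel.
#' @export
setMethod("diffusionCoefficients", "DiffusiveStateModel", function(x, ...) x@D)

#' @describeIn DiffusiveStateModel-class per-frame transition matrix.
#' @export
setMethod("transitionMatrix", "DiffusiveStateModel", function(x) x@transitionMatrix)

#' @describeIn DiffusiveStateModel-class stationary distribution of the chain.
#' @export
setMethod("stationaryDistribution", "DiffusiveStateModel",
          function(x) .stationary(x@transitionMatrix))

#' Dwell times of a diffusive-state model
#'
#' Expected consecutive time in each state, dt / (1 - A_kk).
#' @param x a DiffusiveStateModel.
#' @param dt frame interval in seconds.
#' @export
dwellTimesModel <- function(x, dt = 1 / 30) dt / (1 - diag(x@transitionMatrix))

setMethod("show", "DiffusiveStateModel", function(object) {
  cat("DiffusiveStateModel with", object@nStates, "state(s)\n")
  cat("  D (um^2/s):", paste(signif(object@D, 4), collapse = ", "), "\n")
  cat("  stationary occupancy:",
      paste(signif(.stationary(object@transitionMatrix), 4), collapse = ", "), "\n")
})

#' @describeIn VBPosterior-class posterior-mean diffusion coefficients
#'   (um^2/s); see \code{\link{summarizeModel}} for the localization-error
#'   corrected variant.
#' @param x a VBPosterior.
#' @export
setMethod("diffusionCoefficients", "VBPosterior", function(x, ...) {
  v <- x@gammaRate / pmax(x@gammaShape - 1, 0.5)  # E[1/lambda], per-coordinate
  as.numeric(v / (2 * x@dt))
})

#' @describeIn VBPosterior-class posterior-mean transition matrix.
#' @export
setMethod("transitionMatrix", "VBPosterior",
          function(x) x@transCounts / rowSums(x@transCounts))

#' @describeIn VBPosterior-class expected step-count occupancy.
#' @export
setMethod("occupancies", "VBPosterior",
          function(x) x@stepCounts / sum(x@stepCounts))

#' @describeIn VBPosterior-class attained evidence lower bound.
#' @export
setMethod("elbo", "VBPosterior", function(x) x@elbo)

setMethod("show", "VBPosterior", function(object) {
  cat("VBPosterior: K =", object@K, " ELBO =", format(object@elbo, digits = 8),
      if (object@converged) "(converged)\n" else "(NOT converged)\n")
  cat("  D (um^2/s):",
      paste(signif(diffusionCoefficients(object), 4), collapse = ", "), "\n")
  cat("  occupancy:",
      paste(signif(occupancies(object), 3), collapse = ", "), "\n")
})

#' @describeIn HMMSummary-class diffusion coefficients.
#' @param x an HMMSummary.
#' @export
setMethod("diffusionCoefficients", "HMMSummary", function(x, ...) x@D)

#' @describeIn HMMSummary-class occupancies.
#' @export
setMethod("occupancies", "HMMSummary", function(x) x@occupancy)

#' @describeIn HMMSummary-class dwell times (seconds).
#' @export
setMethod("dwellTimes", "HMMSummary", function(x) x@dwell)

setMethod("show", "HMMSummary", function(object) {
  cat("Diffusive-state HMM summary (", object@K, " states )\n")
  for (k in seq_len(object@K))
    cat(sprintf("  S%d: D = %.3g um^2/s, occupancy = %.1f%%, dwell = %.3g s\n",
                k, object@D[k], 100 * object@occupancy[k], object@dwell[k]))
})

#' @describeIn ModelSelectionResult-class selected model size.
#' @param x a ModelSelectionResult.
#' @export
setMethod("chosenK", "ModelSelectionResult", function(x) x@chosenK)

#' @describeIn ModelSelectionResult-class best lower bound per model size.
#' @export
setMethod("elbo", "ModelSelectionResult", function(x) x@elboPerK)

setMethod("show", "ModelSelectionResult", function(object) {
  cat("Maximum-evidence model selection over K =",
      paste(range(as.integer(names(object@elboPerK))), collapse = ".."), "\n")
  for (k in names(object@elboPerK))
    cat(sprintf("  K=%s: ELBO = %.6g%s\n", k, object@elboPerK[[k]],
                if (as.integer(k) == object@chosenK) "  <- chosen" else ""))
})

setMethod("show", "MSDFit", function(object) {
  cat(sprintf("MSDFit: D_100ms = %.4g um^2/s, intercept = %.3g um^2, R^2 = %.3f (%d lags)\n",
              object@d100ms, object@intercept, object@rSquared, object@nLagsFit))
})

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("MovieStack: %d x %d px, %d frames, %.0f nm px, %.1f fps\n",
              d[1], d[2], d[3], 1000 * object@pixelSize, 1 / object@frameInterval))
})

setMethod("show", "ClusterTrackSet", function(object) {
  cat("ClusterTrackSet:", length(unique(object@tracks$cluster_id)), "tracks,",
      nrow(object@tracks), "detections over", object@nFrames, "frames\n")
})

setMethod("show", "LifetimeFit", function(object) {
  cat(sprintf("LifetimeFit: tau* = %.4g s (%s policy, %d tracks)\n",
              object@tauStar, object@policy, object@nTracks))
})
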