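# Generics shared across the package's containers.

#' Number of trajectories in a set
#' @param x a \linkS4class{TrajectorySet} or \linkS4class{StepSeries}.
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' Trajectory lengths (frames or steps)
#' @param x a \linkS4class{TrajectorySet} or \linkS4class{StepSeries}.
#' @export
setGeneric("trackLengths", function(x) standardGeneric("trackLengths"))

#' Per-state diffusion coefficients (um^2/s)
#' @param x a model, posterior or summary object.
#' @param ... further arguments for methods.
#' @export
setGeneric("diffusionCoefficients",
           function(x, ...) standardGeneric("diffusionCoefficients"))

#' Per-frame transition matrix (point estimate)
#' @param x a model or posterior object.
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' Stationary state distribution
#' @param x a \linkS4class{DiffusiveStateModel}.
#' @export
setGeneric("stationaryDistribution",
           function(x) standardGeneric("stationaryDistribution"))

#' Dwell times per state (seconds)
#' @param x a model or summary object.
#' @export
setGeneric("dwellTimes", function(x) standardGeneric("dwellTimes"))

#' State occupancies
#' @param x a summary or posterior object.
#' @export
setGeneric("occupancies", function(x) standardGeneric("occupancies"))

#' Evidence lower bound (nats)
#' @param x a \linkS4class{VBPosterior} or \linkS4class{ModelSelectionResult}.
#' @export
setGeneric("elbo", function(x) standardGeneric("elbo"))

#' Selected number of diffusive states
#' @param x a \linkS4class{ModelSelectionResult}.
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
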