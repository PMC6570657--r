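#' @import methods
NULL

# ---------------------------------------------------------------------------
# Acquisition parameters
# ---------------------------------------------------------------------------

#' Acquisition parameters of a single-molecule tracking experiment
#'
#' Frame interval, camera pixel size and the per-coordinate localization
#' error of the imaging system. Defaults correspond to video-rate TIRF
#' imaging of disc membranes: 30 frames per second, 76 nm pixels and
#' ~50 nm localization error.
#'
#' @slot frameInterval frame interval in seconds.
#' @slot pixelSize camera pixel size in micrometres.
#' @slot localizationSigma per-coordinate localization error (standard
#'   deviation) in micrometres.
#' @export
setClass("AcquisitionParams",
  representation(frameInterval = "numeric", pixelSize = "numeric",
                 localizationSigma = "numeric"),
  prototype(frameInterval = 1 / 30, pixelSize = 0.076, localizationSigma = 0.050))

setValidity("AcquisitionParams", function(object) {
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a single positive number (seconds)")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (micrometres)")
  if (length(object@localizationSigma) != 1L ||
      !is.finite(object@localizationSigma) || object@localizationSigma <= 0)
    return("localizationSigma must be a single positive number (micrometres)")
  TRUE
})

#' @param frameInterval,pixelSize,localizationSigma see slots.
#' @rdname AcquisitionParams-class
#' @export
AcquisitionParams <- function(frameInterval = 1 / 30, pixelSize = 0.076,
                              localizationSigma = 0.050) {
  new("AcquisitionParams", frameInterval = frameInterval, pixelSize = pixelSize,
      localizationSigma = localizationSigma)
}

# ---------------------------------------------------------------------------
# Confining geometry
# ---------------------------------------------------------------------------

#' Confining geometry for trajectory simulation
#'
#' The membrane area within which simulated particles diffuse: a disc
#' (default 8 um diameter, the size of an exposed photoreceptor disc
#' membrane), a rectangle (default 1 x 2 um, mimicking a small lobule),
#' or unbounded free space. Boundaries act by specular reflection.
#'
#' @slot shape one of \code{"disc"}, \code{"rectangle"}, \code{"unbounded"}.
#' @slot diameter disc diameter in micrometres (disc only).
#' @slot width,height rectangle sides in micrometres (rectangle only).
#' @slot centre centre of the geometry (micrometres, length 2).
#' @export
setClass("DiscGeometry",
  representation(shape = "character", diameter = "numeric", width = "numeric",
                 height = "numeric", centre = "numeric"),
  prototype(shape = "disc", diameter = 8, width = 1, height = 2, centre = c(0, 0)))

setValidity("DiscGeometry", function(object) {
  if (!object@shape %in% c("disc", "rectangle", "unbounded"))
    return("shape must be 'disc', 'rectangle' or 'unbounded'")
  if (object@shape == "disc" && (!is.finite(object@diameter) || object@diameter <= 0))
    return("disc diameter must be strictly positive")
  if (object@shape == "rectangle" &&
      (object@width <= 0 || object@height <= 0 ||
       !all(is.finite(c(object@width, object@height)))))
    return("rectangle width and height must be strictly positive")
  if (length(object@centre) != 2L || !all(is.finite(object@centre)))
    return("centre must be two finite coordinates")
  TRUE
})

#' @param shape,diameter,width,height,centre see slots.
#' @rdname DiscGeometry-class
#' @export
DiscGeometry <- function(shape = c("disc", "rectangle", "unbounded"),
                         diameter = 8, width = 1, height = 2, centre = c(0, 0)) {
  shape <- match.arg(shape)
  new("DiscGeometry", shape = shape, diameter = diameter, width = width,
      height = height, centre = centre)
}

# ---------------------------------------------------------------------------
# Diffusive-state model
# ---------------------------------------------------------------------------

#' Markov-switching diffusion model
#'
#' A K-state hidden Markov model of lateral diffusion: each state k has a
#' diffusion coefficient D_k (um^2/s) and the hidden state evolves as a
#' discrete-time Markov chain with per-frame transition matrix A. The dwell
#' time of state k is dt / (1 - A_kk) and the relative occupancies are the
#' stationary distribution of A.
#'
#' @slot nStates number of diffusive states K.
#' @slot D per-state diffusion coefficients, um^2/s.
#' @slot transitionMatrix K x K row-stochastic per-frame transition matrix.
#' @slot initialDistribution length-K initial state probabilities.
#' @export
setClass("DiffusiveStateModel",
  representation(nStates = "integer", D = "numeric",
                 transitionMatrix = "matrix", initialDistribution = "numeric"))

setValidity("DiffusiveStateModel", function(object) {
  K <- object@nStates
  if (length(object@D) != K || any(!is.finite(object@D)) || any(object@D <= 0))
    return("diffusion coefficients must be K finite positive values")
  A <- object@transitionMatrix
  if (!is.matrix(A) || nrow(A) != K || ncol(A) != K)
    return("transitionMatrix must be K x K")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-12))
    return("transitionMatrix rows must be probabilities summing to 1 (tol 1e-12)")
  p <- object@initialDistribution
  if (length(p) != K || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    return("initialDistribution must be K probabilities summing to 1")
  # irreducibility: every state reachable from every other
  if (K > 1) {
    M <- diag(K) + A
    for (i in seq_len(K)) M <- M %*% (diag(K) + A)
    if (any(M <= 0)) return("transition matrix must define an irreducible chain")
  }
  TRUE
})

#' @param D,transitionMatrix,initialDistribution see slots; when
#'   \code{initialDistribution} is missing the stationary distribution of
#'   \code{transitionMatrix} is used.
#' @rdname DiffusiveStateModel-class
#' @export
DiffusiveStateModel <- function(D, transitionMatrix = NULL,
                                initialDistribution = NULL) {
  K <- length(D)
  if (is.null(transitionMatrix)) transitionMatrix <- diag(K)
  if (!is.matrix(transitionMatrix))
    stop("transitionMatrix must be a K x K matrix")
  if (is.null(initialDistribution))
    initialDistribution <- .stationary(transitionMatrix)
  new("DiffusiveStateModel", nStates = as.integer(K), D = as.numeric(D),
      transitionMatrix = transitionMatrix,
      initialDistribution = as.numeric(initialDistribution))
}

# stationary distribution of a row-stochastic matrix (left eigenvector)
.stationary <- function(A) {
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# ---------------------------------------------------------------------------
# Trajectory set
# ---------------------------------------------------------------------------

#' A set of single-particle trajectories
#'
#' Time-ordered 2-D localizations for a set of tracked particles, held as a
#' long-format data.frame with columns \code{track_id}, \code{frame},
#' \code{x_um}, \code{y_um}, optionally \code{state} (ground-truth diffusive
#' state of the step starting at that frame, simulation only) and
#' \code{true_x_um}/\code{true_y_um} (noise-free positions, retained for
#' oracle checks and never read by inference).
#'
#' @slot tracks the long-format localization table.
#' @slot acquisition an \linkS4class{AcquisitionParams}.
#' @export
setClass("TrajectorySet",
  representation(tracks = "data.frame", acquisition = "AcquisitionParams"))

setValidity("TrajectorySet", function(object) {
  tr <- object@tracks
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(tr)))
    return(paste("tracks must have columns", paste(need, collapse = ", ")))
  if (nrow(tr) > 0) {
    if (!all(is.finite(tr$x_um)) || !all(is.finite(tr$y_um)))
      return("positions must be finite")
    for (id in unique(tr$track_id)) {
      f <- tr$frame[tr$track_id == id]
      if (length(f) < 2L) return("every trajectory must have at least 2 frames")
      if (any(diff(f) != 1L)) return("frames must increase by exactly 1 within a track")
    }
  }
  TRUE
})

#' @param tracks,acquisition see slots.
#' @rdname TrajectorySet-class
#' @export
TrajectorySet <- function(tracks, acquisition = AcquisitionParams()) {
  tracks$track_id <- as.character(tracks$track_id)
  tracks$frame <- as.integer(tracks$frame)
  o <- order(tracks$track_id, tracks$frame)
  new("TrajectorySet", tracks = tracks[o, , drop = FALSE], acquisition = acquisition)
}

# ---------------------------------------------------------------------------
# Displacement series
# ---------------------------------------------------------------------------

#' Per-trajectory displacement sequences
#'
#' Displacement vectors between consecutive frames for every trajectory,
#' concatenated, with trajectory boundaries preserved. The HMM stage works
#' on this representation.
#'
#' @slot steps n x 2 matrix of displacements (um).
#' @slot trajStart 1-based offset of each trajectory's first step.
#' @slot trajLength number of steps per trajectory.
#' @slot dt frame interval in seconds.
#' @export
setClass("StepSeries",
  representation(steps = "matrix", trajStart = "integer",
                 trajLength = "integer", dt = "numeric"))

setValidity("StepSeries", function(object) {
  if (ncol(object@steps) != 2L) return("steps must have two columns")
  if (!all(is.finite(object@steps))) return("displacements must be finite")
  if (length(object@trajStart) != length(object@trajLength))
    return("trajStart and trajLength must have equal length")
  if (sum(object@trajLength) != nrow(object@steps))
    return("trajectory lengths must sum to the number of steps")
  TRUE
})

# ---------------------------------------------------------------------------
# MSD containers
# ---------------------------------------------------------------------------

#' Time-averaged mean-square-displacement curve
#'
#' @slot lags lag times in seconds (multiples of the frame interval).
#' @slot msd MSD at each lag, um^2.
#' @slot nPairs number of (overlapping) displacement pairs per lag.
#' @export
setClass("MSDCurve",
  representation(lags = "numeric", msd = "numeric", nPairs = "integer"))

setValidity("MSDCurve", function(object) {
  if (length(object@msd) != length(object@lags) ||
      length(object@nPairs) != length(object@lags))
    return("lags, msd and nPairs must have equal length")
  if (any(object@msd < -1e-12)) return("msd must be non-negative")
  if (any(diff(object@lags) <= 0)) return("lags must be strictly increasing")
  TRUE
})

#' Short-lag diffusion-coefficient fit of an MSD curve
#'
#' Ordinary least-squares fit of the MSD over lags up to 100 ms with free
#' intercept; \code{d100ms} is slope/4. \code{rSquared} is the goodness of
#' a separate linear fit over the first quarter of available lags and is
#' the statistic used by the trajectory filter.
#'
#' @slot d100ms effective diffusion coefficient within 100 ms, um^2/s.
#' @slot intercept fitted intercept, um^2 (absorbs the static localization
#'   offset 4 sigma^2).
#' @slot rSquared goodness of linear fit over the first quarter of lags.
#' @slot nLagsFit number of lags used for the slope.
#' @export
setClass("MSDFit",
  representation(d100ms = "numeric", intercept = "numeric",
                 rSquared = "numeric", nLagsFit = "integer"))

# ---------------------------------------------------------------------------
# VB-HMM containers
# ---------------------------------------------------------------------------

#' Variational posterior of the diffusion HMM
#'
#' Conjugate posterior over the parameters of a K-state diffusion HMM:
#' gamma posteriors over the per-state step precisions (per-coordinate
#' precision of a displacement, i.e. 1/(2 D_k dt)), Dirichlet posteriors
#' over each transition-matrix row and over the initial distribution, the
#' evidence lower bound attained, and expected per-state step counts.
#' States are ordered by ascending diffusion coefficient.
#'
#' @slot K number of states.
#' @slot dt frame interval, seconds.
#' @slot gammaShape,gammaRate gamma posterior parameters per state.
#' @slot transCounts K x K Dirichlet posterior counts (rows).
#' @slot initCounts length-K Dirichlet posterior counts (initial distribution).
#' @slot priorShape,priorRate,priorTrans prior hyperparameters.
#' @slot stepCounts expected number of steps assigned to each state.
#' @slot elbo evidence lower bound (nats).
#' @slot elboTrace lower-bound trace of the winning restart.
#' @slot converged logical convergence flag.
#' @export
setClass("VBPosterior",
  representation(K = "integer", dt = "numeric",
                 gammaShape = "numeric", gammaRate = "numeric",
                 transCounts = "matrix", initCounts = "numeric",
                 priorShape = "numeric", priorRate = "numeric",
                 priorTrans = "numeric", stepCounts = "numeric",
                 elbo = "numeric", elboTrace = "numeric", converged = "logical"))

setValidity("VBPosterior", function(object) {
  if (!is.finite(object@elbo)) return("lower bound must be finite")
  if (any(object@transCounts < object@priorTrans - 1e-9))
    return("Dirichlet counts cannot fall below the prior counts")
  TRUE
})

#' Point-estimate summary of a fitted diffusion HMM
#'
#' @slot D posterior-mean diffusion coefficients, um^2/s (ascending).
#' @slot occupancy expected fraction of steps per state.
#' @slot dwell dwell times, seconds (dt / (1 - A_kk)).
#' @slot rates off-diagonal transition rates, 1/s (A_kj / dt).
#' @slot K number of reported states (after pruning).
#' @slot dt frame interval, seconds.
#' @export
setClass("HMMSummary",
  representation(D = "numeric", occupancy = "numeric", dwell = "numeric",
                 rates = "matrix", K = "integer", dt = "numeric"))

#' Maximum-evidence model-selection result
#'
#' @slot elboPerK best lower bound attained for each model size.
#' @slot chosenK model size attaining the maximal lower bound (ties broken
#'   towards the smaller model).
#' @slot fits list of \linkS4class{VBPosterior}, one per K.
#' @export
setClass("ModelSelectionResult",
  representation(elboPerK = "numeric", chosenK = "integer", fits = "list"))

# ---------------------------------------------------------------------------
# Cluster kinetics / movies / cluster tracks
# ---------------------------------------------------------------------------

#' Kinetics of transient receptor clusters
#'
#' Parameters of the cluster nucleation / extinction / diffusion process
#' used to simulate semi-multimolecule fluorescence movies, plus the
#' rendering parameters (point-spread function, brightness, camera noise).
#'
#' @slot nucleationRate cluster nucleation rate, events per second per disc.
#' @slot meanLifetime mean cluster lifetime tau*, seconds.
#' @slot clusterDiffusion cluster diffusion coefficient, um^2/s.
#' @slot radialPlacementScale Gaussian scale (um) of the centre-biased
#'   radial placement density.
#' @slot clusterRadius hydrodynamic cluster radius, metres (used by the
#'   Saffman-Delbrueck sizing stage).
#' @slot brightness expected photons per cluster per frame.
#' @slot monomerCount,monomerBrightness number and brightness of background
#'   single-molecule spots.
#' @slot psfSigma Gaussian PSF standard deviation, um.
#' @slot cameraGaussianSd additive Gaussian read noise (counts).
#' @slot cameraOffset camera baseline offset (counts).
#' @export
setClass("ClusterKinetics",
  representation(nucleationRate = "numeric", meanLifetime = "numeric",
                 clusterDiffusion = "numeric", radialPlacementScale = "numeric",
                 clusterRadius = "numeric", brightness = "numeric",
                 monomerCount = "numeric", monomerBrightness = "numeric",
                 psfSigma = "numeric", cameraGaussianSd = "numeric",
                 cameraOffset = "numeric"),
  prototype(nucleationRate = 10, meanLifetime = 0.1, clusterDiffusion = 0.08,
            radialPlacementScale = 1.5, clusterRadius = 90e-9, brightness = 400,
            monomerCount = 15, monomerBrightness = 60, psfSigma = 0.15,
            cameraGaussianSd = 3, cameraOffset = 100))

setValidity("ClusterKinetics", function(object) {
  vals <- c(object@nucleationRate, object@meanLifetime, object@clusterDiffusion,
            object@radialPlacementScale, object@brightness, object@monomerCount,
            object@monomerBrightness, object@psfSigma, object@cameraGaussianSd,
            object@cameraOffset)
  if (any(!is.finite(vals)) || any(vals < 0))
    return("rates, lifetimes, brightnesses and noise levels must be >= 0")
  TRUE
})

#' @param ... slot values overriding the defaults.
#' @rdname ClusterKinetics-class
#' @export
ClusterKinetics <- function(...) new("ClusterKinetics", ...)

#' Fluorescence movie stack
#'
#' @slot data height x width x frames intensity array (counts, >= 0).
#' @slot pixelSize pixel size, um.
#' @slot frameInterval frame interval, seconds.
#' @export
setClass("MovieStack",
  representation(data = "array", pixelSize = "numeric", frameInterval = "numeric"))

setValidity("MovieStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a height x width x frames array")
  if (d[3] < 2L) return("a movie needs at least 2 frames")
  if (any(object@data < 0)) return("intensities must be non-negative")
  TRUE
})

#' Detected (or ground-truth) cluster tracks
#'
#' Long-format table of cluster spot tracks: columns \code{cluster_id},
#' \code{frame}, \code{x_um}, \code{y_um}, \code{intensity}. Coordinates are
#' in the movie frame (origin at the image corner). \code{nFrames} records
#' the movie length so censoring (tracks touching the first or last frame)
#' can be judged.
#'
#' @slot tracks the long-format track table.
#' @slot frameInterval frame interval, seconds.
#' @slot nFrames number of frames in the source movie.
#' @export
setClass("ClusterTrackSet",
  representation(tracks = "data.frame", frameInterval = "numeric",
                 nFrames = "integer"))

#' Exponential cluster-lifetime fit
#'
#' @slot tauStar maximum-likelihood mean lifetime, seconds.
#' @slot nTracks number of track durations used.
#' @slot policy censoring policy applied ("discard" or "censored").
#' @slot minFrames minimum detectable duration, frames.
#' @export
setClass("LifetimeFit",
  representation(tauStar = "numeric", nTracks = "integer", policy = "character",
                 minFrames = "integer"))

setValidity("LifetimeFit", function(object) {
  if (!is.finite(object@tauStar) || object@tauStar <= 0)
    return("tauStar must be strictly positive")
  TRUE
})

# ---------------------------------------------------------------------------
# Hydrodynamics / stoichiometry parameter classes
# ---------------------------------------------------------------------------

#' Membrane hydrodynamics parameters for Saffman-Delbrueck sizing
#'
#' @slot membraneViscosity membrane (2-D) viscosity, Pa s (default 0.8,
#'   i.e. 8 Poise).
#' @slot aqueousViscosity viscosity of the aqueous phase on either side,
#'   Pa s (default 0.02, i.e. 0.2 Poise).
#' @slot membraneThickness bilayer thickness, m (default 4 nm).
#' @slot temperature absolute temperature, K (default 298).
#' @export
setClass("SDParams",
  representation(membraneViscosity = "numeric", aqueousViscosity = "numeric",
                 membraneThickness = "numeric", temperature = "numeric"),
  prototype(membraneViscosity = 0.8, aqueousViscosity = 0.02,
            membraneThickness = 4e-9, temperature = 298))

setValidity("SDParams", function(object) {
  v <- c(object@membraneViscosity, object@aqueousViscosity,
         object@membraneThickness, object@temperature)
  if (any(!is.finite(v)) || any(v <= 0)) return("all parameters must be > 0")
  if (object@membraneViscosity <= object@aqueousViscosity)
    return("membrane viscosity must exceed the aqueous viscosity")
  TRUE
})

#' @param membraneViscosity,aqueousViscosity,membraneThickness,temperature
#'   see slots. Viscosities in Pa s; use \code{poise()} to convert.
#' @rdname SDParams-class
#' @export
SDParams <- function(membraneViscosity = 0.8, aqueousViscosity = 0.02,
                     membraneThickness = 4e-9, temperature = 298) {
  new("SDParams", membraneViscosity = membraneViscosity,
      aqueousViscosity = aqueousViscosity,
      membraneThickness = membraneThickness, temperature = temperature)
}

#' Convert a viscosity from Poise to Pa s
#' @param x viscosity in Poise.
#' @return viscosity in Pa s.
#' @export
poise <- function(x) x * 0.1

#' Stoichiometry of transducin engagement by photoactivated rhodopsin
#'
#' @slot rhodopsinsPerGt rhodopsin : transducin ratio in the disc
#'   membrane (default 10, from the ~100:10 rhodopsin:Gt ratio).
#' @slot rhodopsinsPerComplex rhodopsins sequestered per engaged complex
#'   (default 2: the photoactivated receptor binds Gt as a 2:1 complex).
#' @export
setClass("StoichiometryParams",
  representation(rhodopsinsPerGt = "numeric", rhodopsinsPerComplex = "numeric"),
  prototype(rhodopsinsPerGt = 10, rhodopsinsPerComplex = 2))

setValidity("StoichiometryParams", function(object) {
  if (object@rhodopsinsPerGt < 1 || object@rhodopsinsPerComplex < 1)
    return("both stoichiometry parameters must be >= 1")
  TRUE
})

#' @param rhodopsinsPerGt,rhodopsinsPerComplex see slots.
#' @rdname StoichiometryParams-class
#' @export
StoichiometryParams <- function(rhodopsinsPerGt = 10, rhodopsinsPerComplex = 2) {
  new("StoichiometryParams", rhodopsinsPerGt = rhodopsinsPerGt,
      rhodopsinsPerComplex = rhodopsinsPerComplex)
}
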