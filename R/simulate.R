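# Synthetic trajectory generation: Markov-switching Brownian motion in
# confined disc / lobule geometry, track-length sampling and localization
# noise. These generators emulate video-rate single-molecule tracking on
# an exposed disc membrane and provide ground truth for every downstream
# stage.

#' Sample trajectory lengths
#'
#' Draws track lengths from a shifted-geometric distribution with a hard
#' minimum, matching the reported experimental length statistics (mean ~35
#' frames, minimum >15 frames). The geometric tail mimics stochastic track
#' termination (probe bleaching / loss of tracking).
#'
#' @param n number of lengths to draw.
#' @param meanLength target mean length in frames (default 35).
#' @param minLength minimum length in frames (default 16).
#' @param seed optional integer seed.
#' @return integer vector of lengths, all \code{>= minLength}.
#' @export
sampleTrackLengths <- function(n, meanLength = 35, minLength = 16, seed = NULL) {
  if (meanLength <= minLength)
    stop("meanLength must exceed minLength")
  if (!is.null(seed)) set.seed(seed)
  p <- 1 / (1 + meanLength - minLength)
  as.integer(minLength + stats::rgeom(n, p))
}

# uniform random points inside a geometry
.sampleStart <- function(n, geometry) {
  if (geometry@shape == "disc") {
    R <- geometry@diameter / 2
    r <- R * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(geometry@centre[1] + r * cos(th), geometry@centre[2] + r * sin(th))
  } else if (geometry@shape == "rectangle") {
    cbind(geometry@centre[1] + stats::runif(n, -geometry@width / 2, geometry@width / 2),
          geometry@centre[2] + stats::runif(n, -geometry@height / 2, geometry@height / 2))
  } else {
    matrix(0, n, 2)
  }
}

# Specular reflection of a single sub-step that may overshoot the boundary.
# p: current position (inside); q: proposed position. Returns the reflected
# end point.
.reflect <- function(q, p, geometry) {
  if (geometry@shape == "unbounded") return(q)
  if (geometry@shape == "rectangle") {
    # fold each coordinate independently into the box
    half <- c(geometry@width, geometry@height) / 2
    z <- q - geometry@centre
    for (i in 1:2) {
      L <- 2 * half[i]
      # triangular-wave fold of the infinite line onto [-half, half]
      u <- (z[i] + half[i]) %% (2 * L)
      if (u > L) u <- 2 * L - u
      z[i] <- u - half[i]
    }
    return(z + geometry@centre)
  }
  # disc: iterate specular reflections off the circle
  R <- geometry@diameter / 2
  c0 <- geometry@centre
  for (iter in 1:64) {
    if (sum((q - c0)^2) <= R^2) return(q)
    d <- q - p
    # solve |p + t d - c0|^2 = R^2 for t in (0, 1]
    a <- sum(d^2)
    b <- 2 * sum((p - c0) * d)
    cc <- sum((p - c0)^2) - R^2
    disc <- b^2 - 4 * a * cc
    t <- (-b + sqrt(max(disc, 0))) / (2 * a)
    t <- min(max(t, 0), 1)
    hit <- p + t * d
    nrm <- (hit - c0) / sqrt(sum((hit - c0)^2))
    rem <- q - hit
    rem <- rem - 2 * sum(rem * nrm) * nrm  # mirror the overshoot
    p <- hit
    q <- hit + rem
  }
  # pathological step (much larger than the disc): clamp to the boundary
  c0 + (q - c0) / sqrt(sum((q - c0)^2)) * R * 0.999999
}

#' Simulate Markov-switching Brownian trajectories
#'
#' Generates \code{nTraj} trajectories of Markov-switching Brownian motion:
#' the hidden diffusive state evolves as a discrete-time Markov chain per
#' frame and each displacement is isotropic Gaussian with per-coordinate
#' variance \code{2 * D_state * dt}. Motion is confined to the geometry by
#' specular reflection. Starting points are uniform over the geometry.
#' Ground-truth states are stored in the \code{state} column (one label per
#' displacement step, attached to the step's first frame).
#'
#' Positions returned are noise-free; add measurement error with
#' \code{\link{applyLocalizationNoise}}.
#'
#' @param model a \linkS4class{DiffusiveStateModel}.
#' @param geometry a \linkS4class{DiscGeometry} (default 8-um disc).
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param nTraj number of trajectories.
#' @param lengths integer vector of per-trajectory lengths (frames), or
#'   \code{NULL} to draw from \code{\link{sampleTrackLengths}}.
#' @param meanLength,minLength length distribution parameters used when
#'   \code{lengths} is NULL.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a \linkS4class{TrajectorySet}.
#' @export
simulateTrajectories <- function(model, geometry = DiscGeometry(),
                                 acq = AcquisitionParams(), nTraj = 400,
                                 lengths = NULL, meanLength = 35,
                                 minLength = 16, seed = NULL) {
  stopifnot(is(model, "DiffusiveStateModel"), is(geometry, "DiscGeometry"))
  validObject(model)
  if (nTraj < 1) stop("nTraj must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dt <- acq@frameInterval
  K <- model@nStates
  A <- model@transitionMatrix
  sdStep <- sqrt(2 * model@D * dt)
  gsize <- switch(geometry@shape,
                  disc = geometry@diameter,
                  rectangle = min(geometry@width, geometry@height),
                  unbounded = Inf)
  if (max(sdStep) > gsize)
    warning("single-step standard deviation exceeds the geometry size; ",
            "motion is boundary-dominated")

  if (is.null(lengths))
    lengths <- sampleTrackLengths(nTraj, meanLength, minLength)
  if (length(lengths) != nTraj) lengths <- rep_len(lengths, nTraj)
  if (any(lengths < 2)) stop("trajectory lengths must be >= 2 frames")

  starts <- .sampleStart(nTraj, geometry)
  out <- vector("list", nTraj)
  bounded <- geometry@shape != "unbounded"
  for (i in seq_len(nTraj)) {
    L <- lengths[i]
    nStep <- L - 1L
    # hidden chain: one state per displacement step
    st <- integer(nStep)
    st[1] <- sample.int(K, 1L, prob = model@initialDistribution)
    if (nStep > 1) for (t in 2:nStep) st[t] <- sample.int(K, 1L, prob = A[st[t - 1], ])
    dx <- stats::rnorm(nStep, 0, sdStep[st])
    dy <- stats::rnorm(nStep, 0, sdStep[st])
    pos <- matrix(0, L, 2)
    pos[1, ] <- starts[i, ]
    if (!bounded) {
      pos[-1, 1] <- starts[i, 1] + cumsum(dx)
      pos[-1, 2] <- starts[i, 2] + cumsum(dy)
    } else {
      for (t in seq_len(nStep)) {
        pos[t + 1, ] <- .reflect(pos[t, ] + c(dx[t], dy[t]), pos[t, ], geometry)
      }
    }
    out[[i]] <- data.frame(
      track_id = sprintf("traj%04d", i),
      frame = 0:(L - 1L),
      x_um = pos[, 1], y_um = pos[, 2],
      state = c(st, NA_integer_),
      true_x_um = pos[, 1], true_y_um = pos[, 2])
  }
  TrajectorySet(do.call(rbind, out), acquisition = acq)
}

#' Add localization noise to trajectory positions
#'
#' Adds independent zero-mean Gaussian measurement error of standard
#' deviation \code{sigma} per coordinate per frame to the true positions.
#' True positions are retained in \code{true_x_um}/\code{true_y_um};
#' inference stages only ever read the observed columns.
#'
#' @param set a \linkS4class{TrajectorySet}.
#' @param sigma localization error (um per coordinate); default taken from
#'   the set's acquisition parameters.
#' @param seed optional integer seed.
#' @return a \linkS4class{TrajectorySet} with noisy observed positions.
#' @export
applyLocalizationNoise <- function(set, sigma = set@acquisition@localizationSigma,
                                   seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- set@tracks
  if (is.null(tr$true_x_um)) { tr$true_x_um <- tr$x_um; tr$true_y_um <- tr$y_um }
  if (sigma > 0) {
    n <- nrow(tr)
    tr$x_um <- tr$true_x_um + stats::rnorm(n, 0, sigma)
    tr$y_um <- tr$true_y_um + stats::rnorm(n, 0, sigma)
  }
  TrajectorySet(tr, acquisition = set@acquisition)
}
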