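# Semi-multimolecule movie simulation: transiently nucleating, centrally
# confined diffusing clusters rendered as Gaussian PSF spots over a
# single-molecule background, with Poisson shot noise and Gaussian read
# noise.

# sample cluster centres: 2-D Gaussian of given scale truncated to the disc
.sampleClusterCentre <- function(n, R, scale) {
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- (n - got) * 2 + 8
    x <- stats::rnorm(m, 0, scale); y <- stats::rnorm(m, 0, scale)
    ok <- which(x^2 + y^2 < R^2)
    take <- ok[seq_len(min(length(ok), n - got))]
    if (length(take)) {
      out[(got + 1):(got + length(take)), ] <- cbind(x[take], y[take])
      got <- got + length(take)
    }
  }
  out
}

# add a Gaussian spot (total expected photons 'amp') to a photon image
.renderSpot <- function(img, x, y, amp, sigmaPx, px) {
  H <- nrow(img); W <- ncol(img)
  cx <- x / px + 0.5  # pixel-centre coordinates (1-based)
  cy <- y / px + 0.5
  w <- ceiling(4 * sigmaPx)
  j0 <- max(1L, floor(cx) - w); j1 <- min(W, floor(cx) + w)
  i0 <- max(1L, floor(cy) - w); i1 <- min(H, floor(cy) + w)
  if (j0 > j1 || i0 > i1) return(img)
  gx <- stats::dnorm(j0:j1, mean = cx, sd = sigmaPx)
  gy <- stats::dnorm(i0:i1, mean = cy, sd = sigmaPx)
  # normalized so the window integrates to 'amp' photons
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] +
    amp * outer(gy / sum(gy), gx / sum(gx))
  img
}

#' Simulate a fluorescence movie of transient receptor clusters
#'
#' Clusters nucleate as a Poisson process in time, are placed with a
#' centre-biased radial density (2-D Gaussian of scale
#' \code{radialPlacementScale} truncated to the disc), live exponentially
#' distributed lifetimes of mean \code{meanLifetime}, and diffuse with
#' \code{clusterDiffusion} (reflected at the disc boundary). Each frame is
#' rendered as Gaussian PSF spots for live clusters plus diffusing
#' single-molecule background spots, then Poisson shot noise, a camera
#' baseline and Gaussian read noise are applied and the image is quantized
#' to 16-bit counts.
#'
#' The movie coordinate origin is the image corner; the disc centre sits
#' at the image centre. Ground truth (birth/death frames and per-frame
#' positions of every cluster that appears in at least one frame) is
#' returned alongside the movie, together with the full list of simulated
#' continuous lifetimes for oracle checks.
#'
#' @param kinetics a \linkS4class{ClusterKinetics}.
#' @param geometry a \linkS4class{DiscGeometry} (disc).
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param nFrames number of frames (>= 2).
#' @param seed integer seed.
#' @param margin image margin around the disc, um.
#' @return a list with \code{movie} (a \linkS4class{MovieStack}),
#'   \code{truth} (a \linkS4class{ClusterTrackSet}), \code{nBirths}
#'   (number of nucleation events over the movie) and \code{lifetimes}
#'   (continuous lifetimes in seconds of all nucleated clusters).
#' @export
simulateClusterMovie <- function(kinetics, geometry = DiscGeometry(),
                                 acq = AcquisitionParams(), nFrames,
                                 seed = NULL, margin = 0.5) {
  if (nFrames < 2) stop("nFrames must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  px <- acq@pixelSize
  dt <- acq@frameInterval
  R <- geometry@diameter / 2
  W <- H <- as.integer(ceiling((geometry@diameter + 2 * margin) / px))
  if (W < 1) stop("zero-size image")
  half <- W * px / 2  # disc centre offset in corner-origin coordinates
  Ttot <- nFrames * dt

  nB <- stats::rpois(1, kinetics@nucleationRate * Ttot)
  births <- sort(stats::runif(nB, 0, Ttot))
  lifetimes <- if (nB > 0) stats::rexp(nB, rate = 1 / max(kinetics@meanLifetime, 1e-12)) else numeric(0)
  if (kinetics@meanLifetime == 0) lifetimes <- rep(0, nB)
  centres <- if (nB > 0) .sampleClusterCentre(nB, R, max(kinetics@radialPlacementScale, 1e-6)) else matrix(0, 0, 2)

  sigPx <- kinetics@psfSigma / px
  photon <- array(0, dim = c(H, W, nFrames))
  truthRows <- vector("list", nB)
  geomDisc <- DiscGeometry("disc", diameter = geometry@diameter)
  sdC <- sqrt(2 * kinetics@clusterDiffusion * dt)
  for (i in seq_len(nB)) {
    k0 <- ceiling(births[i] / dt)             # first frame index (0-based)
    k1 <- floor((births[i] + lifetimes[i]) / dt)
    k1 <- min(k1, nFrames - 1L)
    if (k1 < k0 || k0 > nFrames - 1L) next
    nf <- k1 - k0 + 1L
    pos <- matrix(0, nf, 2)
    pos[1, ] <- centres[i, ]
    if (nf > 1) for (t in 2:nf)
      pos[t, ] <- .reflect(pos[t - 1, ] + stats::rnorm(2, 0, sdC),
                           pos[t - 1, ], geomDisc)
    posImg <- pos + half  # to corner-origin coordinates
    for (t in seq_len(nf)) {
      photon[, , k0 + t] <- .renderSpot(photon[, , k0 + t], posImg[t, 1],
                                        posImg[t, 2], kinetics@brightness,
                                        sigPx, px)
    }
    truthRows[[i]] <- data.frame(cluster_id = sprintf("c%04d", i),
                                 frame = k0:k1, x_um = posImg[, 1],
                                 y_um = posImg[, 2],
                                 intensity = kinetics@brightness)
  }

  # diffusing single-molecule background
  nM <- round(kinetics@monomerCount)
  if (nM > 0) {
    mpos <- .sampleStart(nM, geomDisc)
    sdM <- sqrt(2 * 1.0 * dt)  # monomer-like mobility, 1 um^2/s
    for (f in seq_len(nFrames)) {
      for (m in seq_len(nM)) {
        if (f > 1) mpos[m, ] <- .reflect(mpos[m, ] + stats::rnorm(2, 0, sdM),
                                         mpos[m, ], geomDisc)
        photon[, , f] <- .renderSpot(photon[, , f], mpos[m, 1] + half,
                                     mpos[m, 2] + half,
                                     kinetics@monomerBrightness, sigPx, px)
      }
    }
  }

  counts <- array(stats::rpois(length(photon), lambda = photon),
                  dim = dim(photon))
  counts <- counts + kinetics@cameraOffset +
    round(stats::rnorm(length(counts), 0, kinetics@cameraGaussianSd))
  counts <- pmin(pmax(counts, 0), 65535)

  truth <- do.call(rbind, truthRows[!vapply(truthRows, is.null, logical(1))])
  if (is.null(truth))
    truth <- data.frame(cluster_id = character(0), frame = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        intensity = numeric(0))
  list(movie = new("MovieStack", data = counts, pixelSize = px,
                   frameInterval = dt),
       truth = new("ClusterTrackSet", tracks = truth, frameInterval = dt,
                   nFrames = as.integer(nFrames)),
       nBirths = nB, lifetimes = lifetimes)
}
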