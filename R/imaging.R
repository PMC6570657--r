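# Movie analysis: LoG spot detection, nearest-neighbour linking,
# exponential lifetime fitting, kymographs and radial/transverse
# intensity profiles.

# 1-D convolution down the columns with edge replication
.convCols <- function(img, k) {
  w <- (length(k) - 1L) / 2L
  H <- nrow(img)
  pad <- rbind(img[rep(1L, w), , drop = FALSE], img,
               img[rep(H, w), , drop = FALSE])
  out <- matrix(0, H, ncol(img))
  for (m in seq_along(k))
    out <- out + k[m] * pad[m:(m + H - 1L), , drop = FALSE]
  out
}

.convSep <- function(img, kRow, kCol) t(.convCols(t(.convCols(img, kCol)), kRow))

# scale-normalized Laplacian-of-Gaussian response; bright blobs -> maxima
.logResponse <- function(img, sigmaPx) {
  w <- max(2L, ceiling(3.5 * sigmaPx))
  x <- (-w):w
  g <- stats::dnorm(x, 0, sigmaPx); g <- g / sum(g)
  g2 <- (x^2 - sigmaPx^2) / sigmaPx^4 * stats::dnorm(x, 0, sigmaPx)
  g2 <- g2 - mean(g2)  # zero response to constant background
  rxx <- .convSep(img, g2, g)
  ryy <- .convSep(img, g, g2)
  -sigmaPx^2 * (rxx + ryy)
}

#' Detect fluorescent spots in one frame
#'
#' Laplacian-of-Gaussian blob detection at the PSF scale: local maxima of
#' the scale-normalized LoG response exceeding
#' \code{snrThreshold} robust-noise units (MAD of the response) are kept
#' and refined to sub-pixel positions by an intensity-weighted centroid
#' over the 3 x 3 neighbourhood of the response.
#'
#' @param frame an image matrix (rows = y, columns = x) or a
#'   \linkS4class{MovieStack} with a frame index.
#' @param pixelSize pixel size, um.
#' @param psfSigma PSF standard deviation, um.
#' @param snrThreshold detection threshold in robust-noise units.
#' @param frameIndex frame to analyse when \code{frame} is a MovieStack.
#' @return a data.frame with \code{x_um}, \code{y_um} (corner-origin
#'   coordinates) and \code{intensity} (background-subtracted 3x3 sum).
#' @export
detectSpots <- function(frame, pixelSize = 0.076, psfSigma = 0.15,
                        snrThreshold = 5, frameIndex = 1L) {
  if (is(frame, "MovieStack")) {
    pixelSize <- frame@pixelSize
    frame <- frame@data[, , frameIndex]
  }
  if (length(frame) == 0) stop("empty image")
  if (psfSigma <= 0) stop("psfSigma must be > 0")
  H <- nrow(frame); W <- ncol(frame)
  sigPx <- psfSigma / pixelSize
  resp <- .logResponse(frame, sigPx)
  noise <- stats::mad(as.vector(resp))
  if (noise == 0) noise <- stats::sd(as.vector(resp))
  if (is.na(noise) || noise == 0) return(
    data.frame(x_um = numeric(0), y_um = numeric(0), intensity = numeric(0)))
  thr <- snrThreshold * noise
  # strict local maxima over the 8-neighbourhood, excluding the border
  inner <- resp[2:(H - 1), 2:(W - 1)]
  isMax <- inner > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    isMax <- isMax & (inner >= resp[2:(H - 1) + di, 2:(W - 1) + dj])
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(
    data.frame(x_um = numeric(0), y_um = numeric(0), intensity = numeric(0)))
  bg <- stats::median(frame)
  out <- matrix(0, nrow(idx), 3)
  for (s in seq_len(nrow(idx))) {
    i <- idx[s, 1] + 1L; j <- idx[s, 2] + 1L
    wnd <- resp[(i - 1):(i + 1), (j - 1):(j + 1)]
    wnd <- wnd - min(wnd)
    if (sum(wnd) == 0) wnd[] <- 1
    ii <- sum(((i - 1):(i + 1)) * rowSums(wnd)) / sum(wnd)
    jj <- sum(((j - 1):(j + 1)) * colSums(wnd)) / sum(wnd)
    out[s, 1] <- (jj - 0.5) * pixelSize
    out[s, 2] <- (ii - 0.5) * pixelSize
    out[s, 3] <- sum(frame[(i - 1):(i + 1), (j - 1):(j + 1)]) - 9 * bg
  }
  data.frame(x_um = out[, 1], y_um = out[, 2], intensity = out[, 3])
}

#' Link per-frame spot detections into tracks
#'
#' Frame-to-frame greedy reciprocal nearest-neighbour linking: a spot and
#' a live track are linked when each is the other's nearest partner and
#' their distance is below \code{maxDisplacement}; unlinked spots start
#' new tracks. A track missing for up to \code{maxGap} frames stays
#' eligible; beyond that it is closed. Tracks never split or merge.
#'
#' @param spots a list of per-frame data.frames as returned by
#'   \code{\link{detectSpots}} (one entry per frame, possibly empty).
#' @param maxDisplacement maximum frame-to-frame displacement, um.
#' @param maxGap maximum number of missed frames bridged (default 0).
#' @param frameInterval frame interval, seconds.
#' @return a \linkS4class{ClusterTrackSet} (frames 0-based).
#' @export
linkSpots <- function(spots, maxDisplacement, maxGap = 0,
                      frameInterval = 1 / 30) {
  if (maxDisplacement <= 0) stop("maxDisplacement must be > 0")
  nF <- length(spots)
  tracks <- list()   # closed tracks
  active <- list()   # each: list(rows = data.frame, lastFrame)
  nextId <- 1L
  for (f in seq_len(nF)) {
    sp <- spots[[f]]
    nS <- if (is.null(sp)) 0L else nrow(sp)
    # retire tracks that exceeded the gap
    if (length(active)) {
      lastF <- vapply(active, function(a) a$lastFrame, numeric(1))
      expired <- which(lastF < f - 1L - maxGap)
      if (length(expired)) {
        tracks <- c(tracks, lapply(active[expired], function(a) a$rows))
        active <- active[-expired]
      }
    }
    assigned <- integer(0)
    if (nS > 0 && length(active) > 0) {
      ax <- vapply(active, function(a) a$rows$x_um[nrow(a$rows)], numeric(1))
      ay <- vapply(active, function(a) a$rows$y_um[nrow(a$rows)], numeric(1))
      dmat <- outer(ax, sp$x_um, "-")^2 + outer(ay, sp$y_um, "-")^2
      dmat <- sqrt(dmat)
      repeat {
        # reciprocal nearest neighbours within range
        if (all(!is.finite(dmat)) || min(dmat, na.rm = TRUE) > maxDisplacement)
          break
        nnS <- apply(dmat, 1, which.min)       # each track's nearest spot
        nnT <- apply(dmat, 2, which.min)       # each spot's nearest track
        linked <- FALSE
        for (ti in seq_along(nnS)) {
          si <- nnS[ti]
          if (is.finite(dmat[ti, si]) && dmat[ti, si] <= maxDisplacement &&
              nnT[si] == ti) {
            a <- active[[ti]]
            a$rows <- rbind(a$rows, data.frame(
              cluster_id = a$rows$cluster_id[1], frame = f - 1L,
              x_um = sp$x_um[si], y_um = sp$y_um[si],
              intensity = sp$intensity[si]))
            a$lastFrame <- f
            active[[ti]] <- a
            dmat[ti, ] <- Inf
            dmat[, si] <- Inf
            assigned <- c(assigned, si)
            linked <- TRUE
          }
        }
        if (!linked) break
      }
    }
    if (nS > 0) {
      for (si in setdiff(seq_len(nS), assigned)) {
        active[[length(active) + 1L]] <- list(
          rows = data.frame(cluster_id = sprintf("t%05d", nextId),
                            frame = f - 1L, x_um = sp$x_um[si],
                            y_um = sp$y_um[si], intensity = sp$intensity[si]),
          lastFrame = f)
        nextId <- nextId + 1L
      }
    }
  }
  tracks <- c(tracks, lapply(active, function(a) a$rows))
  tab <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(cluster_id = character(0), frame = integer(0),
               x_um = numeric(0), y_um = numeric(0), intensity = numeric(0))
  new("ClusterTrackSet", tracks = tab, frameInterval = frameInterval,
      nFrames = as.integer(nF))
}

#' Detect and link cluster spots across a whole movie
#'
#' Convenience wrapper running \code{\link{detectSpots}} on every frame
#' and \code{\link{linkSpots}} on the result.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param psfSigma PSF standard deviation, um.
#' @param snrThreshold detection threshold (robust-noise units).
#' @param maxDisplacement linking radius, um.
#' @param maxGap gap closing, frames.
#' @return a \linkS4class{ClusterTrackSet}.
#' @export
trackClusters <- function(movie, psfSigma = 0.15, snrThreshold = 5,
                          maxDisplacement = 0.5, maxGap = 0) {
  nF <- dim(movie@data)[3]
  spots <- lapply(seq_len(nF), function(f)
    detectSpots(movie@data[, , f], movie@pixelSize, psfSigma, snrThreshold))
  linkSpots(spots, maxDisplacement, maxGap, movie@frameInterval)
}

# per-track duration/censoring table
.trackDurations <- function(tracks) {
  tr <- tracks@tracks
  ids <- unique(tr$cluster_id)
  birth <- vapply(ids, function(id) min(tr$frame[tr$cluster_id == id]), numeric(1))
  death <- vapply(ids, function(id) max(tr$frame[tr$cluster_id == id]), numeric(1))
  data.frame(cluster_id = ids, birth = birth, death = death,
             duration = death - birth + 1,
             leftCensored = birth == 0,
             rightCensored = death == tracks@nFrames - 1L)
}

#' Exponential fit of cluster lifetimes
#'
#' Estimates the mean cluster lifetime tau* from detected track durations.
#' Durations are frame counts; an exponential lifetime observed on a frame
#' grid has geometrically distributed excess duration over any detection
#' floor, so the maximum-likelihood estimate is
#' \code{tau* = -dt / log(m / (1 + m))} with \code{m} the mean excess
#' duration (frames) over the minimum detectable duration
#' (\code{minFrames}, default 2: a single-frame blip is indistinguishable
#' from noise). This reduces to the familiar mean-excess estimate for
#' lifetimes much longer than a frame and is unbiased under frame
#' quantization, where the naive mean-excess is low by about half a frame.
#'
#' Policies: \code{"discard"} (default) uses only tracks censored at
#' neither movie end; \code{"censored"} additionally counts
#' right-censored tracks as exposures without an observed death
#' (censored-exponential MLE), which can only raise tau*.
#'
#' @param tracks a \linkS4class{ClusterTrackSet}.
#' @param policy censoring policy.
#' @param minFrames minimum detectable duration in frames (default 2).
#' @param minTracks minimum number of usable uncensored tracks (default 5).
#' @return a \linkS4class{LifetimeFit}.
#' @export
fitLifetime <- function(tracks, policy = c("discard", "censored"),
                        minFrames = 2L, minTracks = 5L) {
  policy <- match.arg(policy)
  dur <- .trackDurations(tracks)
  dur <- dur[dur$duration >= minFrames, , drop = FALSE]
  dt <- tracks@frameInterval
  uncensored <- dur[!dur$leftCensored & !dur$rightCensored, , drop = FALSE]
  if (nrow(uncensored) < minTracks)
    stop("need at least ", minTracks, " uncensored tracks (have ",
         nrow(uncensored), ")")
  if (policy == "discard") {
    m <- uncensored$duration - minFrames
    S <- sum(m); nEvents <- nrow(uncensored)
  } else {
    events <- dur[!dur$rightCensored, , drop = FALSE]  # deaths observed
    S <- sum(dur$duration - minFrames)  # all exposures, incl. censored
    nEvents <- nrow(events)
  }
  if (S == 0)
    stop("all durations equal the detection floor; lifetime unresolvable")
  q <- S / (S + nEvents)
  tau <- -dt / log(q)
  new("LifetimeFit", tauStar = tau, nTracks = as.integer(nEvents),
      policy = policy, minFrames = as.integer(minFrames))
}

# bilinear interpolation at (x, y) um, corner-origin, pixel centres at
# (i - 0.5) * px
.bilinear <- function(img, x, y, px) {
  H <- nrow(img); W <- ncol(img)
  fx <- pmin(pmax(x / px + 0.5, 1), W)
  fy <- pmin(pmax(y / px + 0.5, 1), H)
  j0 <- pmin(floor(fx), W - 1); i0 <- pmin(floor(fy), H - 1)
  tx <- fx - j0; ty <- fy - i0
  img[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    img[cbind(i0, j0 + 1)] * tx * (1 - ty) +
    img[cbind(i0 + 1, j0)] * (1 - tx) * ty +
    img[cbind(i0 + 1, j0 + 1)] * tx * ty
}

#' Kymograph along a line across the disc
#'
#' For every frame, the intensity is averaged across a band of
#' \code{width} pixels perpendicular to the line and sampled along it,
#' producing a position x time image.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param p0,p1 line end points, um (corner-origin).
#' @param width band width in pixels (odd; default 3).
#' @return a matrix (positions along the line x frames).
#' @export
kymograph <- function(movie, p0, p1, width = 3) {
  px <- movie@pixelSize
  d <- dim(movie@data)
  lim <- c(d[2] * px, d[1] * px)
  if (any(c(p0, p1) < 0) || p0[1] > lim[1] || p1[1] > lim[1] ||
      p0[2] > lim[2] || p1[2] > lim[2])
    stop("line end points must lie inside the image")
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / px) + 1L)
  tpar <- seq(0, 1, length.out = n)
  xs <- p0[1] + tpar * (p1[1] - p0[1])
  ys <- p0[2] + tpar * (p1[2] - p0[2])
  u <- (p1 - p0) / len
  nv <- c(-u[2], u[1])
  offs <- (seq_len(width) - (width + 1) / 2) * px
  out <- matrix(0, n, d[3])
  for (f in seq_len(d[3])) {
    acc <- numeric(n)
    for (o in offs)
      acc <- acc + .bilinear(movie@data[, , f], xs + o * nv[1],
                             ys + o * nv[2], px)
    out[, f] <- acc / length(offs)
  }
  out
}

#' Intensity profile along a line
#'
#' Bilinearly interpolated intensity along the segment from \code{p0} to
#' \code{p1}.
#'
#' @param image an image matrix.
#' @param p0,p1 end points, um (corner-origin).
#' @param pixelSize pixel size, um.
#' @param n number of samples (default: one per pixel).
#' @return a data.frame with \code{position_um} and \code{intensity}.
#' @export
transverseProfile <- function(image, p0, p1, pixelSize = 0.076, n = NULL) {
  len <- sqrt(sum((p1 - p0)^2))
  if (is.null(n)) n <- max(2L, ceiling(len / pixelSize) + 1L)
  tpar <- seq(0, 1, length.out = n)
  xs <- p0[1] + tpar * (p1[1] - p0[1])
  ys <- p0[2] + tpar * (p1[2] - p0[2])
  data.frame(position_um = tpar * len,
             intensity = .bilinear(image, xs, ys, pixelSize))
}

#' Azimuthally averaged radial intensity profile and confinement index
#'
#' Averages intensity over annular bins of r/R and reports the
#' confinement index: mean intensity inside r < 0.5 R divided by mean
#' intensity in the rim band 0.8 R < r < R. Index > 1 indicates a
#' centre-confined distribution (receptor-like); index < 1 an annular,
#' rim-enriched one (raftophobic-lipid-like).
#'
#' @param image an image matrix (e.g. a time-averaged frame).
#' @param discRadius disc radius, um.
#' @param pixelSize pixel size, um.
#' @param centre disc centre, um (corner-origin); default: intensity
#'   centroid of the image.
#' @param nBins number of radial bins (default 20).
#' @return a list with \code{radius_um} (bin centres), \code{intensity},
#'   and \code{confinementIndex}.
#' @export
radialProfile <- function(image, discRadius, pixelSize = 0.076,
                          centre = NULL, nBins = 20) {
  H <- nrow(image); W <- ncol(image)
  xs <- (seq_len(W) - 0.5) * pixelSize
  ys <- (seq_len(H) - 0.5) * pixelSize
  if (is.null(centre)) {
    tot <- sum(image)
    centre <- c(sum(colSums(image) * xs), sum(rowSums(image) * ys)) / tot
  }
  if (centre[1] < 0 || centre[1] > W * pixelSize ||
      centre[2] < 0 || centre[2] > H * pixelSize)
    stop("centre lies outside the image")
  r <- sqrt(outer(rep(1, H), (xs - centre[1])^2) +
            outer((ys - centre[2])^2, rep(1, W)))
  edges <- seq(0, discRadius, length.out = nBins + 1)
  bin <- findInterval(r, edges, rightmost.closed = TRUE)
  prof <- vapply(seq_len(nBins), function(b) {
    v <- image[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  core <- mean(image[r < 0.5 * discRadius])
  rim <- mean(image[r > 0.8 * discRadius & r < discRadius])
  list(radius_um = (edges[-1] + edges[-(nBins + 1)]) / 2, intensity = prof,
       confinementIndex = core / rim)
}

#' Diffusion coefficients of cluster tracks
#'
#' Delegates to the MSD machinery on cluster centroid tracks: every track
#' with at least \code{minFrames} consecutive detections gets a short-lag
#' diffusion-coefficient fit, and the pooled estimate is the median with
#' its standard error (1.2533 sd / sqrt(n), the asymptotic SE of a
#' median).
#'
#' @param tracks a \linkS4class{ClusterTrackSet}.
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param minFrames minimum track length used (default 4).
#' @return a list with \code{perTrack} (data.frame of per-track fits),
#'   \code{medianD}, \code{seD} and \code{n}.
#' @export
clusterMSD <- function(tracks, acq = AcquisitionParams(), minFrames = 4) {
  tr <- tracks@tracks
  ids <- unique(tr$cluster_id)
  rows <- list()
  for (id in ids) {
    sub <- tr[tr$cluster_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (nrow(sub) < minFrames || any(diff(sub$frame) != 1)) next
    cur <- computeMSD(sub, acq = acq)
    fit <- fitD100ms(cur, acq)
    rows[[length(rows) + 1L]] <- data.frame(cluster_id = id,
                                            n_frames = nrow(sub),
                                            d100ms = fit@d100ms)
  }
  if (!length(rows)) stop("no tracks with >= ", minFrames, " consecutive frames")
  perTrack <- do.call(rbind, rows)
  d <- perTrack$d100ms
  list(perTrack = perTrack, medianD = stats::median(d),
       seD = 1.2533 * stats::sd(d) / sqrt(length(d)), n = length(d))
}
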