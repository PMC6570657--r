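# Time-averaged MSD analysis: per-trajectory MSD curves, short-lag
# diffusion-coefficient estimation (D_100ms), the trajectory quality
# filters, histogram summaries and the two-sample rank comparison.

#' Time-averaged MSD of one trajectory
#'
#' Computes the time-averaged mean-square displacement with overlapping
#' windows: \code{msd(n) = mean_i |r(i+n) - r(i)|^2} for lags
#' \code{n = 1..maxLag}.
#'
#' @param xy two-column matrix of positions (um), or a data.frame with
#'   columns \code{x_um}, \code{y_um}.
#' @param maxLag maximum lag in frames (default: length - 1).
#' @param acq an \linkS4class{AcquisitionParams} supplying the frame
#'   interval.
#' @return an \linkS4class{MSDCurve}.
#' @export
computeMSD <- function(xy, maxLag = NULL, acq = AcquisitionParams()) {
  if (is.data.frame(xy)) xy <- cbind(xy$x_um, xy$y_um)
  L <- nrow(xy)
  if (is.null(L) || L < 2) stop("trajectory must have at least 2 frames")
  if (is.null(maxLag)) maxLag <- L - 1L
  if (L < maxLag + 1) stop("trajectory shorter than maxLag + 1 frames")
  msd <- numeric(maxLag)
  np <- integer(maxLag)
  for (n in seq_len(maxLag)) {
    d <- xy[(n + 1):L, , drop = FALSE] - xy[1:(L - n), , drop = FALSE]
    msd[n] <- mean(d[, 1]^2 + d[, 2]^2)
    np[n] <- L - n
  }
  new("MSDCurve", lags = seq_len(maxLag) * acq@frameInterval, msd = msd,
      nPairs = np)
}

# R^2 of a straight-line fit msd ~ lag over the given indices
.linR2 <- function(lags, msd, idx) {
  x <- lags[idx]; y <- msd[idx]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(NA_real_)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  ss_res <- sum((y - (a + b * x))^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 0 else -Inf)  # flat curve: no trend
  1 - ss_res / ss_tot
}

#' Short-lag diffusion coefficient from an MSD curve
#'
#' Fits \code{msd = intercept + 4 D t} by ordinary least squares over all
#' lags up to 100 ms (lags 1-3 at 30 fps) with a free intercept (which
#' absorbs the static localization offset 4 sigma^2); \code{d100ms} is
#' slope/4. The goodness-of-fit statistic \code{rSquared} used by the
#' trajectory filter is computed from a separate linear fit over the first
#' quarter of available lags (at least 2), following common MSD-analysis
#' practice.
#'
#' @param curve an \linkS4class{MSDCurve}.
#' @param acq an \linkS4class{AcquisitionParams} (unused beyond units;
#'   kept for interface symmetry).
#' @param window fitting window in seconds (default 0.1).
#' @return an \linkS4class{MSDFit}.
#' @export
fitD100ms <- function(curve, acq = AcquisitionParams(), window = 0.1) {
  idx <- which(curve@lags <= window + 1e-12)
  if (length(idx) < 2) stop("need at least 2 lags within the fitting window")
  x <- curve@lags[idx]; y <- curve@msd[idx]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  nAll <- length(curve@lags)
  nq <- max(2L, floor(0.25 * nAll))
  r2 <- .linR2(curve@lags, curve@msd, seq_len(min(nq, nAll)))
  new("MSDFit", d100ms = b / 4, intercept = a,
      rSquared = if (is.na(r2)) -Inf else r2, nLagsFit = length(idx))
}

# per-track MSD fits for a TrajectorySet; returns a data.frame
.msdFitTable <- function(set, window = 0.1) {
  tr <- set@tracks
  ids <- unique(tr$track_id)
  acq <- set@acquisition
  res <- lapply(ids, function(id) {
    sub <- tr[tr$track_id == id, , drop = FALSE]
    cur <- computeMSD(sub, acq = acq)
    fit <- fitD100ms(cur, acq, window = window)
    data.frame(track_id = id, n_frames = nrow(sub), d100ms = fit@d100ms,
               intercept = fit@intercept, r_squared = fit@rSquared)
  })
  do.call(rbind, res)
}

#' MSD fits for every trajectory of a set
#'
#' @param set a \linkS4class{TrajectorySet}.
#' @param window slope-fitting window in seconds (default 0.1).
#' @return a data.frame with one row per track: \code{track_id},
#'   \code{n_frames}, \code{d100ms}, \code{intercept}, \code{r_squared}.
#' @export
msdFitTable <- function(set, window = 0.1) .msdFitTable(set, window)

#' Filter trajectories by length and MSD linearity
#'
#' Applies the two trajectory quality rules used before state inference:
#' (1) tracks shorter than \code{minFrames} frames are removed (the
#' experimental minimum is >15 frames, i.e. 16); (2) tracks whose MSD-lag
#' curve bends away from a straight line - the signature of confinement,
#' e.g. by disc incisures - are removed by the goodness-of-fit criterion
#' R^2 > \code{r2Min} over the first quarter of lags.
#'
#' @param set a \linkS4class{TrajectorySet}.
#' @param minFrames minimum track length in frames (default 16).
#' @param r2Min R^2 threshold; tracks with \code{r_squared <= r2Min} are
#'   removed (default 0.8).
#' @return a list with \code{set} (the filtered \linkS4class{TrajectorySet})
#'   and \code{report} (counts removed per rule).
#' @export
filterTrajectories <- function(set, minFrames = 16, r2Min = 0.8) {
  len <- trackLengths(set)
  shortIds <- names(len)[len < minFrames]
  keep1 <- !(set@tracks$track_id %in% shortIds)
  set1 <- TrajectorySet(set@tracks[keep1, , drop = FALSE], set@acquisition)
  nAfterLen <- nTracks(set1)
  badIds <- character(0)
  if (nAfterLen > 0) {
    fits <- .msdFitTable(set1)
    badIds <- fits$track_id[fits$r_squared <= r2Min]
    set1 <- TrajectorySet(set1@tracks[!(set1@tracks$track_id %in% badIds), ,
                                      drop = FALSE], set@acquisition)
  }
  report <- list(n_input = length(len),
                 removed_short = length(shortIds),
                 removed_r2 = length(badIds),
                 n_output = nTracks(set1))
  if (report$n_output == 0)
    message("filterTrajectories: no trajectories survive the filters")
  list(set = set1, report = report)
}

#' Histogram and median of D_100ms values
#'
#' @param d numeric vector of D_100ms values (um^2/s), or the data.frame
#'   returned by \code{\link{msdFitTable}}.
#' @param binWidth histogram bin width, um^2/s (default 0.05; presentation
#'   only).
#' @return a list with \code{breaks}, \code{counts}, \code{mids} and
#'   \code{median}.
#' @export
summarizeD100ms <- function(d, binWidth = 0.05) {
  if (is.data.frame(d)) d <- d$d100ms
  if (length(d) < 1) stop("need at least one D_100ms value")
  lo <- floor(min(d) / binWidth) * binWidth
  hi <- ceiling(max(d) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       median = stats::median(d))
}

#' Two-sample Mann-Whitney U comparison
#'
#' Rank-sum comparison of two D_100ms distributions. Ties are handled by
#' midranks. For small samples (min group size <= 8) with no ties the
#' two-sided p-value is exact (enumeration); otherwise the normal
#' approximation with tie and continuity corrections is used. Computation
#' is delegated to \code{stats::wilcox.test}.
#'
#' @param a,b numeric samples.
#' @return a list with \code{U} (the U statistic for sample \code{a}),
#'   \code{p.value} (two-sided) and \code{method}.
#' @export
compareDistributions <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  hasTies <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !hasTies
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
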