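# Variational-Bayes HMM over displacement sequences.
#
# Model: displacement x_t of a trajectory, given hidden state k, is
# isotropic 2-D Gaussian with per-coordinate variance 2 D_k dt; hidden
# states follow a discrete-time Markov chain with row-stochastic per-frame
# transition matrix A. Conjugate priors: gamma on each state's step
# precision, symmetric Dirichlet on each transition row and on the initial
# distribution. VBEM alternates a forward-backward E-step under expected
# log-parameters (compiled) with closed-form M-step updates; the evidence
# lower bound (ELBO) is used both for convergence and, maximized over the
# number of states, for model selection.

#' Extract displacement sequences from trajectories
#'
#' @param set a \linkS4class{TrajectorySet} (frames must be consecutive
#'   within each track; upstream simulation/import guarantees this).
#' @param acq acquisition parameters (defaults to the set's).
#' @return a \linkS4class{StepSeries}.
#' @export
extractSteps <- function(set, acq = set@acquisition) {
  tr <- set@tracks
  ids <- unique(tr$track_id)
  steps <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- tr[tr$track_id == ids[i], , drop = FALSE]
    if (nrow(sub) < 2) stop("trajectory ", ids[i], " has fewer than 2 frames")
    if (any(diff(sub$frame) != 1L))
      stop("gap in frames within trajectory ", ids[i])
    steps[[i]] <- cbind(diff(sub$x_um), diff(sub$y_um))
  }
  lens <- vapply(steps, nrow, integer(1))
  new("StepSeries", steps = do.call(rbind, steps),
      trajStart = as.integer(c(1L, 1L + cumsum(lens[-length(lens)]))),
      trajLength = lens, dt = acq@frameInterval)
}

# deterministic per-(K, restart) seed stream derived from the master seed
.derivedSeed <- function(master, K, r)
  as.integer((as.numeric(master %% 100000L) * 10007 + K * 211 + r) %% 2147483647)

# one VBEM run from a random initialization (optimization in compiled code)
.vbemRun <- function(sq, starts, lens, K, prior, maxIter, tol) {
  # initialization: spread state variances over the quantiles of the
  # squared-step distribution, sticky random transitions
  p <- sort(stats::runif(K, 0.05, 0.95))
  v0 <- as.numeric(stats::quantile(sq, p)) / 2 * exp(stats::rnorm(K, 0, 0.2))
  v0 <- pmax(v0, 1e-12)
  diagp <- stats::runif(1, 0.5, 0.95)
  A0 <- if (K == 1) matrix(1, 1, 1) else {
    m <- matrix((1 - diagp) / (K - 1), K, K); diag(m) <- diagp; m
  }
  res <- vb_vbem_cpp(sq, starts - 1L, lens, 1 / v0, -log(v0), log(A0),
                     rep(-log(K), K), prior$a0, prior$b0, prior$alpha0,
                     maxIter, tol)
  list(q = list(a = res$a, b = res$b, alphaA = res$alphaA,
                alphaPi = res$alphaPi),
       elbo = res$elbo, elboTrace = res$elboTrace,
       converged = res$converged, Nk = as.numeric(res$Nk))
}

# order states by ascending posterior-mean step variance (i.e. ascending D)
.sortPosterior <- function(run, K) {
  o <- order(run$q$b / run$q$a)
  run$q$a <- run$q$a[o]; run$q$b <- run$q$b[o]
  run$q$alphaA <- run$q$alphaA[o, o, drop = FALSE]
  run$q$alphaPi <- run$q$alphaPi[o]
  run$Nk <- run$Nk[o]
  run
}

#' Fit the diffusion HMM at fixed K by variational Bayes
#'
#' Runs \code{nRestarts} independent VBEM optimizations from random
#' initializations and returns the one attaining the highest evidence
#' lower bound. Each restart's bound is non-decreasing across iterations.
#' Restart r of model size K draws its initialization from a seed stream
#' derived from \code{(seed, K, r)}, so results are reproducible and
#' independent of execution order. States are reported in ascending-D
#' order.
#'
#' Priors are weak and data-dominated: symmetric Dirichlet (strength
#' \code{priorTrans} per element) on each transition row and the initial
#' distribution; gamma with shape \code{priorShape} (one pseudo-count) on
#' each step precision, with prior mean matched to the pooled moment
#' estimator of the step precision.
#'
#' @param steps a \linkS4class{StepSeries}.
#' @param K number of diffusive states.
#' @param nRestarts independent VBEM restarts (default 25).
#' @param maxIter maximum VBEM sweeps per restart (default 1000).
#' @param tol relative lower-bound change declaring convergence.
#' @param seed master seed.
#' @param priorTrans,priorShape prior strengths (see Details).
#' @return a \linkS4class{VBPosterior}.
#' @export
vbFit <- function(steps, K, nRestarts = 25, maxIter = 1000, tol = 1e-8,
                  seed = 1, priorTrans = 1, priorShape = 1) {
  sq <- steps@steps[, 1]^2 + steps@steps[, 2]^2
  n <- length(sq)
  if (K > n) stop("K exceeds the total number of steps")
  prior <- list(a0 = priorShape, b0 = priorShape * mean(sq) / 2,
                alpha0 = priorTrans)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    set.seed(.derivedSeed(seed, K, r))
    run <- .vbemRun(sq, steps@trajStart, steps@trajLength, K, prior,
                    maxIter, tol)
    if (is.null(best) || run$elbo > best$elbo) best <- run
  }
  if (!best$converged)
    warning("VBEM did not converge within ", maxIter, " iterations (K=", K, ")")
  best <- .sortPosterior(best, K)
  new("VBPosterior", K = as.integer(K), dt = steps@dt,
      gammaShape = as.numeric(best$q$a), gammaRate = as.numeric(best$q$b),
      transCounts = as.matrix(best$q$alphaA),
      initCounts = as.numeric(best$q$alphaPi),
      priorShape = prior$a0, priorRate = prior$b0, priorTrans = prior$alpha0,
      stepCounts = best$Nk, elbo = best$elbo, elboTrace = best$elboTrace,
      converged = best$converged)
}

#' Maximum-evidence selection of the number of diffusive states
#'
#' Fits the diffusion HMM for K = 1..\code{kMax} and selects the model
#' size attaining the maximal evidence lower bound. Bounds equal within
#' \code{tol} (relative) are resolved towards the smaller model
#' (parsimony).
#'
#' @param steps a \linkS4class{StepSeries}.
#' @param kMax largest model size tried (default 5).
#' @param ... further arguments passed to \code{\link{vbFit}}.
#' @param tol relative lower-bound tolerance (convergence and ties).
#' @return a \linkS4class{ModelSelectionResult}.
#' @export
selectModel <- function(steps, kMax = 5, tol = 1e-8, ...) {
  if (nrow(steps@steps) < kMax)
    stop("total steps must be at least kMax")
  fits <- vector("list", kMax)
  el <- numeric(kMax)
  for (K in seq_len(kMax)) {
    fits[[K]] <- vbFit(steps, K, tol = tol, ...)
    el[K] <- fits[[K]]@elbo
  }
  names(el) <- as.character(seq_len(kMax))
  chosen <- which(el >= max(el) - tol * max(1, abs(max(el))))[1]
  new("ModelSelectionResult", elboPerK = el, chosenK = as.integer(chosen),
      fits = fits)
}

#' Point-estimate summary of a fitted posterior
#'
#' Posterior-mean diffusion coefficients, expected step-count occupancies,
#' dwell times (dt / (1 - A_kk) from the posterior-mean transition row) and
#' off-diagonal transition rates (A_kj / dt). States whose expected
#' occupancy falls below \code{pruneFloor} steps are removed before
#' reporting. By default the emission model ignores localization error,
#' as the reference inference method does, which biases each D upward by
#' about sigma^2/dt; setting \code{correctLocalization = TRUE} subtracts
#' the per-coordinate noise variance 2 sigma^2 from the posterior-mean
#' step variance before converting to D.
#'
#' @param post a \linkS4class{VBPosterior}.
#' @param correctLocalization subtract the static localization variance.
#' @param sigma localization error (um) used by the correction.
#' @param pruneFloor minimum expected step count for a state to be
#'   reported (default 1).
#' @return an \linkS4class{HMMSummary}.
#' @export
summarizeModel <- function(post, correctLocalization = FALSE, sigma = 0.05,
                           pruneFloor = 1) {
  keep <- which(post@stepCounts >= pruneFloor)
  if (length(keep) == 0) keep <- which.max(post@stepCounts)
  a <- post@gammaShape[keep]; b <- post@gammaRate[keep]
  v <- ifelse(a > 1, b / (a - 1), b / a)  # posterior-mean step variance
  if (correctLocalization) v <- pmax(v - 2 * sigma^2, 1e-9)
  D <- v / (2 * post@dt)
  Ahat <- post@transCounts[keep, keep, drop = FALSE]
  Ahat <- Ahat / rowSums(Ahat)
  occ <- post@stepCounts[keep] / sum(post@stepCounts[keep])
  dwell <- post@dt / pmax(1 - diag(Ahat), 1e-12)
  rates <- Ahat / post@dt
  diag(rates) <- 0
  new("HMMSummary", D = as.numeric(D), occupancy = as.numeric(occ),
      dwell = as.numeric(dwell), rates = rates,
      K = length(keep), dt = post@dt)
}

# subset a StepSeries by trajectory indices (with repetition)
.subsetSteps <- function(steps, idx) {
  parts <- lapply(idx, function(i) {
    s <- steps@trajStart[i]
    steps@steps[s:(s + steps@trajLength[i] - 1L), , drop = FALSE]
  })
  lens <- steps@trajLength[idx]
  new("StepSeries", steps = do.call(rbind, parts),
      trajStart = as.integer(c(1L, 1L + cumsum(lens[-length(lens)]))),
      trajLength = as.integer(lens), dt = steps@dt)
}

#' Bootstrap uncertainty of the HMM parameters
#'
#' Resamples whole trajectories (steps within a trajectory are dependent)
#' with replacement \code{nBoot} times and refits the model at fixed K.
#' States are matched across replicates by ascending D (the fitting
#' routine's reporting convention).
#'
#' @param steps a \linkS4class{StepSeries} with at least 2 trajectories.
#' @param K model size.
#' @param nBoot number of bootstrap replicates (default 100).
#' @param seed master seed.
#' @param nRestarts VBEM restarts per replicate (default 5; replicate
#'   fits are easier than the exploratory fit).
#' @param resampleIndices optional list of index vectors overriding the
#'   random resampling (one vector per replicate), e.g. the identity for
#'   verification.
#' @param ... passed to \code{\link{vbFit}}.
#' @return a list with matrices \code{D}, \code{occupancy}, \code{dwell}
#'   (replicates x states) and a \code{quantiles} summary.
#' @export
bootstrapUncertainty <- function(steps, K, nBoot = 100, seed = 1,
                                 nRestarts = 5, resampleIndices = NULL, ...) {
  nT <- length(steps@trajStart)
  if (nT < 2) stop("bootstrap needs at least 2 trajectories")
  D <- occ <- dw <- matrix(NA_real_, nBoot, K)
  for (bIdx in seq_len(nBoot)) {
    if (is.null(resampleIndices)) {
      set.seed(.derivedSeed(seed, K, 100000L + bIdx))
      idx <- sample.int(nT, nT, replace = TRUE)
    } else idx <- resampleIndices[[bIdx]]
    bs <- .subsetSteps(steps, idx)
    fit <- vbFit(bs, K, nRestarts = nRestarts,
                 seed = .derivedSeed(seed, K, 200000L + bIdx), ...)
    sm <- summarizeModel(fit, pruneFloor = 0)
    D[bIdx, ] <- sm@D
    occ[bIdx, ] <- sm@occupancy
    dw[bIdx, ] <- sm@dwell
  }
  qs <- function(m) apply(m, 2, stats::quantile,
                          probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  list(D = D, occupancy = occ, dwell = dw,
       quantiles = list(D = qs(D), occupancy = qs(occ), dwell = qs(dw)))
}

#' Viterbi decoding of diffusive states
#'
#' Most probable state path per trajectory under the posterior-mean
#' parameters. Labels follow the ascending-D convention of the fit.
#'
#' @param post a \linkS4class{VBPosterior}.
#' @param x a \linkS4class{StepSeries} or \linkS4class{TrajectorySet}.
#' @return a list of integer state-label vectors, one per trajectory
#'   (one label per displacement step).
#' @export
decodeStates <- function(post, x) {
  steps <- if (is(x, "TrajectorySet")) extractSteps(x) else x
  sq <- steps@steps[, 1]^2 + steps@steps[, 2]^2
  lam <- post@gammaShape / post@gammaRate
  A <- transitionMatrix(post)
  piHat <- post@initCounts / sum(post@initCounts)
  path <- viterbi_cpp(sq, steps@trajStart - 1L, steps@trajLength,
                      lam, log(lam), log(A), log(piHat)) + 1L
  out <- vector("list", length(steps@trajStart))
  for (i in seq_along(out)) {
    s <- steps@trajStart[i]
    out[[i]] <- path[s:(s + steps@trajLength[i] - 1L)]
  }
  out
}
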