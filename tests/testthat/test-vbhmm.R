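# Variational-Bayes HMM: step extraction, fitting, model selection,
# bootstrap, summaries and decoding.

acq30 <- AcquisitionParams()

test_that("step extraction preserves displacements and boundaries", {
  df <- data.frame(track_id = c("a", "a", "a", "b", "b"),
                   frame = c(0:2, 0:1),
                   x_um = c(0, 1, 1, 5, 5), y_um = c(0, 0, 1, 5, 6))
  st <- extractSteps(TrajectorySet(df, acq30))
  expect_equal(unname(st@steps), rbind(c(1, 0), c(0, 1), c(0, 1)))
  expect_identical(st@trajLength, c(2L, 1L))
  expect_identical(st@trajStart, c(1L, 3L))

  bad <- data.frame(track_id = "a", frame = c(0, 2, 3),
                    x_um = 1:3, y_um = 1:3)
  expect_error(TrajectorySet(bad, acq30) |> extractSteps(), "frame")
})

test_that("total step count matches the generated set arithmetic", {
  p <- discPreset("dark")
  s <- simulateTrajectories(p$model, p$geometry, acq30, nTraj = 400, seed = 30)
  st <- extractSteps(s)
  expect_equal(nrow(st@steps), sum(trackLengths(s)) - 400)
  # mean length ~35 -> total steps near 400 * 34
  expect_lt(abs(nrow(st@steps) - 400 * 34) / (400 * 34), 0.1)
})

test_that("K = 1 posterior mean matches the moment estimator", {
  m <- DiffusiveStateModel(D = 0.5, transitionMatrix = matrix(1, 1, 1),
                           initialDistribution = 1)
  s <- simulateTrajectories(m, DiscGeometry("unbounded"), acq30, nTraj = 100,
                            lengths = rep(101, 100), seed = 31)
  st <- extractSteps(s)
  fit <- vbFit(st, 1, nRestarts = 3, seed = 1)
  moment <- mean(rowSums(st@steps^2)) / (4 / 30)
  expect_lt(abs(diffusionCoefficients(fit) - moment) / moment, 0.01)
})

test_that("two well-separated states are recovered within 10%", {
  ts <- twoStateSteps(nTraj = 100, len = 101, D = c(0.01, 1),
                      dwellFrames = 20, seed = 32)
  fit <- vbFit(ts$steps, 2, nRestarts = 10, seed = 2)
  D <- diffusionCoefficients(fit)
  expect_lt(abs(D[1] - 0.01) / 0.01, 0.10)
  expect_lt(abs(D[2] - 1) / 1, 0.10)
  expect_lt(max(abs(occupancies(fit) - 0.5)), 0.1)
})

test_that("the evidence lower bound is non-decreasing within a restart", {
  ts <- twoStateSteps(nTraj = 30, len = 51, seed = 33)
  for (K in 1:3) {
    fit <- vbFit(ts$steps, K, nRestarts = 2, seed = 3)
    tr <- fit@elboTrace
    expect_gt(length(tr), 1)
    expect_true(all(diff(tr) >= -1e-9 * pmax(1, abs(tr[-1]))))
  }
})

test_that("model selection is parsimonious on single-state data", {
  m <- DiffusiveStateModel(D = 0.3, transitionMatrix = matrix(1, 1, 1),
                           initialDistribution = 1)
  for (sd in 1:3) {
    s <- simulateTrajectories(m, DiscGeometry("unbounded"), acq30,
                              nTraj = 100, lengths = rep(101, 100),
                              seed = 33 + sd)
    # over-specified K on one-state data may stop at the iteration cap
    # while shrinking the spurious states; that warning is expected
    sel <- suppressWarnings(
      selectModel(extractSteps(s), kMax = 3, nRestarts = 5, seed = sd))
    expect_identical(chosenK(sel), 1L)
  }
  # 10 steps cannot justify extra states
  s2 <- simulateTrajectories(m, DiscGeometry("unbounded"), acq30, nTraj = 1,
                             lengths = 11, seed = 37)
  sel2 <- selectModel(extractSteps(s2), kMax = 2, nRestarts = 5, seed = 1)
  expect_identical(chosenK(sel2), 1L)
})

test_that("summaries report the derived quantities and conventions", {
  ts <- twoStateSteps(nTraj = 60, len = 81, seed = 38)
  fit <- vbFit(ts$steps, 2, nRestarts = 5, seed = 4)
  sm <- summarizeModel(fit)
  # ascending-D convention and normalized occupancy
  expect_true(all(diff(sm@D) > 0))
  expect_equal(sum(sm@occupancy), 1, tolerance = 1e-12)
  # dwell formula: A_kk = 2/3 at 30 fps -> 0.1 s
  Ahat <- transitionMatrix(fit)
  expect_equal(sm@dwell, (1 / 30) / (1 - diag(Ahat)), tolerance = 1e-9)
  # expected step counts account for every step
  expect_equal(sum(fit@stepCounts), nrow(ts$steps@steps), tolerance = 1e-6)
})

test_that("bootstrap respects identity resampling and ordering", {
  ts <- twoStateSteps(nTraj = 25, len = 41, seed = 39)
  full <- vbFit(ts$steps, 2, nRestarts = 5, seed = 5)
  ident <- bootstrapUncertainty(ts$steps, 2, nBoot = 1, seed = 5,
                                nRestarts = 5,
                                resampleIndices = list(1:25))
  expect_equal(as.numeric(ident$D), summarizeModel(full, pruneFloor = 0)@D,
               tolerance = 1e-6)
  bs <- bootstrapUncertainty(ts$steps, 2, nBoot = 6, seed = 6, nRestarts = 3)
  expect_true(all(bs$D[, 1] <= bs$D[, 2]))
  # a single trajectory cannot be resampled
  one <- new("StepSeries", steps = ts$steps@steps[1:40, ],
             trajStart = 1L, trajLength = 40L, dt = 1 / 30)
  expect_error(bootstrapUncertainty(one, 2), "at least 2")
})

test_that("bootstrap spread shrinks with the number of trajectories", {
  m <- DiffusiveStateModel(D = 0.3, transitionMatrix = matrix(1, 1, 1),
                           initialDistribution = 1)
  spread <- sapply(c(100, 400), function(n) {
    s <- simulateTrajectories(m, DiscGeometry("unbounded"), acq30,
                              nTraj = n, lengths = rep(21, n), seed = 40 + n)
    bs <- bootstrapUncertainty(extractSteps(s), 1, nBoot = 30, seed = 7,
                               nRestarts = 2)
    sd(bs$D[, 1])
  })
  # roughly 1/sqrt(n): a factor-2 drop expected, allow slack
  expect_lt(spread[2], spread[1] / 1.3)
})

test_that("Viterbi decoding recovers well-separated state paths", {
  ts <- twoStateSteps(nTraj = 40, len = 101, D = c(0.01, 1),
                      dwellFrames = 25, seed = 41)
  fit <- vbFit(ts$steps, 2, nRestarts = 5, seed = 8)
  paths <- decodeStates(fit, ts$steps)
  truth <- as.data.frame(ts$set)$state
  truth <- truth[!is.na(truth)]
  acc <- mean(unlist(paths) == truth)
  expect_gte(acc, 0.9)

  # K = 1: all labels identical
  one <- vbFit(ts$steps, 1, nRestarts = 2, seed = 9)
  expect_length(unique(unlist(decodeStates(one, ts$steps))), 1L)

  # an immobile stretch inside a fast trajectory decodes as one slow run
  set.seed(42)
  slowSeg <- 41:70
  dx <- rnorm(100, 0, sqrt(2 * 1 / 30)); dy <- rnorm(100, 0, sqrt(2 * 1 / 30))
  dx[slowSeg] <- rnorm(30, 0, sqrt(2 * 0.01 / 30))
  dy[slowSeg] <- rnorm(30, 0, sqrt(2 * 0.01 / 30))
  df <- data.frame(track_id = "z", frame = 0:100,
                   x_um = c(0, cumsum(dx)), y_um = c(0, cumsum(dy)))
  stz <- extractSteps(TrajectorySet(df, acq30))
  pz <- decodeStates(fit, stz)[[1]]
  runs <- rle(pz)
  slowRuns <- which(runs$values == 1 & runs$lengths >= 10)
  expect_length(slowRuns, 1L)
})

test_that("localization noise biases D by sigma^2/dt and the correction removes it", {
  D <- 0.2; sig <- 0.05
  m <- DiffusiveStateModel(D = D, transitionMatrix = matrix(1, 1, 1),
                           initialDistribution = 1)
  s <- simulateTrajectories(m, DiscGeometry("unbounded"), acq30, nTraj = 200,
                            lengths = rep(51, 200), seed = 43)
  noisy <- applyLocalizationNoise(s, sig, seed = 44)
  fit <- vbFit(extractSteps(noisy), 1, nRestarts = 2, seed = 10)
  bias <- sig^2 / (1 / 30)  # 0.075 um^2/s
  raw <- summarizeModel(fit)@D
  expect_lt(abs(raw - (D + bias)) / (D + bias), 0.05)
  corr <- summarizeModel(fit, correctLocalization = TRUE, sigma = sig)@D
  expect_lt(abs(corr - D), 0.2 * bias)  # >= 80% of the bias removed
})

test_that("parameter recovery holds at the experimental data scale", {
  # noise-free dark-preset runs: median errors over seeds stay within
  # 20% (D), 0.05 absolute (occupancy) and 25% (dwell)
  p <- discPreset("dark")
  errs <- sapply(1:5, function(i) {
    s <- simulateTrajectories(p$model, p$geometry, acq30, nTraj = 400,
                              seed = 44 + i)
    fit <- vbFit(extractSteps(s), 3, nRestarts = 5, seed = 10 + i)
    sm <- summarizeModel(fit)
    c(D = max(abs(sm@D - p$model@D) / p$model@D),
      occ = max(abs(sm@occupancy - c(0.2, 0.5, 0.3))),
      dwell = max(abs(sm@dwell - 0.1) / 0.1))
  })
  med <- apply(errs, 1, median)
  expect_lt(med["D"], 0.2)
  expect_lt(med["occ"], 0.05)
  expect_lt(med["dwell"], 0.25)
})
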