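# Trajectory and movie generators: closed-form oracles and invariants.

acq30 <- AcquisitionParams()

test_that("degenerate models behave as closed forms predict", {
  # (near-)zero diffusion: the particle never leaves its start point
  m0 <- DiffusiveStateModel(D = 1e-15, transitionMatrix = matrix(1, 1, 1),
                            initialDistribution = 1)
  s <- simulateTrajectories(m0, DiscGeometry("disc"), acq30, nTraj = 5,
                            lengths = rep(20, 5), seed = 1)
  tr <- as.data.frame(s)
  for (id in unique(tr$track_id)) {
    sub <- tr[tr$track_id == id, ]
    expect_lt(max(abs(sub$x_um - sub$x_um[1])), 1e-5)
    expect_lt(max(abs(sub$y_um - sub$y_um[1])), 1e-5)
  }

  # identity transition matrix: rejected as reducible by the validity check
  expect_error(
    DiffusiveStateModel(D = c(0.05, 0.5),
                        transitionMatrix = matrix(c(1, 0, 0, 1), 2, 2),
                        initialDistribution = c(0.5, 0.5)),
    "irreducible")
  # bypass validity via direct simulation of a nearly-absorbing chain
  eps <- 1e-12
  mA <- DiffusiveStateModel(D = c(0.05, 0.5),
                            transitionMatrix = matrix(c(1 - eps, eps, eps, 1 - eps), 2, 2),
                            initialDistribution = c(0.5, 0.5))
  s2 <- simulateTrajectories(mA, DiscGeometry("unbounded"), acq30, nTraj = 10,
                             lengths = rep(50, 10), seed = 2)
  tr2 <- as.data.frame(s2)
  for (id in unique(tr2$track_id)) {
    st <- tr2$state[tr2$track_id == id]
    st <- st[!is.na(st)]
    expect_length(unique(st), 1L)
  }
})

test_that("unbounded single-state steps match the 4 D dt law", {
  m <- DiffusiveStateModel(D = 0.5, transitionMatrix = matrix(1, 1, 1),
                           initialDistribution = 1)
  s <- simulateTrajectories(m, DiscGeometry("unbounded"), acq30, nTraj = 1,
                            lengths = 100001, seed = 3)
  steps <- extractSteps(s)
  msq <- mean(rowSums(steps@steps^2))
  expect_lt(abs(msq - 4 * 0.5 / 30) / (4 * 0.5 / 30), 0.01)
})

test_that("localization noise has the stated variance and MSD offset", {
  m <- DiffusiveStateModel(D = 1e-15, transitionMatrix = matrix(1, 1, 1),
                           initialDistribution = 1)
  s <- simulateTrajectories(m, DiscGeometry("unbounded"), acq30, nTraj = 1,
                            lengths = 100000, seed = 4)
  expect_identical(applyLocalizationNoise(s, 0)@tracks$x_um, s@tracks$x_um)
  expect_error(applyLocalizationNoise(s, -1), "sigma")

  noisy <- applyLocalizationNoise(s, 0.05, seed = 5)
  dx <- noisy@tracks$x_um - noisy@tracks$true_x_um
  dy <- noisy@tracks$y_um - noisy@tracks$true_y_um
  expect_lt(abs(var(dx) - 0.0025) / 0.0025, 0.02)
  expect_lt(abs(var(dy) - 0.0025) / 0.0025, 0.02)

  # MSD of an immobile noisy particle sits at the static offset 4 sigma^2
  cur <- computeMSD(noisy@tracks[1:50000, ], maxLag = 5, acq = acq30)
  expect_lt(max(abs(cur@msd - 4 * 0.05^2)) / (4 * 0.05^2), 0.05)
})

test_that("ensemble MSD follows 4 D n dt + 4 sigma^2 on unbounded motion", {
  D <- 0.3; sig <- 0.05
  m <- DiffusiveStateModel(D = D, transitionMatrix = matrix(1, 1, 1),
                           initialDistribution = 1)
  s <- simulateTrajectories(m, DiscGeometry("unbounded"), acq30, nTraj = 1,
                            lengths = 10001, seed = 6)
  noisy <- applyLocalizationNoise(s, sig, seed = 7)
  cur <- computeMSD(noisy@tracks, maxLag = 5, acq = acq30)
  expected <- 4 * D * (1:5) / 30 + 4 * sig^2
  expect_lt(max(abs(cur@msd - expected) / expected), 0.06)
})

test_that("bounded motion saturates below the disc bound", {
  m <- DiffusiveStateModel(D = 2, transitionMatrix = matrix(1, 1, 1),
                           initialDistribution = 1)
  g <- DiscGeometry("disc", diameter = 1)
  s <- simulateTrajectories(m, g, acq30, nTraj = 1, lengths = 5000, seed = 8)
  cur <- computeMSD(s@tracks, maxLag = 2000, acq = acq30)
  Rd <- 0.5
  expect_lt(max(cur@msd), 2 * Rd^2)
  # plateau: the last decade of lags grows much slower than the first lag
  expect_lt(cur@msd[2000] - cur@msd[1000], cur@msd[100])
  # all positions remain in the disc
  expect_true(all(s@tracks$x_um^2 + s@tracks$y_um^2 <= Rd^2 + 1e-9))
})

test_that("state occupancy converges to the stationary distribution", {
  p <- discPreset("dark")
  s <- simulateTrajectories(p$model, DiscGeometry("unbounded"), acq30,
                            nTraj = 1, lengths = 100001, seed = 9)
  st <- s@tracks$state
  st <- st[!is.na(st)]
  occ <- as.numeric(table(factor(st, levels = 1:3)) / length(st))
  expect_lt(max(abs(occ - c(0.2, 0.5, 0.3))), 0.02)
})

test_that("track-length sampling has the stated mean and support", {
  len <- sampleTrackLengths(10000, meanLength = 35, minLength = 16, seed = 10)
  expect_true(all(len >= 16))
  expect_lt(abs(mean(len) - 35), 1)
  degen <- sampleTrackLengths(1000, meanLength = 17, minLength = 16, seed = 11)
  expect_true(all(degen >= 16))
  expect_lt(mean(degen), 19)
  expect_error(sampleTrackLengths(10, meanLength = 16, minLength = 16),
               "exceed")
})

test_that("presets encode the published dark-state structure", {
  expect_error(discPreset("nope"), "available")
  expect_identical(discPreset("single_state")$model@nStates, 1L)
  p <- discPreset("dark")
  expect_identical(p$model@nStates, 3L)
  expect_lt(max(abs(stationaryDistribution(p$model) - c(0.2, 0.5, 0.3))), 1e-9)
  # state-1 dwell time: dt / (1 - A_11) = 0.100 s
  expect_equal(dwellTimesModel(p$model)[1], 0.1, tolerance = 1e-12)
  # SD-derived diffusion coefficients seed the states
  expect_equal(p$model@D[1], sdDiffusion(90e-9), tolerance = 1e-12)
  expect_equal(p$model@D[2], sdDiffusion(2e-9), tolerance = 1e-12)
  expect_equal(p$model@D[3], 3 * sdDiffusion(2e-9), tolerance = 1e-12)
  expect_equal(p$kinetics@meanLifetime, 0.1)
  # light (no GTP) raises slow-state occupancy via a longer dwell
  pl <- discPreset("light_noGTP")
  expect_gt(dwellTimesModel(pl$model)[1], dwellTimesModel(p$model)[1])
  expect_gt(stationaryDistribution(pl$model)[1],
            stationaryDistribution(p$model)[1])
})

test_that("simulation is reproducible and seed-sensitive", {
  p <- discPreset("dark")
  a <- simulateTrajectories(p$model, p$geometry, acq30, nTraj = 20, seed = 12)
  b <- simulateTrajectories(p$model, p$geometry, acq30, nTraj = 20, seed = 12)
  c <- simulateTrajectories(p$model, p$geometry, acq30, nTraj = 20, seed = 13)
  expect_identical(a@tracks, b@tracks)
  expect_false(identical(a@tracks$x_um, c@tracks$x_um))
})

test_that("cluster movies honour their kinetic parameters", {
  p <- discPreset("dark")
  # empty scene: no clusters, no monomers -> pure noise, empty truth
  kin0 <- ClusterKinetics(nucleationRate = 0, monomerCount = 0,
                          clusterDiffusion = 0.08)
  mv0 <- simulateClusterMovie(kin0, p$geometry, acq30, nFrames = 10, seed = 14)
  expect_identical(nrow(mv0$truth@tracks), 0L)
  expect_lt(sd(mv0$movie@data),
            2 * kin0@cameraGaussianSd + 1)

  # lifetimes are exponential with the configured mean; coarse pixels keep
  # rendering cheap while the kinetics are unaffected
  acqCoarse <- AcquisitionParams(pixelSize = 0.5)
  mv <- simulateClusterMovie(p$kinetics, p$geometry, acqCoarse,
                             nFrames = 9600, seed = 15)
  expect_gte(mv$nBirths, 500)
  expect_lt(abs(mean(mv$lifetimes) - 0.1) / 0.1, 0.05)

  # nucleation counts are Poisson with rate * T
  lam <- p$kinetics@nucleationRate * 9600 / 30
  expect_lt(abs(mv$nBirths - lam), 4 * sqrt(lam))
})
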