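# Spot detection, linking, lifetime fitting, kymographs and profiles.

acq30 <- AcquisitionParams()
px <- acq30@pixelSize

test_that("LoG detection finds rendered spots and nothing in blank frames", {
  # blank, noise-free frame: no detections
  blank <- matrix(100, 64, 64)
  expect_identical(nrow(detectSpots(blank, px, 0.15, 5)), 0L)
  expect_error(detectSpots(matrix(numeric(0), 0, 0), px), "empty")

  # one bright Gaussian spot on weak noise: one detection within 0.5 px
  set.seed(50)
  img <- renderTestSpot(64, 64, 30.3, 40.7, amp = 2000, sigmaPx = 0.15 / px,
                        background = 100) + rnorm(64 * 64, 0, 3)
  sp <- detectSpots(img, px, 0.15, 10)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$x_um / px + 0.5 - 30.3), 0.5)
  expect_lt(abs(sp$y_um / px + 0.5 - 40.7), 0.5)

  # two spots 10 px apart: two detections
  img2 <- renderTestSpot(64, 64, 25, 25, 2000, 0.15 / px, 100) +
    renderTestSpot(64, 64, 35, 25, 2000, 0.15 / px, 0) + rnorm(64 * 64, 0, 3)
  expect_identical(nrow(detectSpots(img2, px, 0.15, 10)), 2L)
})

test_that("linking builds gap-aware tracks without splits or merges", {
  mkSpot <- function(x, y) data.frame(x_um = x, y_um = y, intensity = 1)
  # one stationary spot over 10 frames -> one track of duration 10
  spots <- rep(list(mkSpot(2, 2)), 10)
  tr <- linkSpots(spots, maxDisplacement = 0.5)
  expect_length(unique(tr@tracks$cluster_id), 1L)
  expect_identical(nrow(tr@tracks), 10L)

  # two spots always far apart: two tracks, never swapped
  spots2 <- rep(list(rbind(mkSpot(1, 1), mkSpot(4, 4))), 8)
  tr2 <- linkSpots(spots2, maxDisplacement = 0.5)
  tab <- tr2@tracks
  expect_length(unique(tab$cluster_id), 2L)
  for (id in unique(tab$cluster_id)) {
    sub <- tab[tab$cluster_id == id, ]
    expect_lt(max(sub$x_um) - min(sub$x_um), 1e-9)  # never jumps tracks
    expect_identical(nrow(sub), 8L)
  }

  # absence longer than maxGap splits the record into two tracks
  spots3 <- c(rep(list(mkSpot(2, 2)), 4), rep(list(mkSpot(0, 0)[0, ]), 2),
              rep(list(mkSpot(2, 2)), 4))
  tr3 <- linkSpots(spots3, maxDisplacement = 0.5, maxGap = 1)
  expect_length(unique(tr3@tracks$cluster_id), 2L)
  # ... but a gap within maxGap is bridged
  tr4 <- linkSpots(spots3, maxDisplacement = 0.5, maxGap = 2)
  expect_length(unique(tr4@tracks$cluster_id), 1L)
})

test_that("lifetime MLE matches the frame-grid exponential model", {
  dt <- 1 / 30
  mkTracks <- function(durFrames, nFrames = 10000, firstFrame = 100) {
    rows <- do.call(rbind, lapply(seq_along(durFrames), function(i) {
      f0 <- firstFrame + i * 50
      data.frame(cluster_id = sprintf("c%04d", i),
                 frame = f0:(f0 + durFrames[i] - 1),
                 x_um = 1, y_um = 1, intensity = 1)
    }))
    new("ClusterTrackSet", tracks = rows, frameInterval = dt,
        nFrames = as.integer(nFrames))
  }
  # degenerate input: every duration 3 frames above the 2-frame floor;
  # the discrete MLE gives -dt / log(3/4)
  fit <- fitLifetime(mkTracks(rep(5L, 20)))
  expect_equal(fit@tauStar, -dt / log(3 / 4), tolerance = 1e-12)

  # frame-quantized exponential lifetimes, tau = 0.1 s, recovered within 10%
  set.seed(51)
  life <- rexp(500, 1 / 0.1)
  u <- runif(500, 0, dt)
  d <- floor((life + u) / dt)
  d <- d[d >= 2]
  fit2 <- fitLifetime(mkTracks(as.integer(d)))
  expect_lt(abs(fit2@tauStar - 0.1) / 0.1, 0.10)

  # too few tracks errors
  expect_error(fitLifetime(mkTracks(rep(5L, 3))), "at least")
})

test_that("the censored policy can only raise the lifetime estimate", {
  dt <- 1 / 30
  set.seed(52)
  nF <- 60L
  life <- pmax(2L, as.integer(rexp(300, 1 / 0.1) / dt))
  birth <- sample(0:(nF - 3), 300, replace = TRUE)
  death <- pmin(birth + life - 1L, nF - 1L)
  rows <- do.call(rbind, lapply(1:300, function(i)
    data.frame(cluster_id = sprintf("c%04d", i), frame = birth[i]:death[i],
               x_um = 1, y_um = 1, intensity = 1)))
  trk <- new("ClusterTrackSet", tracks = rows, frameInterval = dt,
             nFrames = nF)
  tDiscard <- fitLifetime(trk, "discard")@tauStar
  tCens <- fitLifetime(trk, "censored")@tauStar
  expect_gte(tCens, tDiscard)
})

test_that("kymographs reflect temporal structure", {
  dims <- c(40, 40, 6)
  base <- array(7, dims)
  mv <- new("MovieStack", data = base, pixelSize = px, frameInterval = 1 / 30)
  ky <- kymograph(mv, p0 = c(0.5, 1.5), p1 = c(2.5, 1.5))
  # temporally constant movie: identical columns at the background level
  expect_true(all(apply(ky, 1, function(r) max(r) - min(r)) == 0))
  expect_true(all(abs(ky - 7) < 1e-9))

  # a moving spot draws a tilted streak: the per-frame peak advances
  arr <- array(0, c(40, 40, 6))
  for (f in 1:6)
    arr[, , f] <- renderTestSpot(40, 40, x = 5 + 5 * f, y = 20, amp = 1000,
                                 sigmaPx = 2)
  mv2 <- new("MovieStack", data = arr, pixelSize = px, frameInterval = 1 / 30)
  ky2 <- kymograph(mv2, p0 = c(0.1, 20 * px - px / 2),
                   p1 = c(39.9 * px, 20 * px - px / 2))
  peaks <- apply(ky2, 2, which.max)
  expect_true(all(diff(peaks) > 0))
  expect_error(kymograph(mv, c(-5, 0), c(1, 1)), "inside")
})

test_that("radial profiles classify centre-confined vs annular patterns", {
  H <- W <- 101
  xs <- (seq_len(W) - 0.5) * px
  ctr <- c(W, H) / 2 * px
  r <- sqrt(outer(rep(1, H), (xs - ctr[1])^2) + outer((xs - ctr[2])^2, rep(1, W)))
  R <- 3.5
  unif <- matrix(100, H, W); unif[r > R] <- 0
  pr <- radialProfile(unif, discRadius = R, pixelSize = px, centre = ctr)
  expect_equal(pr$confinementIndex, 1, tolerance = 0.05)
  expect_length(pr$intensity, 20)

  centred <- exp(-r^2 / (2 * 1.2^2)) * 100
  prc <- radialProfile(centred, discRadius = R, pixelSize = px, centre = ctr)
  expect_gt(prc$confinementIndex, 1.5)
  # the binned profile decreases towards the rim
  expect_gt(prc$intensity[1], prc$intensity[20])

  annulus <- matrix(10, H, W); annulus[r > 0.8 * R & r < R] <- 200
  pra <- radialProfile(annulus, discRadius = R, pixelSize = px, centre = ctr)
  expect_lt(pra$confinementIndex, 1)
  expect_error(radialProfile(unif, R, px, centre = c(-1, 0)), "outside")
})

test_that("centre-biased cluster placement raises the confinement index", {
  p <- discPreset("dark")
  # noise- and offset-free movies so the index reflects placement alone
  # (shot noise averages out; a clipped read-noise floor would not);
  # a placement scale far beyond the disc radius is effectively uniform
  idx <- sapply(c(1.5, 50), function(scale) {
    kin <- ClusterKinetics(nucleationRate = 40, meanLifetime = 0.1,
                           clusterDiffusion = 0.08,
                           radialPlacementScale = scale, brightness = 400,
                           monomerCount = 0, cameraGaussianSd = 0,
                           cameraOffset = 0)
    mv <- simulateClusterMovie(kin, p$geometry, acq30, nFrames = 120,
                               seed = 53)
    avg <- apply(mv$movie@data, c(1, 2), mean)
    ctr <- dim(avg) / 2 * px
    radialProfile(avg, discRadius = 4, pixelSize = px,
                  centre = ctr)$confinementIndex
  })
  # scale 1.5 um concentrates clusters centrally; scale >> R is uniform
  expect_gt(idx[1], idx[2])
  expect_gt(idx[1], 1.5)
})

test_that("transverse profiles match the underlying image", {
  flat <- matrix(5, 30, 30)
  prof <- transverseProfile(flat, c(0.2, 1), c(2, 1), pixelSize = px)
  expect_true(all(abs(prof$intensity - 5) < 1e-9))
  stepimg <- cbind(matrix(1, 30, 15), matrix(9, 30, 15))
  sp <- transverseProfile(stepimg, c(0.1, 15 * px), c(29 * px, 15 * px),
                          pixelSize = px, n = 100)
  expect_lt(max(sp$intensity[sp$position_um < 0.9]), 1.5)
  expect_gt(min(sp$intensity[sp$position_um > 1.4]), 8.5)
})

test_that("cluster MSD recovers the simulated diffusion coefficient", {
  dt <- 1 / 30
  # stationary tracks: D ~ 0
  rows <- do.call(rbind, lapply(1:6, function(i)
    data.frame(cluster_id = sprintf("s%d", i), frame = 0:9,
               x_um = i, y_um = i, intensity = 1)))
  still <- new("ClusterTrackSet", tracks = rows, frameInterval = dt,
               nFrames = 2000L)
  expect_lt(abs(clusterMSD(still, acq30)$medianD), 1e-9)

  # Brownian cluster tracks at D = 0.08, N = 18 tracks
  set.seed(54)
  D <- 0.08
  rows2 <- do.call(rbind, lapply(1:18, function(i) {
    n <- 30
    data.frame(cluster_id = sprintf("b%02d", i), frame = 0:(n - 1),
               x_um = cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))),
               y_um = cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))),
               intensity = 1)
  }))
  mob <- new("ClusterTrackSet", tracks = rows2, frameInterval = dt,
             nFrames = 2000L)
  est <- clusterMSD(mob, acq30)
  expect_identical(est$n, 18L)
  expect_lt(abs(est$medianD - D) / D, 0.15)

  # the pooled median shrugs off one outlier track
  rows3 <- rbind(rows2, data.frame(cluster_id = "out", frame = 0:29,
                                   x_um = (0:29) * 1.0, y_um = 0,
                                   intensity = 1))
  mob3 <- new("ClusterTrackSet", tracks = rows3, frameInterval = dt,
              nFrames = 2000L)
  expect_lt(abs(clusterMSD(mob3, acq30)$medianD - est$medianD) / est$medianD,
            0.2)
})
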