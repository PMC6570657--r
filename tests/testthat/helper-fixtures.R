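# Shared, lazily computed fixtures. The dark-condition run mirrors the
# experimental data scale (~400 trajectories, mean 35 frames, minimum 16,
# 50-nm localization noise, 8-um disc at 30 fps) and is reused by several
# tests; it is computed once per test session.

.fixtureCache <- new.env(parent = emptyenv())

darkFixture <- function() {
  if (!exists("dark", envir = .fixtureCache)) {
    p <- discPreset("dark")
    sim <- simulateTrajectories(p$model, p$geometry, p$acquisition,
                                nTraj = 400, seed = 101)
    noisy <- applyLocalizationNoise(sim, 0.05, seed = 102)
    filt <- filterTrajectories(noisy)
    steps <- extractSteps(filt$set)
    sel <- selectModel(steps, kMax = 5, nRestarts = 25, seed = 7)
    fits <- msdFitTable(filt$set)
    assign("dark", list(preset = p, sim = sim, noisy = noisy, filt = filt,
                        steps = steps, sel = sel, msdFits = fits),
           envir = .fixtureCache)
  }
  get("dark", envir = .fixtureCache)
}

# small two-state step series with well-separated D, known ground truth
twoStateSteps <- function(nTraj = 100, len = 101, D = c(0.01, 1),
                          dwellFrames = 20, seed = 42) {
  A <- matrix(c(1 - 1 / dwellFrames, 1 / dwellFrames,
                1 / dwellFrames, 1 - 1 / dwellFrames), 2, 2, byrow = TRUE)
  m <- DiffusiveStateModel(D = D, transitionMatrix = A)
  sim <- simulateTrajectories(m, DiscGeometry("unbounded"),
                              AcquisitionParams(), nTraj = nTraj,
                              lengths = rep(len, nTraj), seed = seed)
  list(set = sim, steps = extractSteps(sim), model = m)
}

# render one Gaussian spot of given total intensity onto a flat image
renderTestSpot <- function(H, W, x, y, amp, sigmaPx, background = 0) {
  img <- matrix(background, H, W)
  gx <- dnorm(seq_len(W), x, sigmaPx)
  gy <- dnorm(seq_len(H), y, sigmaPx)
  img + amp * outer(gy / sum(gy), gx / sum(gx))
}
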