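# Generator contracts: determinism, ground-truth locking, event statistics,
# noise-free proportionality, sedation energy scaling.

test_that("white-noise simulation has the stated shape, moments and determinism", {
  rec <- simulateWhiteNoise(3, 10, 488, seed = 99)
  expect_equal(dim(lfpSamples(rec)), c(3L, 4880L))
  expect_lt(max(abs(rowMeans(lfpSamples(rec)))), 3 / sqrt(4880))
  expect_equal(apply(lfpSamples(rec), 1, sd), rep(1, 3), tolerance = 0.05)
  rec2 <- simulateWhiteNoise(3, 10, 488, seed = 99)
  expect_identical(lfpSamples(rec), lfpSamples(rec2))
  expect_error(simulateWhiteNoise(0, 10, 488), "positive")
})

test_that("identical configs and seeds give bit-identical sessions", {
  cfg <- simulationConfig(duration = 10, seed = 21)
  a <- simulateTaskSession(cfg)
  b <- simulateTaskSession(cfg)
  expect_identical(lfpSamples(a@lfp), lfpSamples(b@lfp))
  expect_identical(a@kinematics@torque, b@kinematics@torque)
  expect_identical(a@spikes, b@spikes)
  expect_identical(a@groundTruth@submovements, b@groundTruth@submovements)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(duration = -1), "duration")
  expect_error(simulationConfig(sampleRate = 5, oscillatorFreq = 3), "sampleRate")
  expect_error(simulationConfig(submovementRate = -1), "rates")
  expect_error(simulateTaskSession(simulationConfig(submovementRate = 4)),
               "cannot lock")
  expect_warning(simulateSedationSession(
    simulationConfig(duration = 30, kcomplexAmplitude = 200, seed = 1)),
    "250")
})

test_that("latent phase at submovement peaks is constant (ground-truth locking)", {
  ses <- noiseFreeSession()
  gt <- ses@groundTruth
  idx <- round(gt@submovements$time * 488) + 1L
  phases <- gt@latentPhase[idx] %% (2 * pi)
  # circular SD below 1 degree
  R <- sqrt(mean(sin(phases))^2 + mean(cos(phases))^2)
  expect_lt(sqrt(-2 * log(R)) * 180 / pi, 1)
})

test_that("noise-free areal velocity is exactly proportional to peak speed", {
  ses <- noiseFreeSession()
  gt <- ses@groundTruth
  traj <- stateTrajectory(gt@latents, 488)
  # isolated events (neighbors > 1 s away): no envelope overlap at all
  tt <- gt@submovements$time
  gap <- pmin(c(Inf, diff(tt)), c(diff(tt), Inf))
  iso <- which(gap > 1)
  expect_gt(length(iso), 10)
  mags <- vapply(tt[iso], function(t0)
    sqrt(sum(eventArealVelocityVector(traj, t0)^2)), numeric(1))
  ratio <- mags / gt@submovements$speed[iso]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)
  # and the constant of proportionality is 1/speedCoupling (up to the tilt)
  cfg <- ses@config
  planar <- vapply(tt[iso], function(t0)
    abs(eventArealVelocityVector(traj, t0)[3]), numeric(1))
  expect_equal(planar / gt@submovements$speed[iso],
               rep(1 / cfg$speedCoupling, length(iso)),
               tolerance = 0.005)
})

test_that("rotation axis tilts by the configured angle with direction", {
  ses <- noiseFreeSession()
  gt <- ses@groundTruth
  traj <- stateTrajectory(gt@latents, 488)
  cfg <- ses@config
  tilts <- vapply(seq_len(nrow(gt@submovements)), function(i) {
    v <- eventArealVelocityVector(traj, gt@submovements$time[i])
    acos(v[3] / sqrt(sum(v^2)))
  }, numeric(1))
  expect_equal(mean(tilts), cfg$directionTilt, tolerance = 0.1)
  # azimuth varies with direction: antipodal to the movement direction
  az <- vapply(seq_len(nrow(gt@submovements)), function(i) {
    v <- eventArealVelocityVector(traj, gt@submovements$time[i])
    atan2(v[2], v[1])
  }, numeric(1))
  expect_wrapped_equal(az, gt@submovements$direction + pi, 0.05)
})

test_that("uniform-phase spiking rejects the Rayleigh test at the nominal rate", {
  cfg <- simulationConfig(duration = 20, nChannelsM1 = 2, nChannelsPmv = 2,
                          nNeurons = 1, spikeKappa = 0,
                          spikeRateModulation = 0, pinkSd = 0, seed = 1)
  rejections <- withr::with_seed(7, {
    vapply(seq_len(200), function(i) {
      cfg$seed <- sample.int(1e6, 1)
      ses <- simulateTaskSession(cfg)
      sp <- ses@spikes[[1]]
      phi <- ses@groundTruth@latentPhase[round(sp * 488) + 1L]
      rayleighTest(phi)$p < 0.05
    }, logical(1))
  })
  # nominal 5% rate: binomial 99% interval for 200 draws
  expect_lt(mean(rejections), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("intersubmovement-interval histogram peaks near 300 ms", {
  ses <- taskSession()
  ev <- detectSubmovements(ses@kinematics, trialBounds = ses@trialBounds)
  iac <- intervalAutocorrelation(ev$peakTime, ses@trialBounds)
  mode <- iac$lag[which.max(iac$ratio)]
  expect_gt(mode, 0.25)
  expect_lt(mode, 0.35)
})

test_that("sedation K complexes are all recovered by the 250 uV detector", {
  sed <- sedationSession()
  kc <- detectKComplexes(sed@lfp)
  gtk <- sed@groundTruth@kcomplexes
  expect_equal(nrow(kc), length(gtk))
  d <- vapply(gtk, function(tt) min(abs(kc$peakTime - tt)), numeric(1))
  expect_lt(max(d), 0.02)
})

test_that("zero K-complex rate is rejected; kcomplexRate drives event count", {
  expect_error(simulateSedationSession(
    simulationConfig(duration = 30, kcomplexRate = 0)), "positive")
})

test_that("sedation delta amplitude exceeds task by the configured ratio", {
  task <- taskSession()
  sed <- sedationSession()
  ratio <- task@config$sedationAmplitudeRatio
  envAt <- function(ses, times) {
    ch <- lfpSamples(meanReference(lowpassDelta(ses@lfp)))[1, ]
    e <- Mod(analyticSignal(ch))
    median(e[round(times * 488) + 1L])
  }
  measured <- envAt(sed, sed@groundTruth@kcomplexes) /
    envAt(task, task@groundTruth@submovements$time)
  expect_equal(measured, ratio, tolerance = 0.2)
})

test_that("task and sedation share the channel phase pattern", {
  task <- taskSession()
  sed <- sedationSession()
  ev <- detectSubmovements(task@kinematics)
  kc <- detectKComplexes(sed@lfp)
  td <- meanReference(lowpassDelta(task@lfp))
  sd2 <- meanReference(lowpassDelta(sed@lfp))
  smPh <- apply(lfpSamples(td), 1, function(ch) as.numeric(suppressWarnings(
    eventRelativePhase(eventTriggeredAverage(ch, ev$peakTime, 488)))))
  kcPh <- apply(lfpSamples(sd2), 1, function(ch) as.numeric(suppressWarnings(
    eventRelativePhase(eventTriggeredAverage(ch, kc$peakTime, 488)))))
  cc <- circularCorrelation(smPh, kcPh)
  expect_gt(cc$rho, 0.9)
})
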