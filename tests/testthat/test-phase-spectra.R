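# Hilbert phases, circular statistics, spike-triggered analyses, Welch
# coherence and power spectra, normalized firing rates.

fs <- 488

test_that("event-relative phase follows the cosine convention", {
  # +/-0.2 s windows hold 1.2 cycles at 3 Hz; spectral leakage allows a
  # phase bias of a degree or two
  t <- seq(-0.2, 0.2, by = 1 / fs)
  expect_equal(as.numeric(eventRelativePhase(cos(2 * pi * 3 * t))), 0,
               tolerance = 0.05)
  expect_equal(as.numeric(eventRelativePhase(sin(2 * pi * 3 * t))), -pi / 2,
               tolerance = 0.05)
  expect_warning(p <- eventRelativePhase(c(rep(0, 97), 1, rep(0, 98)) * 0 +
                                           c(seq(-1, 1, length.out = 196))),
                 NA)  # a ramp has nonzero analytic amplitude: no warning
})

test_that("event-triggered averaging preserves locked and shrinks unlocked signals", {
  t <- seq(0, 60, by = 1 / fs)
  sig <- 2 * cos(2 * pi * 3 * t)
  locked <- seq(1, 59, by = 1 / 3)
  avg <- eventTriggeredAverage(sig, locked, fs)
  expect_equal(max(abs(avg$mean)), 2, tolerance = 1e-3)
  one <- eventTriggeredAverage(sig, 10, fs)
  ctr <- round(10 * fs) + 1L
  h <- round(0.2 * fs)
  expect_equal(one$mean, sig[(ctr - h):(ctr + h)])
  rnd <- withr::with_seed(8, eventTriggeredAverage(sig, runif(400, 1, 59), fs))
  expect_lt(max(abs(rnd$mean)), 2 * 3 / sqrt(400) * 3)
  expect_error(eventTriggeredAverage(sig, 0.01, fs), "full window")
})

test_that("per-channel phases recover the configured channel phase offsets", {
  ses <- noiseFreeSession()
  ev <- ses@groundTruth@submovements
  phases <- apply(lfpSamples(ses@lfp), 1, function(ch) as.numeric(
    suppressWarnings(eventRelativePhase(
      eventTriggeredAverage(ch, ev$time, fs)))))
  psi <- ses@config$channelPhases
  # channel c carries cos(phi + psi_c); around an event (locked at phase 0)
  # it is cos(omega tau + psi_c), so the event-relative phase is psi_c
  expect_wrapped_equal(phases, psi, 5 * pi / 180)
})

test_that("circular-circular correlation hits its exact extremes", {
  withr::with_seed(6, phi <- runif(12, -2, 2))
  expect_equal(circularCorrelation(phi, phi)$rho, 1, tolerance = 1e-12)
  expect_equal(circularCorrelation(phi, -phi)$rho, -1, tolerance = 1e-12)
  shifted <- circularCorrelation(phi + 0.8, phi - 1.1)
  expect_equal(shifted$rho, 1, tolerance = 1e-9)
  expect_error(circularCorrelation(phi, phi[1:5]), "equal length")
  expect_error(circularCorrelation(phi[1:3], phi[1:3]), "at least 5")
  even <- seq(0, 2 * pi - pi / 4, by = pi / 4)  # zero resultant
  expect_error(circularCorrelation(even, even), "resultant")
})

test_that("the rho_CC p value is calibrated against a permutation oracle", {
  # tail probability of |rho| >= 0.81 at n = 10 for independent uniform
  # phases, compared with the analytic p at that observed rho
  withr::with_seed(13, {
    n <- 10
    draws <- vapply(1:4000, function(i)
      circularCorrelation(runif(n, 0, 2 * pi), runif(n, 0, 2 * pi))$rho,
      numeric(1))
    tail <- mean(abs(draws) >= 0.81)
  })
  # the analytic two-sided p for rho = 0.81 at n = 10 is ~0.025 on real
  # data of this kind; the permutation tail must be of the same order
  expect_lt(tail, 0.05)
  expect_gt(tail, 0.001)
  expect_equal(mean(draws), 0, tolerance = 0.02)
})

test_that("Rayleigh test: identical phases reject, uniform phases hold the level", {
  ident <- rayleighTest(rep(1.3, 20))
  expect_equal(ident$R, 1)
  expect_lt(ident$p, 1e-8)
  rate <- withr::with_seed(17, mean(vapply(1:500, function(i)
    rayleighTest(runif(30, 0, 2 * pi))$p < 0.05, logical(1))))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 500))
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 500))
})

test_that("plane rotation zeroes the trajectory phase at peak speed", {
  # trajectory with event phase 90 degrees: rotation must be -90 degrees
  t <- seq(0, 60, by = 1 / fs)
  traj <- stateTrajectory(cbind(cos(2 * pi * 3 * t + pi / 2),
                                sin(2 * pi * 3 * t + pi / 2)), fs)
  events <- seq(1, 59, by = 1 / 3)  # t where the un-shifted phase is 0
  rot <- rotatePlaneToSpeedPhase(traj, events)
  expect_equal(rot$angle, -pi / 2, tolerance = 0.02)
  eta <- eventTriggeredAverage(rot$traj@x[, 1:2], events, fs)
  ctr <- (length(eta$time) + 1) %/% 2
  expect_equal(atan2(eta$mean[ctr, 2], eta$mean[ctr, 1]), 0, tolerance = 0.01)

  already <- rotatePlaneToSpeedPhase(rot$traj, events)
  expect_equal(already$angle, 0, tolerance = 0.01)
})

test_that("spike preferred phases recover the ground truth", {
  # near-continuous oscillation (long envelope) with isotropic channel
  # phases: spike phases then reflect only the von Mises locking, without
  # envelope weighting or orbit anisotropy
  cfg <- simulationConfig(duration = 120, spikeKappa = 2,
                          spikeRateModulation = 0, noiseSd = 2, pinkSd = 2,
                          nNeurons = 6, seed = 31, envelopeSd = 0.2,
                          channelPhases = c(seq(0, 2 * pi, length.out = 11)[1:10],
                                            seq(0, 2 * pi, length.out = 7)[1:6]))
  ses <- cachedFixture("lockedUnits", simulateTaskSession(cfg))
  rec <- meanReference(lowpassDelta(ses@lfp))
  traj <- projectRecording(rec, fitPCA(rec, 2))
  ev <- detectSubmovements(ses@kinematics)
  rot <- rotatePlaneToSpeedPhase(traj, ev$peakTime)
  for (j in seq_along(ses@spikes)) {
    pp <- preferredPhase(ses@spikes[[j]], rot$traj)
    expect_lt(abs(atan2(sin(pp$meanPhase - ses@groundTruth@preferredPhases[j]),
                        cos(pp$meanPhase - ses@groundTruth@preferredPhases[j]))),
              10 * pi / 180)
    expect_lt(pp$p, 0.01)
  }
  # population mean precedes zero phase (firing leads peak speed)
  mu <- vapply(seq_along(ses@spikes), function(j)
    preferredPhase(ses@spikes[[j]], rot$traj)$meanPhase, numeric(1))
  popMean <- atan2(mean(sin(mu)), mean(cos(mu)))
  expect_lt(popMean, 0)
  expect_gt(popMean, -pi / 2)
})

test_that("spike-triggered trajectories are rotational for locked units only", {
  ses <- cachedFixture("lockedUnits", simulateTaskSession(
    simulationConfig(duration = 120, spikeKappa = 2, spikeRateModulation = 0,
                     noiseSd = 2, pinkSd = 2, nNeurons = 6, seed = 31,
                     envelopeSd = 0.2,
                     channelPhases = c(seq(0, 2 * pi, length.out = 11)[1:10],
                                       seq(0, 2 * pi, length.out = 7)[1:6]))))
  rec <- meanReference(lowpassDelta(ses@lfp))
  traj <- projectRecording(rec, fitPCA(rec, 2))
  sta <- spikeTriggeredTrajectory(ses@spikes[[1]], traj)
  radius <- sqrt(rowSums(sta$mean^2))
  # locked unit: a substantial rotational orbit
  expect_gt(max(radius), 5 * mean(abs(diff(radius))))

  unif <- withr::with_seed(3, sort(runif(3000, 0, 120)))
  staU <- spikeTriggeredTrajectory(unif, traj)
  expect_lt(max(sqrt(rowSums(staU$mean^2))), max(radius) / 3)
  expect_error(spikeTriggeredTrajectory(numeric(), traj), "empty")
  expect_error(spikeTriggeredTrajectory(seq(1, 2, by = 0.1), traj), "50")
})

test_that("coherence is 1 for identical signals and ~1/L for independent noise", {
  withr::with_seed(23, {
    a <- rnorm(2048 * 8)
    b <- rnorm(2048 * 8)
  })
  same <- coherenceSpectrum(a, a, fs)
  expect_true(all(same$coherence > 1 - 1e-9))
  indep <- coherenceSpectrum(a, b, fs)
  L <- attr(indep, "nSegments")
  expect_equal(L, 8)
  # estimator bias: E[coh] ~ 1/L for independent signals
  expect_equal(mean(indep$coherence), 1 / L, tolerance = 0.25)
  expect_true(all(indep$coherence >= 0 & indep$coherence <= 1))
  # symmetry
  expect_equal(coherenceSpectrum(b, a, fs)$coherence, indep$coherence,
               tolerance = 1e-12)
  expect_error(coherenceSpectrum(a[1:3000], b[1:3000], fs), "2 full segments")
})

test_that("task coherence between speed and LFP-PCs peaks at the oscillator frequency", {
  ses <- taskSession()
  traj <- taskTrajectory(ses, 2)
  coh <- coherenceSpectrum(ses@kinematics@radialSpeed, stateX(traj)[, 2], fs)
  peak <- coh$freq[which.max(coh$coherence)]
  expect_equal(peak, 3, tolerance = 0.15)
})

test_that("power spectra satisfy Parseval and localize sinusoids", {
  t <- seq(0, 40, by = 1 / fs)
  ps <- powerSpectrum(sin(2 * pi * 7 * t), fs)
  expect_equal(ps$freq[which.max(ps$power)], 7, tolerance = 0.3)
  withr::with_seed(29, x <- rnorm(fs * 40, 0, 2))
  psn <- powerSpectrum(x, fs)
  df <- psn$freq[2] - psn$freq[1]
  expect_equal(sum(psn$power) * df, 4, tolerance = 0.1)
  # sedation delta power exceeds task delta power
  task <- taskSession()
  sed <- sedationSession()
  pt <- powerSpectrum(lfpSamples(task@lfp)[1, ], fs)
  psd <- powerSpectrum(lfpSamples(sed@lfp)[1, ], fs)
  delta <- pt$freq > 0.5 & pt$freq < 5
  expect_gt(sum(psd$power[delta]), 10 * sum(pt$power[delta]))
})

test_that("normalized firing rates are z-scored and flat for Poisson units", {
  withr::with_seed(37, sp <- sort(runif(600, 0, 60)))
  nfr <- normalizedFiringRate(sp, 60)
  expect_equal(mean(nfr$rate), 0, tolerance = 1e-10)
  expect_equal(sd(nfr$rate), 1, tolerance = 1e-10)
  expect_gt(nfr$rateSd, 0)
  expect_error(normalizedFiringRate(numeric(), 60), "at least 2")
  expect_error(normalizedFiringRate(5, 60), "at least 2")
})

test_that("phase estimates are equivariant under a common time shift", {
  t <- seq(0, 30, by = 1 / fs)
  sig <- cos(2 * pi * 3 * t)
  ev <- seq(2, 28, by = 1 / 3)
  p1 <- as.numeric(eventRelativePhase(eventTriggeredAverage(sig, ev, fs)))
  shift <- 0.75  # multiple of a sample, not of the cycle
  p2 <- as.numeric(eventRelativePhase(eventTriggeredAverage(sig, ev + shift, fs)))
  dphi <- 2 * pi * 3 * shift
  expect_wrapped_equal(p2, p1 + dphi, 0.02)
})
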