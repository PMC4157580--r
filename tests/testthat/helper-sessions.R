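# Shared fixtures: simulated sessions are cached per configuration so that
# multiple test files can reuse them without re-simulating.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Standard 120 s task session at default noise.
taskSession <- function(seed = 3, duration = 120) {
  key <- sprintf("task_%d_%g", seed, duration)
  cachedFixture(key, simulateTaskSession(
    simulationConfig(duration = duration, seed = seed)))
}

# Paired sedation session (same config and seed: same channel phases/gains).
sedationSession <- function(seed = 3, duration = 120) {
  key <- sprintf("sed_%d_%g", seed, duration)
  cachedFixture(key, simulateSedationSession(
    simulationConfig(duration = duration, seed = seed)))
}

# Noise-free sparse-event session: exact areal-velocity proportionality.
noiseFreeSession <- function(seed = 5) {
  key <- sprintf("clean_%d", seed)
  cachedFixture(key, simulateTaskSession(simulationConfig(
    duration = 120, submovementRate = 0.5, noiseSd = 0, pinkSd = 0,
    betaAmplitude = 0, kinematicNoiseSd = 0, seed = seed)))
}

# Delta-band preprocessing chain -> PC trajectory on the task basis.
taskTrajectory <- function(ses, nComponents = 2) {
  key <- sprintf("traj_%s_%d", substr(digest_session(ses), 1, 8), nComponents)
  cachedFixture(key, {
    rec <- meanReference(lowpassDelta(ses@lfp))
    projectRecording(rec, fitPCA(rec, nComponents))
  })
}

digest_session <- function(ses) {
  sprintf("%s_%d_%g_%d", ses@condition, nChannels(ses@lfp),
          ncol(lfpSamples(ses@lfp)), length(ses@spikes))
}

# Analytic circular trajectory at frequency f and radius r.
circleTrajectory <- function(f = 3, r = 1, duration = 5, fs = 488,
                             phase0 = 0) {
  t <- seq(0, duration, by = 1 / fs)
  stateTrajectory(r * cbind(cos(2 * pi * f * t + phase0),
                            sin(2 * pi * f * t + phase0)), fs)
}

# simple phase unwrapping (oracle for rotation-frequency checks)
unwrap <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

expect_wrapped_equal <- function(a, b, tol) {
  d <- abs(atan2(sin(a - b), cos(a - b)))
  expect_lt(max(d), tol)
}
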