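# Synthetic session generator. Emulates the statistical structure of
# motor-cortical recordings: a ~3 Hz planar rotational latent oscillation
# mixed into LFP channels with fixed per-channel phases; submovements
# emitted by a phase-locked renewal process (one candidate per oscillator
# cycle) whose peak cursor speed is locked to a fixed oscillator phase;
# areal velocity proportional to peak speed with a direction-dependent tilt
# of the rotation axis; phase-locked inhomogeneous-Poisson spiking;
# rectified-noise EMG; and a sedation mode with large K complexes flanked
# by delta bursts sharing the task channel-phase pattern.

#' Simulation configuration
#'
#' Builds a validated configuration list for [simulateTaskSession()] and
#' [simulateSedationSession()]. All arguments have defaults representing a
#' typical session; override any subset.
#'
#' @param nChannelsM1,nChannelsPmv LFP channel counts per area (10, 6).
#' @param sampleRate Hz (488).
#' @param duration seconds (300).
#' @param oscillatorFreq latent oscillation frequency, Hz (3).
#' @param channelPhases radians per channel (M1 then PMv); default evenly
#'   spaced over \[0, 1.5 pi\] within each area. (Exactly uniform coverage of
#'   the circle would make the cross-channel circular mean undefined.)
#' @param submovementRate events/s (2.5); must not exceed `oscillatorFreq`
#'   (one event per cycle at most).
#' @param speedCoupling peak speed (%/s) per unit of window-averaged areal
#'   velocity (0.007; with the default speed distribution this puts the
#'   latent orbit near 55 microvolts).
#' @param speedMedian,speedSdlog,speedMin log-normal peak-speed
#'   distribution: median %/s (60), log-SD (0.4), lower truncation (35,
#'   above the 30 %/s detection threshold).
#' @param directionTilt rotation-axis tilt, radians, per unit direction
#'   harmonic (0.26, ~15 degrees).
#' @param nDirections number of equally spaced target directions (8).
#' @param phaseLock oscillator phase (radians) at peak cursor speed (0).
#' @param envelopeSd SD of the per-event latent amplitude envelope, s
#'   (0.07).
#' @param spikeKappa von Mises concentration of firing around each unit's
#'   preferred phase (1); 0 gives uniform phases.
#' @param nNeurons units (15). @param spikeRate mean rate, Hz (10).
#' @param preferredPhaseMean,preferredPhaseSd distribution of preferred
#'   phases across units, radians (-0.5, 0.4); the default mean precedes
#'   the peak-speed phase.
#' @param spikeRateModulation fraction of the rate modulated by the latent
#'   amplitude envelope (0.5).
#' @param noiseSd white sensor-noise SD, microvolts (5).
#' @param pinkSd pink (1/f) background SD, microvolts (7).
#' @param betaAmplitude amplitude of a common single-phase beta oscillation,
#'   microvolts (3). @param betaFreq its frequency, Hz (20).
#' @param kinematicNoiseSd smoothed torque noise SD, percent (0.2).
#' @param kcomplexRate K complexes per second in sedation mode (0.12).
#' @param kcomplexAmplitude K-complex peak, microvolts (400; must exceed the
#'   250 uV detection threshold to be detectable).
#' @param kcomplexMinSpacing minimum K-complex spacing, s (3).
#' @param burstSd SD of the sedation delta-burst envelope, s (0.25; spans
#'   roughly 1-3 oscillator cycles).
#' @param sedationAmplitudeRatio sedation / task delta amplitude ratio (10).
#' @param trialLength nominal trial duration, s (5).
#' @param seed RNG seed used by the simulators.
#' @return a validated configuration list (class `"SimulationConfig"`).
#' @export
simulationConfig <- function(nChannelsM1 = 10L, nChannelsPmv = 6L,
                             sampleRate = 488, duration = 300,
                             oscillatorFreq = 3, channelPhases = NULL,
                             submovementRate = 2.5, speedCoupling = 0.007,
                             speedMedian = 60, speedSdlog = 0.4,
                             speedMin = 35, directionTilt = 0.26,
                             nDirections = 8L, phaseLock = 0,
                             envelopeSd = 0.07, spikeKappa = 1,
                             nNeurons = 15L, spikeRate = 10,
                             preferredPhaseMean = -0.5,
                             preferredPhaseSd = 0.4,
                             spikeRateModulation = 0.5,
                             noiseSd = 5, pinkSd = 7, betaAmplitude = 3,
                             betaFreq = 20, kinematicNoiseSd = 0.2,
                             kcomplexRate = 0.12, kcomplexAmplitude = 400,
                             kcomplexMinSpacing = 3, burstSd = 0.25,
                             sedationAmplitudeRatio = 10, trialLength = 5,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$sampleRate <= 2 * cfg$oscillatorFreq)
    stop("'sampleRate' must exceed twice 'oscillatorFreq'")
  if (cfg$duration <= 0) stop("'duration' must be positive")
  rates <- c(cfg$submovementRate, cfg$kcomplexRate, cfg$spikeRate)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (cfg$speedMin <= 0 || cfg$speedMedian <= 0)
    stop("speed parameters must be positive")
  nCh <- cfg$nChannelsM1 + cfg$nChannelsPmv
  if (is.null(cfg$channelPhases))
    cfg$channelPhases <- c(seq(0, 1.5 * pi, length.out = max(cfg$nChannelsM1, 2L))[seq_len(cfg$nChannelsM1)],
                           seq(0, 1.5 * pi, length.out = max(cfg$nChannelsPmv, 2L))[seq_len(cfg$nChannelsPmv)])
  if (length(cfg$channelPhases) != nCh)
    stop("'channelPhases' must have one entry per channel (", nCh, ")")
  class(cfg) <- "SimulationConfig"
  cfg
}

# Pink (1/f amplitude ~ f^-1/2 power... here power ~ 1/f) noise via FFT
# shaping, unit variance.
pinkNoise <- function(n) {
  nf <- nextn(n, 2)
  w <- rnorm(nf)
  W <- fft(w)
  f <- c(1, seq_len(nf - 1))  # avoid the DC singularity
  f <- pmin(f, nf - f + 1)    # two-sided symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE))[seq_len(n)] / nf
  (x - mean(x)) / sd(x)
}

# Per-channel mixing parameters; drawn FIRST inside the seeded block of
# every simulator so that task and sedation sessions with the same config
# and seed share identical channel gains and phases.
drawChannelParams <- function(cfg) {
  nCh <- cfg$nChannelsM1 + cfg$nChannelsPmv
  list(psi = cfg$channelPhases,
       gain = exp(rnorm(nCh, 0, 0.15)),
       tiltLoad = rnorm(nCh, 0, 0.4),
       kcGain = exp(rnorm(nCh, 0, 0.1)))
}

mixingMatrix <- function(chan) {
  cbind(chan$gain * cos(chan$psi), -chan$gain * sin(chan$psi), chan$tiltLoad)
}

# Mean of the squared event envelope G(t/sigma)^2 over the discrete
# +/-0.2 s areal-velocity window, evaluated on the sample grid so the
# generator's coupling matches the decoder's window average exactly.
windowGamma <- function(envelopeSd, fs, halfWindow = 0.2) {
  k <- (-round(halfWindow * fs)):(round(halfWindow * fs))
  mean(exp(-(k / fs)^2 / envelopeSd^2))
}

# Orbit radius producing a window-averaged planar areal velocity of
# speed / speedCoupling.
orbitRadius <- function(speed, cfg) {
  omega <- 2 * pi * cfg$oscillatorFreq
  sqrt(2 * speed / (cfg$speedCoupling * omega *
                      windowGamma(cfg$envelopeSd, cfg$sampleRate)))
}

# Add a * exp(-(t - t0)^2 / (2 sigma^2)) into x (sampled at fs), windowed to
# +/- 6 sigma for speed.
addBump <- function(x, t0, a, sigma, fs) {
  n <- length(x)
  i0 <- max(1L, floor((t0 - 6 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((t0 + 6 * sigma) * fs) + 1L)
  if (i0 > i1) return(x)
  tt <- (i0:i1 - 1L) / fs
  x[i0:i1] <- x[i0:i1] + a * exp(-(tt - t0)^2 / (2 * sigma^2))
  x
}

# Inhomogeneous-Poisson spike trains (one per unit) by per-bin thinning;
# rate(t) in Hz must be < fs everywhere for the bin approximation.
drawSpikes <- function(rateMatrixFun, nNeurons, n, fs) {
  lapply(seq_len(nNeurons), function(j) {
    r <- rateMatrixFun(j)
    hit <- which(runif(n) < r / fs)
    (hit - 1L) / fs + 0.5 / fs
  })
}

vonMisesRate <- function(phase, kappa, phiPref, meanRate) {
  if (kappa == 0) return(rep(meanRate, length(phase)))
  meanRate * exp(kappa * cos(phase - phiPref)) / besselI(kappa, 0)
}

#' Simulate an isometric-task session
#'
#' Generates a complete task session with known ground truth: LFP channels
#' mixing a 3 Hz planar rotational latent (amplitude bursts locked to
#' submovements) with pink and white noise plus a common single-phase beta
#' oscillation; 2D torque kinematics whose radial-speed peaks are the
#' submovements, each locked to the configured oscillator phase, with
#' log-normal peak speeds and directions drawn from equally spaced targets;
#' phase-locked Poisson spike trains; and rectified-noise EMG modulated by
#' the speed envelope.
#'
#' Submovements arise from a phase-locked renewal process: each oscillator
#' cycle emits at most one event (probability `submovementRate /
#' oscillatorFreq`), so intersubmovement intervals peak at multiples of the
#' cycle length (~333 ms at 3 Hz). The window-averaged planar areal
#' velocity of the noise-free latent equals `peakSpeed / speedCoupling`,
#' and the rotation axis tilts by `directionTilt` in a direction-dependent
#' azimuth via loading on a third latent dimension.
#'
#' @param config a [simulationConfig()].
#' @return A [RecordingSession-class] (condition `"task"`) with
#'   [GroundTruth-class] attached.
#' @examples
#' cfg <- simulationConfig(duration = 20, nNeurons = 3, seed = 7)
#' ses <- simulateTaskSession(cfg)
#' ses
#' @export
simulateTaskSession <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  if (cfg$submovementRate > cfg$oscillatorFreq)
    stop("'submovementRate' exceeds 'oscillatorFreq'; cannot lock one ",
         "event per cycle")
  fs <- cfg$sampleRate
  n <- round(cfg$duration * fs)
  t <- (0:(n - 1L)) / fs
  withSeed(cfg$seed, {
    chan <- drawChannelParams(cfg)

    # submovement times: one candidate per oscillator cycle, at the locked
    # phase, kept with probability rate / freq
    cycle <- 1 / cfg$oscillatorFreq
    margin <- 0.5
    cand <- seq(cfg$phaseLock / (2 * pi) * cycle, cfg$duration, by = cycle)
    cand <- cand[cand > margin & cand < cfg$duration - margin]
    keep <- runif(length(cand)) < cfg$submovementRate / cfg$oscillatorFreq
    evTimes <- cand[keep]
    nEv <- length(evTimes)
    u <- runif(nEv, plnorm(cfg$speedMin, log(cfg$speedMedian), cfg$speedSdlog), 1)
    evSpeeds <- qlnorm(u, log(cfg$speedMedian), cfg$speedSdlog)
    evDirs <- wrapToPi(sample.int(cfg$nDirections, nEv, replace = TRUE) *
                         2 * pi / cfg$nDirections)

    # latent trajectory
    phase <- 2 * pi * cfg$oscillatorFreq * t
    r <- numeric(n)
    L3 <- numeric(n)
    cTilt <- tan(cfg$directionTilt)
    for (i in seq_len(nEv)) {
      ri <- orbitRadius(evSpeeds[i], cfg)
      r <- addBump(r, evTimes[i], ri, cfg$envelopeSd, fs)
      L3 <- L3 + cTilt * addBump(numeric(n), evTimes[i], ri, cfg$envelopeSd, fs) *
        cos(phase - evDirs[i])
    }
    L1 <- r * cos(phase)
    L2 <- r * sin(phase)
    latents <- cbind(L1, L2, L3)

    # channels = mixing + beta + pink + white noise
    M <- mixingMatrix(chan)
    nCh <- nrow(M)
    betaEnv <- 1 + 0.5 * sin(2 * pi * 0.2 * t + runif(1, 0, 2 * pi))
    beta <- cfg$betaAmplitude * betaEnv * cos(2 * pi * cfg$betaFreq * t)
    lfp <- M %*% t(latents)
    for (ch in seq_len(nCh)) {
      noise <- if (cfg$pinkSd > 0) cfg$pinkSd * pinkNoise(n) else 0
      if (cfg$noiseSd > 0) noise <- noise + rnorm(n, 0, cfg$noiseSd)
      lfp[ch, ] <- lfp[ch, ] + chan$gain[ch] * beta + noise
    }
    areas <- rep(c("M1", "PMv"), c(cfg$nChannelsM1, cfg$nChannelsPmv))
    rec <- multichannelRecording(lfp, fs, areas, "surface")

    # kinematics: each submovement is an out-and-back radial pulse whose
    # positive speed peak equals the drawn peak speed at the locked time
    sigmaP <- 0.05
    torque <- matrix(0, n, 2L)
    for (i in seq_len(nEv)) {
      amp <- evSpeeds[i] * sigmaP * exp(0.5)
      pulse <- addBump(numeric(n), evTimes[i] + sigmaP, amp, sigmaP, fs)
      torque[, 1] <- torque[, 1] + pulse * cos(evDirs[i])
      torque[, 2] <- torque[, 2] + pulse * sin(evDirs[i])
    }
    if (cfg$kinematicNoiseSd > 0) {
      coefs <- butterCoefs(4, 5 / (fs / 2), "low")
      for (k in 1:2) {
        kn <- zeroPhaseFilter(rnorm(n), coefs$b, coefs$a, 3L * ceiling(fs / 5))
        torque[, k] <- torque[, k] + cfg$kinematicNoiseSd * kn / sd(kn)
      }
    }
    kin <- computeRadialSpeed(torque, fs)

    # spikes: von Mises phase locking, optionally modulated by the envelope
    phiPref <- rnorm(cfg$nNeurons, cfg$preferredPhaseMean, cfg$preferredPhaseSd)
    envNorm <- if (max(r) > 0) r / max(r) else r
    mod <- (1 - cfg$spikeRateModulation) + cfg$spikeRateModulation * envNorm
    spikes <- drawSpikes(function(j)
      vonMisesRate(phase, cfg$spikeKappa, phiPref[j], cfg$spikeRate) * mod,
      cfg$nNeurons, n, fs)

    # EMG: rectified white noise modulated by the speed envelope
    spdEnv <- numeric(n)
    for (i in seq_len(nEv)) spdEnv <- addBump(spdEnv, evTimes[i], evSpeeds[i], sigmaP, fs)
    emg <- sapply(1:4, function(k)
      abs(rnorm(n)) * (1 + 2 * spdEnv / max(max(spdEnv), 1)))

    nTrials <- max(1L, floor(cfg$duration / cfg$trialLength))
    trials <- cbind(start = (0:(nTrials - 1L)) * cfg$trialLength,
                    end = (1:nTrials) * cfg$trialLength)

    gt <- new("GroundTruth", latentPhase = phase, latentAmplitude = r,
              submovements = data.frame(time = evTimes, speed = evSpeeds,
                                        direction = evDirs),
              kcomplexes = numeric(), preferredPhases = phiPref,
              mixingMatrix = M, latents = latents)
    new("RecordingSession", lfp = rec, kinematics = kin, emg = emg,
        spikes = spikes, condition = "task", trialBounds = trials,
        config = unclass(cfg), groundTruth = gt)
  })
}

#' Simulate a ketamine-sedation session
#'
#' Generates a sedation-like session: large positive K complexes
#' (difference-of-Gaussians transients peaking at `kcomplexAmplitude`) at
#' snapped-to-cycle Poisson times with refractory spacing, each flanked by a
#' 1-3-cycle burst of the same latent oscillator with the SAME per-channel
#' phase pattern as the task generator (given the same config and seed), at
#' `sedationAmplitudeRatio` times the task delta amplitude; spiking is
#' concentrated on the K-complex rising phase and peak.
#'
#' @param config a [simulationConfig()] with `kcomplexRate > 0`. A
#'   `kcomplexAmplitude` at or below 250 microvolts is flagged with a
#'   warning (events would be undetectable by the standard threshold).
#' @return A [RecordingSession-class] (condition `"sedation"`, no
#'   kinematics).
#' @export
simulateSedationSession <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  if (cfg$kcomplexRate <= 0) stop("'kcomplexRate' must be positive")
  if (cfg$kcomplexAmplitude <= 250)
    warning("'kcomplexAmplitude' <= 250 uV: events will not be detectable ",
            "by the standard 250 uV threshold")
  fs <- cfg$sampleRate
  n <- round(cfg$duration * fs)
  t <- (0:(n - 1L)) / fs
  withSeed(cfg$seed, {
    chan <- drawChannelParams(cfg)

    cycle <- 1 / cfg$oscillatorFreq
    margin <- 1.5
    # Poisson candidates, snapped to the nearest locked-phase cycle time,
    # thinned to the refractory spacing
    nCand <- rpois(1, cfg$kcomplexRate * cfg$duration)
    cand <- sort(runif(nCand, margin, cfg$duration - margin))
    snapped <- round((cand - cfg$phaseLock / (2 * pi) * cycle) / cycle) * cycle +
      cfg$phaseLock / (2 * pi) * cycle
    kcTimes <- numeric()
    for (tk in snapped)
      if (!length(kcTimes) || tk - tail(kcTimes, 1) >= cfg$kcomplexMinSpacing)
        kcTimes <- c(kcTimes, tk)

    phase <- 2 * pi * cfg$oscillatorFreq * t
    rSed <- cfg$sedationAmplitudeRatio * orbitRadius(cfg$speedMedian, cfg)
    r <- numeric(n)
    for (tk in kcTimes) r <- addBump(r, tk, rSed, cfg$burstSd, fs)
    latents <- cbind(r * cos(phase), r * sin(phase), 0)

    # K-complex waveform: positive difference-of-Gaussians transient
    kcWave <- numeric(n)
    for (tk in kcTimes) {
      kcWave <- addBump(kcWave, tk, cfg$kcomplexAmplitude / 0.5, 0.12, fs)
      kcWave <- addBump(kcWave, tk, -cfg$kcomplexAmplitude, 0.35, fs)
    }

    M <- mixingMatrix(chan)
    nCh <- nrow(M)
    lfp <- M %*% t(latents)
    for (ch in seq_len(nCh)) {
      noise <- if (cfg$pinkSd > 0) cfg$pinkSd * pinkNoise(n) else 0
      if (cfg$noiseSd > 0) noise <- noise + rnorm(n, 0, cfg$noiseSd)
      lfp[ch, ] <- lfp[ch, ] + chan$kcGain[ch] * kcWave + noise
    }
    areas <- rep(c("M1", "PMv"), c(cfg$nChannelsM1, cfg$nChannelsPmv))
    rec <- multichannelRecording(lfp, fs, areas, "surface")

    # spiking: quiet before each K complex, strong on the rising phase/peak
    phiPref <- rnorm(cfg$nNeurons, cfg$preferredPhaseMean, cfg$preferredPhaseSd)
    envNorm <- if (max(r) > 0) r / max(r) else r
    spikes <- drawSpikes(function(j)
      0.5 + 4 * cfg$spikeRate * envNorm *
        vonMisesRate(phase, max(cfg$spikeKappa, 1), phiPref[j], 1),
      cfg$nNeurons, n, fs)

    gt <- new("GroundTruth", latentPhase = phase, latentAmplitude = r,
              submovements = data.frame(time = numeric(), speed = numeric(),
                                        direction = numeric()),
              kcomplexes = kcTimes, preferredPhases = phiPref,
              mixingMatrix = M, latents = latents)
    new("RecordingSession", lfp = rec, kinematics = NULL,
        emg = matrix(0, 0, 0), spikes = spikes, condition = "sedation",
        trialBounds = cbind(start = 0, end = cfg$duration),
        config = unclass(cfg), groundTruth = gt)
  })
}

#' Simulate white-noise recordings
#'
#' Independent unit-variance Gaussian samples per channel; reproducible from
#' the seed.
#'
#' @param nChannels channel count.
#' @param duration seconds.
#' @param sampleRate Hz.
#' @param seed RNG seed (NULL draws from the current stream).
#' @return A [MultichannelRecording-class] (all channels labeled `"M1"`).
#' @export
simulateWhiteNoise <- function(nChannels, duration, sampleRate, seed = NULL) {
  if (nChannels <= 0 || duration <= 0 || sampleRate <= 0)
    stop("all arguments must be positive")
  n <- round(duration * sampleRate)
  samples <- withSeed(seed, matrix(rnorm(nChannels * n), nChannels, n))
  multichannelRecording(samples, sampleRate, "M1", "surface")
}
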