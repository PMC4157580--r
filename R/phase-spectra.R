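# Event-relative LFP phases (Hilbert), circular statistics, spike-triggered
# trajectory averages, Welch coherence / power spectra, normalized firing
# rates.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real numeric vector.
#' @return complex vector; `Arg()` of it is the instantaneous phase with the
#'   convention that a cosine has phase 0 at its peak.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Event-triggered average of a signal
#'
#' Pointwise mean of the signal over windows of +/- `halfWindow` around each
#' event time; events with clipped windows are skipped and counted.
#'
#' @param x numeric vector (one channel) or a
#'   [MultichannelRecording-class] (averaged per channel).
#' @param eventTimes event times, s.
#' @param sampleRate Hz (taken from the recording when `x` is one).
#' @param halfWindow half window, s (default 0.2).
#' @return list with `time` (window axis), `mean` (vector, or window x
#'   channels matrix), `nEvents`, `nSkipped`. Errors when no event has a
#'   full window.
#' @export
eventTriggeredAverage <- function(x, eventTimes, sampleRate = NULL,
                                  halfWindow = 0.2) {
  if (is(x, "MultichannelRecording")) {
    sampleRate <- x@sampleRate
    x <- t(x@samples)
  }
  x <- as.matrix(x)
  if (is.null(sampleRate)) stop("'sampleRate' is required for plain signals")
  h <- round(halfWindow * sampleRate)
  centers <- round(eventTimes * sampleRate) + 1L
  ok <- centers - h >= 1L & centers + h <= nrow(x)
  if (!any(ok)) stop("no events with full windows")
  acc <- matrix(0, 2L * h + 1L, ncol(x))
  for (ctr in centers[ok]) acc <- acc + x[(ctr - h):(ctr + h), , drop = FALSE]
  m <- acc / sum(ok)
  list(time = ((-h):h) / sampleRate,
       mean = if (ncol(m) == 1L) as.numeric(m) else m,
       nEvents = sum(ok), nSkipped = sum(!ok))
}

#' Event-relative phase of an averaged LFP window
#'
#' The phase of the event-triggered average at the event time (window
#' center), from the angle of its analytic signal. Convention: a
#' cosine-like oscillation peaking at the event has phase 0; a sine (peak a
#' quarter cycle after the event) has phase -pi/2.
#'
#' @param avg an event-triggered average as returned by
#'   [eventTriggeredAverage()] (vector `mean`), or a plain numeric window
#'   centered on the event.
#' @param minAmplitude fraction of the maximum analytic amplitude below
#'   which the center phase is flagged unreliable (default 0.05).
#' @return phase in radians in `[-pi, pi)`, with attributes `amplitude` and
#'   `reliable`.
#' @export
eventRelativePhase <- function(avg, minAmplitude = 0.05) {
  w <- if (is.list(avg)) avg$mean else avg
  if (!is.numeric(w)) stop("'avg' must be a numeric window")
  a <- analyticSignal(w - mean(w))
  ctr <- (length(w) + 1L) %/% 2L
  amp <- Mod(a[ctr])
  phi <- wrapToPi(Arg(a[ctr]))
  attr(phi, "amplitude") <- amp
  attr(phi, "reliable") <- amp >= minAmplitude * max(Mod(a))
  if (!attr(phi, "reliable"))
    warning("near-zero analytic amplitude at the event time; phase unreliable")
  phi
}

circularMean <- function(phi) {
  s <- mean(sin(phi)); c <- mean(cos(phi))
  if (sqrt(s^2 + c^2) < 1e-12)
    stop("zero resultant; circular mean undefined")
  atan2(s, c)
}

#' Circular-circular correlation coefficient
#'
#' The Jammalamadaka-SenGupta coefficient
#' rho = sum sin(a - abar) sin(b - bbar) /
#' sqrt(sum sin^2(a - abar) * sum sin^2(b - bbar)), with abar, bbar the
#' circular means, and the standard asymptotic normal p value.
#'
#' @param phiA,phiB equal-length vectors of angles, radians (n >= 5).
#' @return list with `rho` and `p`.
#' @export
circularCorrelation <- function(phiA, phiB) {
  n <- length(phiA)
  if (length(phiB) != n) stop("'phiA' and 'phiB' must have equal length")
  if (n < 5L) stop("need at least 5 phase pairs")
  sa <- sin(phiA - circularMean(phiA))
  sb <- sin(phiB - circularMean(phiB))
  denom <- sqrt(sum(sa^2) * sum(sb^2))
  if (denom < 1e-12) stop("degenerate phase spread; correlation undefined")
  rho <- sum(sa * sb) / denom
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  z <- if (l22 > 0) sqrt(n * l20 * l02 / l22) * rho else 0
  list(rho = rho, p = 2 * (1 - stats::pnorm(abs(z))))
}

#' Rayleigh test of circular uniformity
#'
#' Computes the mean resultant length R of the phase sample and the
#' standard approximation to the Rayleigh p value: with Rn = n * R,
#' p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n)).
#'
#' @param phi angles, radians.
#' @return list with `meanPhase`, `R` (mean resultant length), `n`, `p`.
#' @export
rayleighTest <- function(phi) {
  n <- length(phi)
  if (n < 1L) stop("empty phase sample")
  R <- sqrt(mean(sin(phi))^2 + mean(cos(phi))^2)
  Rn <- n * R
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(meanPhase = atan2(mean(sin(phi)), mean(cos(phi))), R = R, n = n,
       p = min(p, 1))
}

#' Spike-triggered average LFP-PC trajectory
#'
#' Averages the trajectory over +/- `halfWindow` around each spike and
#' normalizes by the standard deviation of the unit's smoothed firing rate
#' (see [normalizedFiringRate()]).
#'
#' @param spikeTimes spike times, s (>= 50 with full windows required).
#' @param traj a [StateTrajectory-class].
#' @param halfWindow half window, s (default 0.2).
#' @param rateSd standard deviation of the unit's smoothed firing rate; if
#'   NULL it is computed from the spike train over the trajectory duration.
#' @return list as [eventTriggeredAverage()] plus `rateSd`.
#' @export
spikeTriggeredTrajectory <- function(spikeTimes, traj, halfWindow = 0.2,
                                     rateSd = NULL) {
  stopifnot(is(traj, "StateTrajectory"))
  if (length(spikeTimes) < 1L) stop("empty spike train")
  if (is.null(rateSd)) {
    nfr <- normalizedFiringRate(spikeTimes,
                                duration = nrow(traj@x) / traj@sampleRate,
                                sampleRate = traj@sampleRate)
    rateSd <- nfr$rateSd
  }
  eta <- eventTriggeredAverage(traj@x, spikeTimes, traj@sampleRate, halfWindow)
  if (eta$nEvents < 50L)
    stop("fewer than 50 spikes with full windows (", eta$nEvents, ")")
  eta$mean <- eta$mean / rateSd
  eta$rateSd <- rateSd
  eta
}

#' Rotate the PC plane to zero phase at peak speed
#'
#' Rigidly rotates the PC1-PC2 plane so that the submovement-triggered
#' average trajectory has polar angle zero at the moment of peak cursor
#' speed. All phases measured in the rotated frame are then relative to
#' peak speed.
#'
#' @param traj a [StateTrajectory-class] (first two components rotated;
#'   a third component, if present, is left unchanged).
#' @param eventTimes submovement peak-speed times, s.
#' @param halfWindow half window for the triggered average, s (default 0.2).
#' @return list with `traj` (rotated [StateTrajectory-class]) and `angle`
#'   (the rotation applied, radians; the average trajectory's phase at the
#'   event was `-angle`). Errors if the average radius at the event time is
#'   near zero.
#' @export
rotatePlaneToSpeedPhase <- function(traj, eventTimes, halfWindow = 0.2) {
  stopifnot(is(traj, "StateTrajectory"))
  eta <- eventTriggeredAverage(traj@x[, 1:2], eventTimes, traj@sampleRate,
                               halfWindow)
  ctr <- (length(eta$time) + 1L) %/% 2L
  c0 <- eta$mean[ctr, ]
  scale <- max(sqrt(rowSums(eta$mean^2)))
  if (sqrt(sum(c0^2)) < 1e-6 * max(scale, 1e-300))
    stop("average trajectory radius at the event time is near zero")
  alpha <- atan2(c0[2], c0[1])
  R <- matrix(c(cos(-alpha), sin(-alpha), -sin(-alpha), cos(-alpha)), 2L, 2L)
  x <- traj@x
  x[, 1:2] <- traj@x[, 1:2] %*% t(R)
  list(traj = stateTrajectory(x, traj@sampleRate, band = traj@band),
       angle = -alpha)
}

#' Preferred firing phase of a unit and Rayleigh test
#'
#' Assigns each spike the instantaneous phase of the (rotated) PC pair at
#' the spike time — by default the polar angle atan2(x2, x1); alternatively
#' the Hilbert phase of PC1 — and returns the circular mean, mean resultant
#' length and Rayleigh p. Samples where the orbit radius (or analytic
#' amplitude) is below `tol` times its maximum are masked; if more than half
#' the spikes fall on masked samples, an error is raised.
#'
#' @param spikeTimes spike times, s (>= 10 usable required).
#' @param traj a [StateTrajectory-class], normally rotated via
#'   [rotatePlaneToSpeedPhase()].
#' @param method `"polar"` (default) or `"hilbert"`.
#' @param tol relative amplitude mask threshold (default 0.05).
#' @return list with `meanPhase`, `R`, `n`, `p` (as [rayleighTest()]) plus
#'   `nMasked`.
#' @export
preferredPhase <- function(spikeTimes, traj, method = c("polar", "hilbert"),
                           tol = 0.05) {
  stopifnot(is(traj, "StateTrajectory"))
  method <- match.arg(method)
  if (method == "polar") {
    phase <- atan2(traj@x[, 2], traj@x[, 1])
    amp <- sqrt(rowSums(traj@x[, 1:2]^2))
  } else {
    a <- analyticSignal(traj@x[, 1] - mean(traj@x[, 1]))
    phase <- Arg(a)
    amp <- Mod(a)
  }
  masked <- amp < tol * max(amp)
  idx <- round(spikeTimes * traj@sampleRate) + 1L
  idx <- idx[idx >= 1L & idx <= length(phase)]
  if (!length(idx)) stop("no spikes inside the trajectory")
  ok <- !masked[idx]
  if (mean(ok) < 0.5)
    stop("more than half of the spikes fall on masked (low-amplitude) samples")
  phi <- phase[idx[ok]]
  if (length(phi) < 10L) stop("fewer than 10 usable spikes")
  out <- rayleighTest(phi)
  out$nMasked <- sum(!ok)
  out
}

# Segment a pair of signals into non-overlapping rectangular windows and
# accumulate auto/cross periodograms.
welchSpectra <- function(a, b, sampleRate, segLength) {
  n <- length(a)
  L <- n %/% segLength
  if (L < 2L) stop("fewer than 2 full segments (", L, "); need longer data")
  nf <- segLength %/% 2 + 1L
  Saa <- Sbb <- numeric(nf)
  Sab <- complex(nf)
  for (k in seq_len(L)) {
    idx <- ((k - 1L) * segLength + 1L):(k * segLength)
    A <- fft(a[idx] - mean(a[idx]))[1:nf]
    B <- fft(b[idx] - mean(b[idx]))[1:nf]
    Saa <- Saa + Mod(A)^2
    Sbb <- Sbb + Mod(B)^2
    Sab <- Sab + A * Conj(B)
  }
  list(freq = (0:(nf - 1L)) * sampleRate / segLength,
       Saa = Saa, Sbb = Sbb, Sab = Sab, L = L, segLength = segLength)
}

#' Magnitude-squared coherence spectrum
#'
#' Welch-style estimator with rectangular windows of `segLength` samples
#' and no overlap (frequency resolution `sampleRate / segLength`, about
#' 0.238 Hz at 488 samples/s with the default 2048-point window). Values
#' lie in \[0, 1\]. The attribute `confidenceFloor` gives the level
#' 1 - 0.05^(1/(L-1)) below which coherence from L independent segments is
#' not distinguishable from zero at p = 0.05.
#'
#' @param a,b numeric signals of equal length (>= 2 segments).
#' @param sampleRate Hz.
#' @param segLength window length, samples (default 2048).
#' @return data.frame with `freq` (Hz) and `coherence`, with attributes
#'   `nSegments` and `confidenceFloor`.
#' @export
coherenceSpectrum <- function(a, b, sampleRate, segLength = 2048L) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  w <- welchSpectra(a, b, sampleRate, segLength)
  coh <- Mod(w$Sab)^2 / (w$Saa * w$Sbb)
  coh[!is.finite(coh)] <- 0
  out <- data.frame(freq = w$freq, coherence = pmin(coh, 1))
  attr(out, "nSegments") <- w$L
  attr(out, "confidenceFloor") <- 1 - 0.05^(1 / (w$L - 1))
  out
}

#' Welch power spectrum
#'
#' One-sided power spectral density with the same segmentation as
#' [coherenceSpectrum()] (rectangular `segLength`-point windows, no
#' overlap). Units are (signal units)^2 per Hz; the spectrum integrates to
#' the signal variance.
#'
#' @param x numeric signal.
#' @param sampleRate Hz.
#' @param segLength window length, samples (default 2048).
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
powerSpectrum <- function(x, sampleRate, segLength = 2048L) {
  w <- welchSpectra(x, x, sampleRate, segLength)
  p <- w$Saa / (w$L * sampleRate * segLength)
  one <- rep(2, length(p))
  one[1L] <- 1
  if (segLength %% 2 == 0) one[length(one)] <- 1
  data.frame(freq = w$freq, power = p * one)
}

#' Normalized firing-rate profile of a unit
#'
#' Bins spikes at the LFP sample rate (488 bins/s by default), low-pass
#' filters the counts at 5 Hz (four-pole, zero-phase) and normalizes to
#' zero mean and unit standard deviation over the entire recording. The
#' pre-normalization standard deviation (`rateSd`, in spikes/sample) is
#' returned for use by [spikeTriggeredTrajectory()].
#'
#' @param spikeTimes spike times, s (>= 2 spikes required).
#' @param duration recording duration, s.
#' @param sampleRate bin rate, Hz (default 488).
#' @return list with `rate` (normalized series), `rateSd`, `sampleRate`.
#' @export
normalizedFiringRate <- function(spikeTimes, duration, sampleRate = 488) {
  if (length(spikeTimes) < 2L)
    stop("need at least 2 spikes for a rate profile")
  n <- ceiling(duration * sampleRate)
  counts <- tabulate(pmin(floor(spikeTimes * sampleRate) + 1L, n), nbins = n)
  coefs <- butterCoefs(4, 5 / (sampleRate / 2), "low")
  sm <- zeroPhaseFilter(as.numeric(counts), coefs$b, coefs$a,
                        padLength = 10L * ceiling(sampleRate / 5))
  s <- sd(sm)
  if (s < 1e-300) stop("zero-variance firing rate")
  list(rate = (sm - mean(sm)) / s, rateSd = s, sampleRate = sampleRate)
}
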