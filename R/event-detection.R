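# Submovement and K-complex detection, and interval rhythmicity statistics.

# Indices of strict local maxima of v exceeding `threshold`, thinned so no
# two kept peaks are closer than `minSep` samples (larger peak wins).
localPeaks <- function(v, threshold, minSepSamples) {
  n <- length(v)
  if (n < 3L) return(integer())
  core <- 2:(n - 1L)
  isPeak <- v[core] > v[core - 1L] & v[core] >= v[core + 1L] & v[core] > threshold
  idx <- core[isPeak]
  if (!length(idx)) return(integer())
  keep <- logical(length(idx))
  taken <- integer()
  for (k in order(v[idx], idx, decreasing = c(TRUE, FALSE), method = "radix")) {
    if (!length(taken) || all(abs(idx[k] - taken) >= minSepSamples)) {
      keep[k] <- TRUE
      taken <- c(taken, idx[k])
    }
  }
  sort(idx[keep])
}

#' Radial cursor kinematics from a 2D torque trace
#'
#' Radial position is the Euclidean norm of the 2D torque vector per sample;
#' radial speed is its central-difference time derivative (signed: positive
#' for movement away from the center).
#'
#' @param torque time x 2 matrix, percent of screen (100% = 0.67 Nm).
#' @param sampleRate Hz.
#' @return A [KinematicsTrace-class].
#' @examples
#' tq <- cbind(seq(0, 1, length.out = 489), 0)
#' kin <- computeRadialSpeed(tq, 488)   # 1 unit/s outward
#' @export
computeRadialSpeed <- function(torque, sampleRate) {
  torque <- as.matrix(torque)
  if (ncol(torque) != 2L) stop("'torque' must have 2 columns")
  if (any(!is.finite(torque))) stop("non-finite torque values")
  r <- sqrt(rowSums(torque^2))
  new("KinematicsTrace", torque = torque, radialPosition = r,
      radialSpeed = as.numeric(centralDiff(r, sampleRate)),
      sampleRate = sampleRate)
}

#' Detect submovements from radial cursor speed
#'
#' A submovement is a local maximum of radial speed strictly exceeding the
#' threshold (default 30 %/s), with a minimum peak separation (default
#' 100 ms; the larger peak is kept). Direction is the angle of the
#' instantaneous torque-velocity vector at the peak.
#'
#' @param kin a [KinematicsTrace-class].
#' @param threshold peak-speed threshold, %/s.
#' @param refractory minimum separation between kept peaks, s.
#' @param trialBounds optional n x 2 matrix of trial start/end times; events
#'   get a `trial` column (NA outside all trials).
#' @return data.frame with columns `peakTime` (s), `peakSpeed` (%/s),
#'   `direction` (radians in `[-pi, pi)`), and optionally `trial`.
#' @export
detectSubmovements <- function(kin, threshold = 30, refractory = 0.1,
                               trialBounds = NULL) {
  stopifnot(is(kin, "KinematicsTrace"))
  fs <- kin@sampleRate
  idx <- localPeaks(kin@radialSpeed, threshold, round(refractory * fs))
  if (!length(idx))
    return(data.frame(peakTime = numeric(), peakSpeed = numeric(),
                      direction = numeric()))
  tvel <- centralDiff(kin@torque, fs)
  ev <- data.frame(peakTime = (idx - 1L) / fs,
                   peakSpeed = kin@radialSpeed[idx],
                   direction = wrapToPi(atan2(tvel[idx, 2], tvel[idx, 1])))
  if (!is.null(trialBounds)) {
    ev$trial <- NA_integer_
    for (i in seq_len(nrow(trialBounds))) {
      inTrial <- ev$peakTime >= trialBounds[i, 1] & ev$peakTime <= trialBounds[i, 2]
      ev$trial[inTrial] <- i
    }
  }
  ev
}

#' Detect K complexes from a surface-referenced LFP channel
#'
#' K complexes are the peaks of positive deflections exceeding the threshold
#' (default 250 microvolts) on one designated surface-referenced channel,
#' with 1 s minimum separation (larger peak kept).
#'
#' @param rec a surface-referenced [MultichannelRecording-class].
#' @param channel index of the designated channel (default 1).
#' @param threshold microvolts (default 250).
#' @param refractory minimum separation, s (default 1).
#' @return data.frame with columns `peakTime` (s) and `peakAmplitude` (uV).
#' @export
detectKComplexes <- function(rec, channel = 1L, threshold = 250, refractory = 1) {
  stopifnot(is(rec, "MultichannelRecording"))
  v <- rec@samples[channel, ]
  fs <- rec@sampleRate
  idx <- localPeaks(v, threshold, round(refractory * fs))
  data.frame(peakTime = (idx - 1L) / fs, peakAmplitude = v[idx])
}

#' Poisson-normalized interval autocorrelation histogram
#'
#' Histogram of all pairwise within-trial event intervals, normalized
#' bin-wise by the expectation for the same numbers of independently,
#' uniformly placed events in the same trial windows. For a trial of
#' duration D with n events, the pairwise-interval density is triangular,
#' f(tau) = 2 (D - tau) / D^2, and the expected bin count is
#' n (n - 1) / 2 times its integral over the bin, summed over trials. A
#' rhythmic process shows peaks at multiples of its cycle; a Poisson process
#' is flat at 1.
#'
#' @param eventTimes numeric vector of event times (s).
#' @param trialBounds n x 2 matrix of trial start/end times (s).
#' @param binWidth histogram bin width, s (default 0.025).
#' @param maxLag largest interval considered, s (default 1).
#' @return data.frame with columns `lag` (bin centers), `observed`,
#'   `expected`, and `ratio` (observed / expected; NaN where the expectation
#'   is 0).
#' @export
intervalAutocorrelation <- function(eventTimes, trialBounds, binWidth = 0.025,
                                    maxLag = 1) {
  trialBounds <- as.matrix(trialBounds)
  breaks <- seq(0, maxLag, by = binWidth)
  nb <- length(breaks) - 1L
  obs <- numeric(nb)
  expd <- numeric(nb)
  nPairs <- 0
  for (i in seq_len(nrow(trialBounds))) {
    tt <- eventTimes[eventTimes >= trialBounds[i, 1] & eventTimes <= trialBounds[i, 2]]
    n <- length(tt)
    if (n < 2L) next
    d <- abs(outer(tt, tt, "-"))
    d <- d[upper.tri(d)]
    nPairs <- nPairs + length(d)
    h <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE,
                               left.open = TRUE), nbins = nb)
    # d == 0 falls outside bin 1 with left-open intervals; count it in bin 1
    h[1L] <- h[1L] + sum(d == 0)
    obs <- obs + h
    D <- trialBounds[i, 2] - trialBounds[i, 1]
    Ftau <- function(tau) {
      tau <- pmin(tau, D)
      (2 * D * tau - tau^2) / D^2
    }
    expd <- expd + (n * (n - 1) / 2) * (Ftau(breaks[-1L]) - Ftau(breaks[-length(breaks)]))
  }
  if (nPairs == 0L) stop("no within-trial event pairs")
  data.frame(lag = breaks[-length(breaks)] + binWidth / 2,
             observed = obs, expected = expd, ratio = obs / expd)
}
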