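# Trace-zero first-order linear dynamical model of 2D LFP-PC trajectories:
# xdot = A x with A = [[a, b], [c, -a]], three free parameters fit by least
# squares; vector coefficient of determination; cross-condition
# generalization; white-noise null calibration.

#' Fit the trace-zero linear dynamical model
#'
#' Least-squares regression of the trajectory derivative on the trajectory,
#' xdot(t) = A x(t), constrained to A = \[\[a, b\], \[c, -a\]\] (trace zero;
#' off-diagonals free). Solved in closed form from the normal equations in
#' (a, b, c).
#'
#' @param traj a 2-component [StateTrajectory-class] with >= 100 samples.
#' @param sourceCondition condition label stored with the model.
#' @return A [DynamicsModel-class] with `codFit` set via [dynamicsCoD()].
#' @examples
#' t <- seq(0, 5, by = 1/488)
#' traj <- stateTrajectory(cbind(cos(2*pi*3*t), sin(2*pi*3*t)), 488)
#' m <- fitDynamics(traj)
#' modelFrequency(m)   # ~3 Hz
#' @export
fitDynamics <- function(traj, sourceCondition = "task") {
  stopifnot(is(traj, "StateTrajectory"))
  if (ncol(traj@x) != 2L) stop("a 2-component trajectory is required")
  if (nrow(traj@x) < 100L) stop("need at least 100 samples")
  x1 <- traj@x[, 1]; x2 <- traj@x[, 2]
  d1 <- traj@xdot[, 1]; d2 <- traj@xdot[, 2]
  s11 <- sum(x1 * x1); s22 <- sum(x2 * x2); s12 <- sum(x1 * x2)
  if (s11 + s22 < 1e-20 * length(x1)) stop("degenerate trajectory (zero variance)")
  # residuals: (d1 - a x1 - b x2), (d2 - c x1 + a x2); normal equations in (a,b,c)
  M <- rbind(c(s11 + s22, s12, -s12),
             c(s12,       s22,  0),
             c(-s12,      0,    s11))
  rhs <- c(sum(x1 * d1) - sum(x2 * d2), sum(x2 * d1), sum(x1 * d2))
  abc <- tryCatch(solve(M, rhs), error = function(e)
    stop("degenerate trajectory: ", conditionMessage(e)))
  A <- matrix(c(abc[1], abc[3], abc[2], -abc[1]), 2L, 2L)
  m <- new("DynamicsModel", A = A, band = traj@band,
           sourceCondition = sourceCondition, codFit = NA_real_)
  m@codFit <- dynamicsCoD(m, traj)
  m
}

#' Vector coefficient of determination of a dynamics model
#'
#' CoD = 1 - int |A x(t) - xdot(t)|^2 dt / int |xdot(t)|^2 dt, the integrals
#' taken as Riemann sums over all samples of the recording. May be negative
#' when the model predicts worse than the zero derivative; A = 0 gives
#' exactly 0.
#'
#' @param model a [DynamicsModel-class].
#' @param traj a 2-component [StateTrajectory-class].
#' @return unitless CoD (<= 1).
#' @export
dynamicsCoD <- function(model, traj) {
  stopifnot(is(model, "DynamicsModel"), is(traj, "StateTrajectory"))
  if (ncol(traj@x) != 2L) stop("a 2-component trajectory is required")
  pred <- traj@x %*% t(model@A)
  denom <- sum(traj@xdot^2)
  if (denom == 0) stop("zero-energy derivative; CoD undefined")
  1 - sum((pred - traj@xdot)^2) / denom
}

#' Cross-condition generalization CoD
#'
#' Applies a model fit on one condition to a trajectory from another
#' condition (projected onto the same task-derived PC basis) without
#' refitting. The band tags of model and trajectory must agree.
#'
#' @param model a [DynamicsModel-class] fit on the source condition.
#' @param traj a [StateTrajectory-class] from the target condition.
#' @return the generalization CoD.
#' @export
generalizeDynamics <- function(model, traj) {
  if (!identical(model@band, traj@band))
    stop("band mismatch: model is '", model@band, "', trajectory is '",
         traj@band, "'")
  dynamicsCoD(model, traj)
}

#' Oscillation frequency of a dynamics model
#'
#' With trace(A) = 0 the eigenvalues are +/- sqrt(-det(A)). When det(A) > 0
#' they are imaginary, +/- i omega with omega = sqrt(det(A)), and the model
#' describes elliptical rotation at omega / (2 pi) Hz; the sign follows the
#' rotation sense (positive anticlockwise). When det(A) <= 0 the model is
#' non-oscillatory and NA is returned.
#'
#' @param model a [DynamicsModel-class].
#' @return signed frequency in Hz, or NA.
#' @export
modelFrequency <- function(model) {
  d <- det(model@A)
  if (d <= 0) return(NA_real_)
  sqrt(d) / (2 * pi) * sign(model@A[2, 1] - model@A[1, 2])
}

#' White-noise null distribution of the dynamics CoD
#'
#' Calibrates the chance level of the model fit: for each replicate,
#' independent Gaussian white-noise channels are passed through the full
#' preprocessing chain (5 Hz zero-phase low-pass, within-area mean
#' referencing, 2-component PCA, projection) and the trace-zero model is
#' fit; the resulting CoD distribution and its 95th percentile are
#' returned.
#'
#' @param nChannels channels per replicate (default 10).
#' @param duration replicate length, s (default 600).
#' @param sampleRate Hz (default 488).
#' @param nReps replicates (default 200; at least 2 so a percentile exists).
#' @param seed RNG seed.
#' @return list with `cod` (length `nReps`) and `p95`.
#' @export
whiteNoiseNull <- function(nChannels = 10L, duration = 600, sampleRate = 488,
                           nReps = 200L, seed = NULL) {
  if (nReps < 2L) stop("'nReps' must be at least 2 to report a percentile")
  withSeed(seed, {
    cod <- vapply(seq_len(nReps), function(i) {
      rec <- simulateWhiteNoise(nChannels, duration, sampleRate,
                                seed = NULL)
      rec <- meanReference(lowpassDelta(rec))
      traj <- projectRecording(rec, fitPCA(rec, 2L, sourceCondition = "noise"))
      fitDynamics(traj, sourceCondition = "noise")@codFit
    }, numeric(1))
    list(cod = cod, p95 = unname(quantile(cod, 0.95, type = 7)))
  })
}

#' Oscillation frequency from the PC1-PC2 cross-correlation
#'
#' Cross-correlates the two components over lags of +/- `maxLag` and
#' determines the frequency from the interval between the cross-correlation
#' peak and trough nearest zero lag: f = 1 / (2 |lag_peak - lag_trough|).
#' Peak and trough positions are refined by parabolic interpolation.
#'
#' @param traj a 2-component [StateTrajectory-class].
#' @param maxLag lag range, s (default 1).
#' @param minAmplitude reliability floor on the absolute correlation of both
#'   extrema (default `3 / sqrt(n)`); below it the estimate errors.
#' @return frequency, Hz.
#' @export
correlationFrequency <- function(traj, maxLag = 1, minAmplitude = NULL) {
  stopifnot(is(traj, "StateTrajectory"))
  if (ncol(traj@x) != 2L) stop("a 2-component trajectory is required")
  fs <- traj@sampleRate
  n <- nrow(traj@x)
  L <- min(round(maxLag * fs), n - 2L)
  if (is.null(minAmplitude)) minAmplitude <- 3 / sqrt(n)
  a <- traj@x[, 1] - mean(traj@x[, 1])
  b <- traj@x[, 2] - mean(traj@x[, 2])
  # FFT-based cross-correlation, normalized to correlation units
  nf <- nextn(n + L, 2)
  cc <- Re(fft(fft(c(a, numeric(nf - n))) *
              Conj(fft(c(b, numeric(nf - n)))), inverse = TRUE)) / nf
  cc <- c(cc[(nf - L + 1L):nf], cc[1:(L + 1L)]) / (n * sd(a) * sd(b)) *
    n / (n - 1)
  lags <- (-L):L / fs
  refine <- function(i) {
    if (i <= 1L || i >= length(cc)) return(lags[i])
    denom <- cc[i - 1L] - 2 * cc[i] + cc[i + 1L]
    if (abs(denom) < 1e-15) return(lags[i])
    lags[i] + 0.5 * (cc[i - 1L] - cc[i + 1L]) / denom / fs
  }
  iMax <- which.max(cc)
  iMin <- which.min(cc)
  interior <- function(i) i > 1L && i < length(cc)
  if (!interior(iMax) || !interior(iMin))
    stop("no interior cross-correlation extrema within the lag range")
  if (abs(cc[iMax]) < minAmplitude || abs(cc[iMin]) < minAmplitude)
    stop("cross-correlation extrema below the amplitude floor; ",
         "frequency estimate unreliable")
  1 / (2 * abs(refine(iMax) - refine(iMin)))
}
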