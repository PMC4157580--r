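#' Multichannel LFP recording
#'
#' A uniformly sampled block of local field potential (LFP) channels with
#' per-channel cortical-area labels. Samples are stored channels x time, in
#' microvolts. The `reference` tag records whether channels are raw
#' surface-referenced signals or have had the within-area mean subtracted.
#'
#' @slot samples numeric matrix, channels x time, microvolts.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelArea character vector, one area label (e.g. `"M1"`, `"PMv"`)
#'   per channel.
#' @slot reference `"surface"` or `"area-mean"`.
#'
#' @seealso [multichannelRecording()], [lowpassDelta()], [meanReference()]
#' @export
setClass("MultichannelRecording",
  representation(samples = "matrix", sampleRate = "numeric",
                 channelArea = "character", reference = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@samples)) msg <- c(msg, "'samples' must be numeric")
    if (anyNA(object@samples) || any(!is.finite(object@samples)))
      msg <- c(msg, "'samples' must be finite with no NAs")
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
      msg <- c(msg, "'sampleRate' must be a single positive number")
    if (length(object@channelArea) != nrow(object@samples))
      msg <- c(msg, "'channelArea' must have one label per channel")
    if (!object@reference %in% c("surface", "area-mean"))
      msg <- c(msg, "'reference' must be \"surface\" or \"area-mean\"")
    if (length(msg)) msg else TRUE
  })

#' Construct a MultichannelRecording
#'
#' @param samples channels x time numeric matrix (microvolts).
#' @param sampleRate sampling rate, Hz.
#' @param channelArea area label per channel; recycled if length 1.
#' @param reference `"surface"` (default) or `"area-mean"`.
#' @return A [MultichannelRecording-class] object.
#' @examples
#' rec <- multichannelRecording(matrix(rnorm(200), 2), 100)
#' nChannels(rec)
#' @export
multichannelRecording <- function(samples, sampleRate,
                                  channelArea = "M1", reference = "surface") {
  if (length(channelArea) == 1L) channelArea <- rep(channelArea, nrow(samples))
  new("MultichannelRecording", samples = samples, sampleRate = sampleRate,
      channelArea = channelArea, reference = reference)
}

#' Kinematics of isometric cursor control
#'
#' Holds the 2D torque trace (cursor position, percent of screen where 100%
#' corresponds to 0.67 Nm), the radial position (its Euclidean norm) and the
#' signed radial speed (its time derivative, positive for movement away from
#' the screen center).
#'
#' @slot torque time x 2 matrix, percent of screen.
#' @slot radialPosition numeric vector, percent.
#' @slot radialSpeed numeric vector, percent/s.
#' @slot sampleRate Hz.
#' @seealso [computeRadialSpeed()], [detectSubmovements()]
#' @export
setClass("KinematicsTrace",
  representation(torque = "matrix", radialPosition = "numeric",
                 radialSpeed = "numeric", sampleRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@torque) != 2L) msg <- c(msg, "'torque' must have 2 columns")
    if (length(object@radialPosition) != nrow(object@torque) ||
        length(object@radialSpeed) != nrow(object@torque))
      msg <- c(msg, "radialPosition/radialSpeed must match torque length")
    if (any(object@radialPosition < -1e-9))
      msg <- c(msg, "'radialPosition' must be non-negative")
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
      msg <- c(msg, "'sampleRate' must be positive")
    if (length(msg)) msg else TRUE
  })

#' Principal-component basis of an LFP recording
#'
#' Orthonormal channel loadings of the LFP covariance with the rotational
#' orientation convention applied (see [fitPCA()]). Channel means used for
#' centering are stored so that other conditions can be projected onto the
#' same axes.
#'
#' @slot loadings channels x components matrix, columns orthonormal.
#' @slot centers per-channel means removed before projection.
#' @slot varianceExplained fraction of variance per component (non-increasing).
#' @slot sourceCondition label of the condition the basis was fit on.
#' @slot orientationFixed whether the anticlockwise orientation convention
#'   was applied (requires >= 2 components).
#' @seealso [fitPCA()], [projectRecording()]
#' @export
setClass("PCBasis",
  representation(loadings = "matrix", centers = "numeric",
                 varianceExplained = "numeric", sourceCondition = "character",
                 orientationFixed = "logical"),
  validity = function(object) {
    msg <- character()
    k <- ncol(object@loadings)
    if (length(object@centers) != nrow(object@loadings))
      msg <- c(msg, "'centers' must have one entry per channel")
    ortho <- crossprod(object@loadings)
    if (max(abs(ortho - diag(k))) > 1e-8)
      msg <- c(msg, "loading columns must be orthonormal")
    ve <- object@varianceExplained
    if (length(ve) != k || any(diff(ve) > 1e-12) || sum(ve) > 1 + 1e-8)
      msg <- c(msg, "'varianceExplained' must be non-increasing and sum <= 1")
    if (length(msg)) msg else TRUE
  })

#' State trajectory of LFP principal components
#'
#' A 2D or 3D time series of LFP-PC scores together with its time derivative
#' (central differences, one-sided at the endpoints) and a band label.
#'
#' @slot x time x d matrix of PC scores (d in 2:3), microvolt-scaled units.
#' @slot xdot time x d matrix, units per second.
#' @slot sampleRate Hz.
#' @slot band `"delta"` or `"beta"`.
#' @seealso [projectRecording()], [arealVelocity()], [fitDynamics()]
#' @export
setClass("StateTrajectory",
  representation(x = "matrix", xdot = "matrix", sampleRate = "numeric",
                 band = "character"),
  validity = function(object) {
    msg <- character()
    if (!ncol(object@x) %in% 2:3) msg <- c(msg, "'x' must have 2 or 3 columns")
    if (!identical(dim(object@x), dim(object@xdot)))
      msg <- c(msg, "'x' and 'xdot' must have identical dimensions")
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
      msg <- c(msg, "'sampleRate' must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a StateTrajectory from a score matrix
#'
#' The derivative is computed by central differences times the sample rate,
#' one-sided at the endpoints.
#'
#' @param x time x d numeric matrix (d = 2 or 3).
#' @param sampleRate Hz.
#' @param band band label, `"delta"` (default) or `"beta"`.
#' @return A [StateTrajectory-class] object.
#' @export
stateTrajectory <- function(x, sampleRate, band = "delta") {
  x <- as.matrix(x)
  new("StateTrajectory", x = x, xdot = centralDiff(x, sampleRate),
      sampleRate = sampleRate, band = band)
}

#' Areal-velocity series of a state trajectory
#'
#' The vector areal velocity v(t) = x(t) x xdot(t) / 2 of a 2D or 3D
#' trajectory. For 2D input the trajectory is embedded in the z = 0 plane so
#' the series is (0, 0, z(t)). Units are component-units squared per second.
#'
#' @slot v time x 3 matrix.
#' @slot sampleRate Hz.
#' @seealso [arealVelocity()], [rotationFrequency()]
#' @export
setClass("ArealVelocitySeries",
  representation(v = "matrix", sampleRate = "numeric"),
  validity = function(object) {
    if (ncol(object@v) != 3L) "'v' must have 3 columns" else TRUE
  })

#' Areal-velocity kinematic decoder model
#'
#' The five direction-basis coefficient vectors b0..b4 (each 3D, 15 free
#' scalars) of the areal-velocity model v_i = s_i * b(theta_i), with
#' b(theta) = b0 + b1 cos(theta) + b2 sin(theta) + b3 cos(2 theta) +
#' b4 sin(2 theta).
#'
#' @slot coefficients 5 x 3 matrix; rows b0..b4, columns areal-velocity
#'   components; units of areal velocity per (%/s).
#' @slot nEventsFit number of submovements used for the fit.
#' @seealso [fitDecoder()], [decodeSpeed()], [decodeDirection()]
#' @export
setClass("DecoderModel",
  representation(coefficients = "matrix", nEventsFit = "integer"),
  validity = function(object) {
    if (!identical(dim(object@coefficients), c(5L, 3L)))
      "'coefficients' must be a 5 x 3 matrix (b0..b4 by component)"
    else TRUE
  })

#' Leave-one-out decoding result
#'
#' Per-event decoded speed and direction under leave-one-out
#' cross-validation, with coefficients of determination
#' CoD(speed) = 1 - sum((s - shat)^2) / sum(s^2) and
#' CoD(direction) = mean(cos(theta - thetahat)), and optional 95th-percentile
#' shuffle thresholds.
#'
#' @slot decodedSpeed,decodedDirection per-event estimates (NA where an event
#'   could not be decoded).
#' @slot codSpeed,codDirection coefficients of determination.
#' @slot nUndecoded number of events excluded from the CoDs.
#' @slot shuffleThresholdSpeed,shuffleThresholdDirection 95th percentiles of
#'   the CoD under label shuffling (NA until [shuffleSignificance()] is run).
#' @seealso [looDecode()], [shuffleSignificance()]
#' @export
setClass("DecodingResult",
  representation(decodedSpeed = "numeric", decodedDirection = "numeric",
                 codSpeed = "numeric", codDirection = "numeric",
                 nUndecoded = "integer",
                 shuffleThresholdSpeed = "numeric",
                 shuffleThresholdDirection = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@decodedSpeed) != length(object@decodedDirection))
      msg <- c(msg, "decoded speed/direction must have equal length")
    if (is.finite(object@codDirection) && object@codDirection > 1 + 1e-12)
      msg <- c(msg, "'codDirection' cannot exceed 1")
    if (length(msg)) msg else TRUE
  })

#' Trace-zero linear dynamics model
#'
#' A 2 x 2 matrix A with trace(A) = 0 (three free parameters) describing
#' xdot(t) = A x(t) for the first two LFP-PCs, with fit metadata.
#'
#' @slot A 2 x 2 matrix, units 1/s; trace zero.
#' @slot band band label of the trajectory the model was fit on.
#' @slot sourceCondition condition label of the fitting data.
#' @slot codFit vector coefficient of determination of the fit,
#'   1 - int |A x - xdot|^2 dt / int |xdot|^2 dt.
#' @seealso [fitDynamics()], [dynamicsCoD()], [modelFrequency()]
#' @export
setClass("DynamicsModel",
  representation(A = "matrix", band = "character",
                 sourceCondition = "character", codFit = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@A), c(2L, 2L)))
      msg <- c(msg, "'A' must be 2 x 2")
    else {
      tr <- abs(object@A[1, 1] + object@A[2, 2])
      scale <- max(abs(object@A), 1e-300)
      if (tr > 1e-10 * max(1, scale))
        msg <- c(msg, "trace(A) must be zero")
    }
    if (length(msg)) msg else TRUE
  })

#' Ground truth of a synthetic session
#'
#' Everything the synthetic generator knows that a real experiment does not:
#' the latent oscillator phase and amplitude over time, the injected
#' submovement and K-complex events, the per-neuron preferred phases, and
#' the channels x latent-dimensions mixing matrix.
#'
#' @slot latentPhase radians over time (unwrapped).
#' @slot latentAmplitude latent orbit radius over time (microvolt scale).
#' @slot submovements data.frame with columns `time`, `speed`, `direction`.
#' @slot kcomplexes numeric vector of K-complex peak times (s).
#' @slot preferredPhases radians per neuron.
#' @slot mixingMatrix channels x latent-dims matrix (full column rank).
#' @slot latents time x 3 matrix of the noise-free latent trajectory
#'   (orbit plane in columns 1:2, direction-tilt axis in column 3).
#' @export
setClass("GroundTruth",
  representation(latentPhase = "numeric", latentAmplitude = "numeric",
                 submovements = "data.frame", kcomplexes = "numeric",
                 preferredPhases = "numeric", mixingMatrix = "matrix",
                 latents = "matrix"))

#' A complete recorded (or simulated) session
#'
#' Time-aligned LFP, kinematics, EMG and spike trains for one behavioral
#' condition, with trial bounds, the generating configuration (for synthetic
#' sessions) and ground truth where known.
#'
#' @slot lfp a [MultichannelRecording-class].
#' @slot kinematics a [KinematicsTrace-class] or NULL (non-task conditions).
#' @slot emg time x muscles matrix (possibly 0 columns).
#' @slot spikes list of strictly increasing spike-time vectors (s), one per
#'   unit.
#' @slot condition `"task"`, `"reach"`, `"sleep"` or `"sedation"`.
#' @slot trialBounds n x 2 matrix of trial start/end times (s).
#' @slot config the simulation configuration list (empty for real data).
#' @slot groundTruth a [GroundTruth-class] or NULL.
#' @seealso [simulateTaskSession()], [simulateSedationSession()],
#'   [writeSession()]
#' @export
setClass("RecordingSession",
  representation(lfp = "MultichannelRecording", kinematics = "ANY",
                 emg = "matrix", spikes = "list", condition = "character",
                 trialBounds = "matrix", config = "list",
                 groundTruth = "ANY"),
  validity = function(object) {
    msg <- character()
    if (!object@condition %in% c("task", "reach", "sleep", "sedation"))
      msg <- c(msg, "'condition' must be task/reach/sleep/sedation")
    if (length(object@spikes) &&
        !all(vapply(object@spikes, function(s) !is.unsorted(s, strictly = TRUE),
                    logical(1))))
      msg <- c(msg, "spike times must be strictly increasing per unit")
    if (ncol(object@trialBounds) != 2L)
      msg <- c(msg, "'trialBounds' must have 2 columns")
    if (length(msg)) msg else TRUE
  })
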