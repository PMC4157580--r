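#' Accessors for lfpdyn classes
#'
#' Small accessor generics: `lfpSamples()` returns the channels x time
#' matrix, `sampleRate()` the sampling rate in Hz, `channelArea()` the
#' per-channel area labels, `nChannels()` the channel count, `loadings()`
#' the channels x components PC loading matrix, `varianceExplained()` the
#' per-component variance fractions, `stateX()` / `stateXdot()` the
#' trajectory and its derivative, `dynamicsMatrix()` the 2 x 2 trace-zero
#' matrix and `decoderCoefficients()` the 5 x 3 coefficient matrix (rows
#' b0..b4).
#'
#' @param object an lfpdyn object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases sampleRate lfpSamples channelArea nChannels loadings
#'   varianceExplained stateX stateXdot dynamicsMatrix decoderCoefficients
NULL

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("lfpSamples", function(object) standardGeneric("lfpSamples"))
#' @rdname accessors
#' @export
setGeneric("channelArea", function(object) standardGeneric("channelArea"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(object) standardGeneric("varianceExplained"))
#' @rdname accessors
#' @export
setGeneric("stateX", function(object) standardGeneric("stateX"))
#' @rdname accessors
#' @export
setGeneric("stateXdot", function(object) standardGeneric("stateXdot"))
#' @rdname accessors
#' @export
setGeneric("dynamicsMatrix", function(object) standardGeneric("dynamicsMatrix"))
#' @rdname accessors
#' @export
setGeneric("decoderCoefficients", function(object) standardGeneric("decoderCoefficients"))

#' @rdname accessors
setMethod("sampleRate", "MultichannelRecording", function(object) object@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "StateTrajectory", function(object) object@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "KinematicsTrace", function(object) object@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "ArealVelocitySeries", function(object) object@sampleRate)
#' @rdname accessors
setMethod("lfpSamples", "MultichannelRecording", function(object) object@samples)
#' @rdname accessors
setMethod("channelArea", "MultichannelRecording", function(object) object@channelArea)
#' @rdname accessors
setMethod("nChannels", "MultichannelRecording", function(object) nrow(object@samples))
#' @rdname accessors
setMethod("loadings", "PCBasis", function(object) object@loadings)
#' @rdname accessors
setMethod("varianceExplained", "PCBasis", function(object) object@varianceExplained)
#' @rdname accessors
setMethod("stateX", "StateTrajectory", function(object) object@x)
#' @rdname accessors
setMethod("stateXdot", "StateTrajectory", function(object) object@xdot)
#' @rdname accessors
setMethod("dynamicsMatrix", "DynamicsModel", function(object) object@A)
#' @rdname accessors
setMethod("decoderCoefficients", "DecoderModel", function(object) object@coefficients)

setMethod("show", "MultichannelRecording", function(object) {
  cat(sprintf("MultichannelRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@samples), ncol(object@samples), object@sampleRate,
              ncol(object@samples) / object@sampleRate))
  cat(sprintf("  areas: %s; reference: %s\n",
              paste(sprintf("%s (%d)", names(table(object@channelArea)),
                            table(object@channelArea)), collapse = ", "),
              object@reference))
})

setMethod("show", "KinematicsTrace", function(object) {
  cat(sprintf("KinematicsTrace: %d samples @ %g Hz; peak radial speed %.1f %%/s\n",
              nrow(object@torque), object@sampleRate, max(object@radialSpeed)))
})

setMethod("show", "PCBasis", function(object) {
  cat(sprintf("PCBasis: %d channels x %d components (source: %s)\n",
              nrow(object@loadings), ncol(object@loadings), object@sourceCondition))
  cat(sprintf("  variance explained: %s; orientation fixed: %s\n",
              paste(sprintf("%.1f%%", 100 * object@varianceExplained), collapse = ", "),
              object@orientationFixed))
})

setMethod("show", "StateTrajectory", function(object) {
  cat(sprintf("StateTrajectory: %d samples x %d components @ %g Hz (band: %s)\n",
              nrow(object@x), ncol(object@x), object@sampleRate, object@band))
})

setMethod("show", "ArealVelocitySeries", function(object) {
  cat(sprintf("ArealVelocitySeries: %d samples @ %g Hz; mean |v| = %.3g\n",
              nrow(object@v), object@sampleRate,
              mean(sqrt(rowSums(object@v^2)))))
})

setMethod("show", "DecoderModel", function(object) {
  cat(sprintf("DecoderModel: 15 coefficients (b0..b4 x 3), fit on %d events\n",
              object@nEventsFit))
  cat(sprintf("  |b0| = %.4g\n", sqrt(sum(object@coefficients[1, ]^2))))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %d events (%d undecoded)\n",
              length(object@decodedSpeed), object@nUndecoded))
  cat(sprintf("  CoD(speed) = %.3f  CoD(direction) = %.3f\n",
              object@codSpeed, object@codDirection))
  if (is.finite(object@shuffleThresholdSpeed))
    cat(sprintf("  shuffle 95%% thresholds: speed %.3f, direction %.3f\n",
                object@shuffleThresholdSpeed, object@shuffleThresholdDirection))
})

setMethod("show", "DynamicsModel", function(object) {
  f <- modelFrequency(object)
  cat(sprintf("DynamicsModel (band: %s, source: %s): CoD = %.3f\n",
              object@band, object@sourceCondition, object@codFit))
  cat(sprintf("  A = [[%.3g, %.3g], [%.3g, %.3g]]; frequency = %s Hz\n",
              object@A[1, 1], object@A[1, 2], object@A[2, 1], object@A[2, 2],
              if (is.na(f)) "NA (non-oscillatory)" else sprintf("%.3f", f)))
})

setMethod("show", "RecordingSession", function(object) {
  cat(sprintf("RecordingSession (%s): %.1f s, %d LFP channels, %d units\n",
              object@condition, ncol(object@lfp@samples) / object@lfp@sampleRate,
              nrow(object@lfp@samples), length(object@spikes)))
  if (!is.null(object@groundTruth))
    cat(sprintf("  ground truth: %d submovements, %d K complexes\n",
                nrow(object@groundTruth@submovements),
                length(object@groundTruth@kcomplexes)))
})
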