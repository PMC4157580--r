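# Zero-phase Butterworth filtering and the preprocessing chain:
# band filtering -> within-area mean referencing -> PCA -> projection.

# Forward-backward IIR filtering with odd-reflection edge padding (the
# classic filtfilt strategy): pad with 2*x[1] - x[p+1 .. 2] at the start and
# mirror-image at the end, filter forward, reverse, filter again, reverse,
# strip the padding. The double pass squares the magnitude response and
# cancels the phase response.
zeroPhaseFilter <- function(x, b, a, padLength) {
  n <- length(x)
  p <- min(padLength, n - 1L)
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- .iirFilter(b, a, xp)
  y <- rev(.iirFilter(b, a, rev(y)))
  y[(p + 1L):(p + n)]
}

butterCoefs <- function(order, W, type) {
  bt <- signal::butter(order, W, type)
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

filterRecording <- function(rec, coefs, padLength) {
  out <- rec@samples
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- zeroPhaseFilter(out[ch, ], coefs$b, coefs$a, padLength)
  initialize(rec, samples = out)
}

#' Delta-band low-pass filter (5 Hz, four-pole, zero-phase)
#'
#' Applies a 4-pole Butterworth low-pass at 5 Hz forward and backward
#' (zero phase lag, doubled attenuation) to every channel, with
#' odd-reflection edge padding so the output has the same length as the
#' input.
#'
#' @param rec a [MultichannelRecording-class]; sample rate must exceed 10 Hz.
#' @param cutoff cutoff frequency in Hz (default 5).
#' @return A filtered [MultichannelRecording-class].
#' @examples
#' rec <- multichannelRecording(matrix(rnorm(2000), 2), 488)
#' lp <- lowpassDelta(rec)
#' @export
lowpassDelta <- function(rec, cutoff = 5) {
  stopifnot(is(rec, "MultichannelRecording"))
  fs <- rec@sampleRate
  if (fs <= 2 * cutoff) stop("sample rate must exceed twice the cutoff")
  irScale <- ceiling(fs / cutoff)  # samples per cutoff period
  if (ncol(rec@samples) < 3L * irScale)
    stop("recording shorter than 3x the filter impulse-response scale (",
         3L * irScale, " samples needed)")
  coefs <- butterCoefs(4, cutoff / (fs / 2), "low")
  # pad well past the transient (~10 cutoff periods) so edge effects decay
  filterRecording(rec, coefs, padLength = 10L * irScale)
}

#' Beta-band filter (10-30 Hz, four-pole, zero-phase)
#'
#' Four-pole Butterworth band-pass (order-2 design, giving 4 poles) applied
#' forward and backward as in [lowpassDelta()].
#'
#' @param rec a [MultichannelRecording-class].
#' @param band numeric length-2, passband edges in Hz (default `c(10, 30)`).
#' @return A filtered [MultichannelRecording-class].
#' @export
bandpassBeta <- function(rec, band = c(10, 30)) {
  stopifnot(is(rec, "MultichannelRecording"), length(band) == 2L)
  fs <- rec@sampleRate
  if (fs <= 2 * band[2]) stop("sample rate must exceed twice the upper edge")
  irScale <- ceiling(fs / band[1])
  if (ncol(rec@samples) < 3L * irScale)
    stop("recording shorter than 3x the filter impulse-response scale (",
         3L * irScale, " samples needed)")
  coefs <- butterCoefs(2, band / (fs / 2), "pass")
  filterRecording(rec, coefs, padLength = 10L * irScale)
}

#' Within-area mean referencing
#'
#' Subtracts, at every sample, the mean across channels belonging to the
#' same cortical area. After referencing, the cross-channel mean within each
#' area is exactly zero at every sample.
#'
#' @param rec a [MultichannelRecording-class] with at least 2 channels per
#'   area.
#' @return A referenced [MultichannelRecording-class] (`reference ==
#'   "area-mean"`).
#' @export
meanReference <- function(rec) {
  stopifnot(is(rec, "MultichannelRecording"))
  out <- rec@samples
  for (area in unique(rec@channelArea)) {
    idx <- which(rec@channelArea == area)
    if (length(idx) < 2L)
      stop("area '", area, "' has a single channel; mean reference undefined")
    out[idx, ] <- sweep(out[idx, , drop = FALSE], 2L, colMeans(out[idx, , drop = FALSE]))
  }
  initialize(rec, samples = out, reference = "area-mean")
}

#' Principal-component basis with rotational orientation convention
#'
#' Computes the orthonormal eigenbasis of the channel covariance (over the
#' full recording) and applies two sign conventions for reproducibility:
#' every component's largest-magnitude loading is made positive, and then,
#' if the time-averaged planar areal velocity of the PC1-PC2 projection is
#' clockwise (negative z), PC2 is negated so that the predominant rotation
#' is anticlockwise.
#'
#' @param rec a [MultichannelRecording-class], normally delta-filtered and
#'   mean-referenced.
#' @param nComponents number of components to keep (<= channel count and
#'   <= covariance rank).
#' @param sourceCondition label recorded in the basis (default `"task"`).
#' @return A [PCBasis-class].
#' @examples
#' t <- seq(0, 2, by = 1/488)
#' rec <- multichannelRecording(rbind(cos(2*pi*3*t), sin(2*pi*3*t)), 488)
#' basis <- fitPCA(rec, 2)
#' varianceExplained(basis)
#' @export
fitPCA <- function(rec, nComponents, sourceCondition = "task") {
  stopifnot(is(rec, "MultichannelRecording"))
  X <- rec@samples
  nc <- nrow(X)
  if (nComponents > nc) stop("more components requested than channels")
  centers <- rowMeans(X)
  Xc <- X - centers
  cv <- tcrossprod(Xc) / (ncol(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-10)
  if (nComponents > rank)
    stop("covariance has rank ", rank, "; cannot extract ", nComponents,
         " components")
  L <- eg$vectors[, seq_len(nComponents), drop = FALSE]
  # sign convention 1: largest-magnitude loading positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  orientationFixed <- FALSE
  if (nComponents >= 2L) {
    # sign convention 2: anticlockwise predominant rotation in PC1-PC2
    sc <- crossprod(Xc, L[, 1:2, drop = FALSE])
    scd <- centralDiff(sc, rec@sampleRate)
    meanZ <- mean(sc[, 1] * scd[, 2] - sc[, 2] * scd[, 1]) / 2
    if (meanZ < 0) L[, 2] <- -L[, 2]
    orientationFixed <- TRUE
  }
  new("PCBasis", loadings = L, centers = centers,
      varianceExplained = ev[seq_len(nComponents)] / sum(ev),
      sourceCondition = sourceCondition, orientationFixed = orientationFixed)
}

#' Project a recording onto a PC basis
#'
#' Projects any condition's channels onto the axes (and centering) derived
#' from another condition, returning a [StateTrajectory-class] with the
#' central-difference derivative.
#'
#' @param rec a [MultichannelRecording-class]; channel count must match the
#'   basis.
#' @param basis a [PCBasis-class].
#' @param band band label stored in the trajectory (default `"delta"`).
#' @return A [StateTrajectory-class].
#' @export
projectRecording <- function(rec, basis, band = "delta") {
  stopifnot(is(rec, "MultichannelRecording"), is(basis, "PCBasis"))
  if (nrow(rec@samples) != nrow(basis@loadings))
    stop("channel count (", nrow(rec@samples), ") does not match basis (",
         nrow(basis@loadings), ")")
  x <- crossprod(rec@samples - basis@centers, basis@loadings)
  stateTrajectory(x, rec@sampleRate, band = band)
}
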