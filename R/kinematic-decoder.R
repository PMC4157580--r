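# Fourier-parameterized areal-velocity decoder of submovement speed and
# direction: v_i = s_i * b(theta_i), with
# b(theta) = b0 + b1 cos(theta) + b2 sin(theta) + b3 cos(2 theta) +
# b4 sin(2 theta), fit by least squares; leave-one-out decoding and shuffle
# significance.

harmonicNames <- c("b0", "b1.cos", "b2.sin", "b3.cos2", "b4.sin2")

designRow <- function(s, theta) {
  cbind(s, s * cos(theta), s * sin(theta), s * cos(2 * theta), s * sin(2 * theta))
}

checkDecoderInputs <- function(v, s, theta) {
  v <- as.matrix(v)
  if (ncol(v) != 3L) stop("'v' must be an n x 3 matrix of areal-velocity vectors")
  n <- nrow(v)
  if (length(s) != n || length(theta) != n)
    stop("'s' and 'theta' must match the number of rows of 'v'")
  if (any(!is.finite(v)) || any(!is.finite(s)) || any(!is.finite(theta)))
    stop("non-finite decoder inputs")
  v
}

#' Fit the areal-velocity kinematic decoder
#'
#' Least-squares solution of the stacked linear system
#' v_i = s_i * b(theta_i) over all three areal-velocity components: 15 free
#' scalar coefficients (five 3-vectors b0..b4). Deterministic.
#'
#' @param v n x 3 matrix of per-submovement average areal-velocity vectors
#'   (see [eventArealVelocityVector()]).
#' @param s peak speeds, %/s (nonzero).
#' @param theta directions, radians.
#' @return A [DecoderModel-class]. Errors on a rank-deficient design (e.g.
#'   all directions equal), naming the deficient harmonics.
#' @export
fitDecoder <- function(v, s, theta) {
  v <- checkDecoderInputs(v, s, theta)
  if (nrow(v) < 15L) stop("need at least 15 events to fit 15 coefficients")
  X <- designRow(s, theta)
  qrX <- qr(X)
  if (qrX$rank < 5L) {
    bad <- harmonicNames[sort(qrX$pivot[(qrX$rank + 1L):5L])]
    stop("rank-deficient design; deficient harmonics: ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qrX, v)
  dimnames(B) <- list(c("b0", "b1", "b2", "b3", "b4"), c("v1", "v2", "v3"))
  new("DecoderModel", coefficients = B, nEventsFit = nrow(v))
}

#' Direction basis vector b(theta) of a decoder model
#'
#' @param model a [DecoderModel-class].
#' @param theta direction(s), radians.
#' @return length(theta) x 3 matrix of basis vectors.
#' @export
directionBasis <- function(model, theta) {
  F <- cbind(1, cos(theta), sin(theta), cos(2 * theta), sin(2 * theta))
  F %*% model@coefficients
}

#' Decode submovement speed from an areal-velocity vector
#'
#' The decoded speed is |v_j| / |b0|.
#'
#' @param v length-3 areal-velocity vector, or an n x 3 matrix.
#' @param model a [DecoderModel-class] with |b0| > 0.
#' @return decoded speed(s), %/s.
#' @export
decodeSpeed <- function(v, model) {
  b0 <- sqrt(sum(model@coefficients[1, ]^2))
  if (b0 < 1e-12) stop("|b0| is (near) zero; speed decoding undefined")
  v <- if (is.matrix(v)) v else matrix(v, 1L)
  sqrt(rowSums(v^2)) / b0
}

decoderGrid <- function(gridStep = 0.5) {
  seq(0, 360 - gridStep, by = gridStep) * pi / 180
}

# Grid objective and argmax for one event given a coefficient matrix B.
decodeDirectionB <- function(v, B, thetaGrid, Fgrid) {
  if (sqrt(sum(v^2)) < 1e-12) stop("undecodable event (zero areal velocity)")
  Bg <- Fgrid %*% B
  nrm <- sqrt(rowSums(Bg^2))
  if (any(nrm < 1e-12)) stop("|b(theta)| vanishes on the grid")
  obj <- as.numeric(Bg %*% v) / nrm
  if (diff(range(obj)) < 1e-12)
    stop("flat direction objective; direction not encoded by the model")
  wrapToPi(thetaGrid[which.max(obj)])
}

#' Decode submovement direction from an areal-velocity vector
#'
#' Brute-force grid search over theta in [0, 360) degrees at `gridStep`
#' resolution, maximizing the normalized dot product
#' v_j . b(theta) / |b(theta)|. Ties are broken by the smallest theta.
#'
#' @param v length-3 areal-velocity vector.
#' @param model a [DecoderModel-class].
#' @param gridStep grid resolution, degrees (default 0.5).
#' @return decoded direction, radians in `[-pi, pi)`.
#' @export
decodeDirection <- function(v, model, gridStep = 0.5) {
  thetaGrid <- decoderGrid(gridStep)
  Fgrid <- cbind(1, cos(thetaGrid), sin(thetaGrid),
                 cos(2 * thetaGrid), sin(2 * thetaGrid))
  decodeDirectionB(as.numeric(v), model@coefficients, thetaGrid, Fgrid)
}

# Core leave-one-out decoder. Uses downdated normal equations
# (G - x_j x_j', H - x_j v_j') so each held-out fit is a 5 x 5 solve.
looCore <- function(v, s, theta, gridStep = 0.5,
                    what = c("speed", "direction")) {
  n <- nrow(v)
  X <- designRow(s, theta)
  G <- crossprod(X)
  H <- crossprod(X, v)
  thetaGrid <- decoderGrid(gridStep)
  Fgrid <- cbind(1, cos(thetaGrid), sin(thetaGrid),
                 cos(2 * thetaGrid), sin(2 * thetaGrid))
  sHat <- rep(NA_real_, n)
  thetaHat <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    xj <- X[j, ]
    Bj <- tryCatch(
      solve(G - tcrossprod(xj), H - tcrossprod(xj, v[j, ])),
      error = function(e) NULL)
    if (is.null(Bj)) next
    if ("speed" %in% what) {
      b0 <- sqrt(sum(Bj[1, ]^2))
      if (b0 > 1e-12) sHat[j] <- sqrt(sum(v[j, ]^2)) / b0
    }
    if ("direction" %in% what)
      thetaHat[j] <- tryCatch(
        decodeDirectionB(v[j, ], Bj, thetaGrid, Fgrid),
        error = function(e) NA_real_)
  }
  list(sHat = sHat, thetaHat = thetaHat)
}

#' Leave-one-out decoding of submovement kinematics
#'
#' For each submovement j the decoder is fit on the other N - 1 events and
#' used to decode event j; repeated until all N events are estimated.
#' Performance is summarized by
#' CoD(speed) = 1 - sum((s_j - shat_j)^2) / sum(s_j^2) (note: normalized by
#' the raw sum of squares, not the variance) and
#' CoD(direction) = mean(cos(theta_j - thetahat_j)). Events whose held-out
#' fit or decode fails are excluded from the CoDs and counted.
#'
#' @inheritParams fitDecoder
#' @param gridStep direction grid resolution, degrees (default 0.5).
#' @return A [DecodingResult-class].
#' @export
looDecode <- function(v, s, theta, gridStep = 0.5) {
  v <- checkDecoderInputs(v, s, theta)
  n <- nrow(v)
  if (n < 16L) stop("need at least 16 events for leave-one-out decoding")
  res <- looCore(v, s, theta, gridStep)
  okS <- is.finite(res$sHat)
  okT <- is.finite(res$thetaHat)
  new("DecodingResult",
      decodedSpeed = res$sHat, decodedDirection = res$thetaHat,
      codSpeed = 1 - sum((s[okS] - res$sHat[okS])^2) / sum(s[okS]^2),
      codDirection = mean(cos(theta[okT] - res$thetaHat[okT])),
      nUndecoded = sum(!(okS & okT)),
      shuffleThresholdSpeed = NA_real_, shuffleThresholdDirection = NA_real_)
}

#' Shuffle significance thresholds for decoding CoDs
#'
#' Repeats the full leave-one-out procedure on surrogate data sets in which
#' the speeds (for the speed CoD) or the directions (for the direction CoD)
#' are permuted across submovements, the areal-velocity vectors staying
#' fixed. Reports the 95th percentile of each CoD under its null.
#'
#' @inheritParams looDecode
#' @param nShuffles number of surrogate data sets (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list with `thresholdSpeed`, `thresholdDirection` (95th
#'   percentiles), and the full null distributions `codSpeed`,
#'   `codDirection`.
#' @export
shuffleSignificance <- function(v, s, theta, nShuffles = 1000L, seed = NULL,
                                gridStep = 0.5) {
  v <- checkDecoderInputs(v, s, theta)
  if (nShuffles < 1L) stop("'nShuffles' must be at least 1")
  n <- nrow(v)
  withSeed(seed, {
    codS <- numeric(nShuffles)
    codT <- numeric(nShuffles)
    for (k in seq_len(nShuffles)) {
      sPerm <- s[sample.int(n)]
      resS <- looCore(v, sPerm, theta, gridStep, what = "speed")
      ok <- is.finite(resS$sHat)
      codS[k] <- 1 - sum((sPerm[ok] - resS$sHat[ok])^2) / sum(sPerm[ok]^2)
      tPerm <- theta[sample.int(n)]
      resT <- looCore(v, s, tPerm, gridStep, what = "direction")
      ok <- is.finite(resT$thetaHat)
      codT[k] <- mean(cos(tPerm[ok] - resT$thetaHat[ok]))
    }
    list(thresholdSpeed = unname(quantile(codS, 0.95, type = 7)),
         thresholdDirection = unname(quantile(codT, 0.95, type = 7)),
         codSpeed = codS, codDirection = codT)
  })
}
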