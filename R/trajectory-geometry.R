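# Areal velocity and rotation frequency of LFP-PC trajectories, and
# event-aligned averages binned by speed or direction.

embed3 <- function(m) {
  if (ncol(m) == 3L) m else cbind(m, 0)
}

crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Areal velocity of a state trajectory
#'
#' The vector areal velocity v(t) = x(t) x xdot(t) / 2 — the area swept per
#' unit time about the origin. For a 2D trajectory the plane is embedded at
#' z = 0, so v(t) = (0, 0, (x1 xdot2 - x2 xdot1) / 2) and the z component is
#' the signed planar areal velocity (anticlockwise positive).
#'
#' @param traj a [StateTrajectory-class] with 2 or 3 components.
#' @return An [ArealVelocitySeries-class].
#' @examples
#' t <- seq(0, 1, by = 1/488)
#' traj <- stateTrajectory(cbind(cos(2*pi*3*t), sin(2*pi*3*t)), 488)
#' v <- arealVelocity(traj)   # |v| = pi * 3 * r^2 with r = 1
#' @export
arealVelocity <- function(traj) {
  stopifnot(is(traj, "StateTrajectory"))
  v <- crossRows(embed3(traj@x), embed3(traj@xdot)) / 2
  new("ArealVelocitySeries", v = v, sampleRate = traj@sampleRate)
}

#' Instantaneous rotation frequency of a trajectory
#'
#' From |v(t)| = |x(t)|^2 * 2 pi f(t) / 2, the rotation frequency is
#' f(t) = |v(t)| / (pi |x(t)|^2), signed by the rotation sense (sign of the
#' z component of the areal velocity). Samples where |x| falls below a
#' relative tolerance are masked as NA.
#'
#' @param traj a [StateTrajectory-class].
#' @param tol relative tolerance on |x|^2 (fraction of its maximum) below
#'   which the frequency is undefined (default 1e-10).
#' @return numeric vector of signed frequencies, Hz (NA where undefined).
#' @export
rotationFrequency <- function(traj, tol = 1e-10) {
  v <- arealVelocity(traj)@v
  r2 <- rowSums(traj@x^2)
  f <- sqrt(rowSums(v^2)) / (pi * r2) * sign(v[, 3])
  f[r2 < tol * max(r2)] <- NA_real_
  f
}

#' Bin events into equal-count groups by increasing peak speed
#'
#' Events are sorted by peak speed (ties broken by event time, earlier
#' first) and split into `nGroups` groups of as-equal-as-possible size, with
#' remainders going to the lowest (slowest) groups. Higher speed never lands
#' in a lower group.
#'
#' @param events data.frame with `peakSpeed` and `peakTime` columns (as from
#'   [detectSubmovements()]).
#' @param nGroups number of groups (default 9).
#' @return integer vector of group indices (1 = slowest), aligned with the
#'   rows of `events`.
#' @export
binEventsBySpeed <- function(events, nGroups = 9L) {
  n <- nrow(events)
  if (n < nGroups) stop("need at least ", nGroups, " events")
  ord <- order(events$peakSpeed, events$peakTime, method = "radix")
  base <- n %/% nGroups
  extra <- n %% nGroups
  sizes <- rep(base, nGroups) + c(rep(1L, extra), rep(0L, nGroups - extra))
  groups <- integer(n)
  groups[ord] <- rep(seq_len(nGroups), times = sizes)
  groups
}

#' Bin events into direction groups
#'
#' Assigns each event to one of `nGroups` equal angular bins, the first bin
#' centered at 0 radians.
#'
#' @param events data.frame with a `direction` column (radians).
#' @param nGroups number of bins (default 6, i.e. 60 degrees each).
#' @return integer vector of bin indices in `1:nGroups`.
#' @export
binEventsByDirection <- function(events, nGroups = 6L) {
  width <- 2 * pi / nGroups
  (as.integer(round(events$direction / width)) %% nGroups) + 1L
}

#' Event-aligned trajectory averages per group
#'
#' For each group, the pointwise mean of the trajectory over windows of
#' +/- `halfWindow` around each event's peak time. Events whose window would
#' be clipped by the recording edge are skipped and counted.
#'
#' @param traj a [StateTrajectory-class].
#' @param events data.frame with a `peakTime` column.
#' @param groups integer group index per event (default: all one group).
#' @param halfWindow half window length, s (default 0.2).
#' @return list of one element per group, each a list with `group`, `time`
#'   (window time axis, s), `meanX` (window x d matrix), `nEvents`,
#'   `nSkipped`. Errors if any group has no usable events.
#' @export
averageEventTrajectories <- function(traj, events, groups = NULL,
                                     halfWindow = 0.2) {
  stopifnot(is(traj, "StateTrajectory"))
  if (is.null(groups)) groups <- rep(1L, nrow(events))
  fs <- traj@sampleRate
  h <- round(halfWindow * fs)
  n <- nrow(traj@x)
  out <- lapply(sort(unique(groups)), function(g) {
    tt <- events$peakTime[groups == g]
    centers <- round(tt * fs) + 1L
    ok <- centers - h >= 1L & centers + h <= n
    if (!any(ok)) stop("group ", g, " has no events with full windows")
    acc <- matrix(0, 2L * h + 1L, ncol(traj@x))
    for (ctr in centers[ok])
      acc <- acc + traj@x[(ctr - h):(ctr + h), , drop = FALSE]
    list(group = g, time = ((-h):h) / fs, meanX = acc / sum(ok),
         nEvents = sum(ok), nSkipped = sum(!ok))
  })
  out
}

#' Average 3D areal-velocity vector of one event window
#'
#' The time-average of v(t) = x(t) x xdot(t) / 2 over +/- `halfWindow`
#' around the event's peak time. This is the per-submovement vector consumed
#' by the kinematic decoder: its magnitude scales with submovement speed and
#' its orientation tilts with submovement direction.
#'
#' @param traj a 3-component [StateTrajectory-class].
#' @param eventTime event peak time, s.
#' @param halfWindow half window, s (default 0.2).
#' @return length-3 numeric vector. Errors if the window is clipped.
#' @export
eventArealVelocityVector <- function(traj, eventTime, halfWindow = 0.2) {
  stopifnot(is(traj, "StateTrajectory"))
  if (ncol(traj@x) != 3L) stop("a 3-component trajectory is required")
  fs <- traj@sampleRate
  h <- round(halfWindow * fs)
  ctr <- round(eventTime * fs) + 1L
  if (ctr - h < 1L || ctr + h > nrow(traj@x))
    stop("event window clipped by the recording edge")
  w <- (ctr - h):(ctr + h)
  colMeans(crossRows(traj@x[w, , drop = FALSE], traj@xdot[w, , drop = FALSE])) / 2
}

# Average areal-velocity vectors for a whole event table, dropping clipped
# events; returns the n x 3 matrix plus the kept-row index.
eventArealVelocityMatrix <- function(traj, events, halfWindow = 0.2) {
  fs <- traj@sampleRate
  h <- round(halfWindow * fs)
  ctr <- round(events$peakTime * fs) + 1L
  ok <- ctr - h >= 1L & ctr + h <= nrow(traj@x)
  v <- t(vapply(events$peakTime[ok],
                function(tt) eventArealVelocityVector(traj, tt, halfWindow),
                numeric(3)))
  list(v = v, kept = which(ok))
}
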