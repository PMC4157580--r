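# Areal velocity, rotation frequency, speed/direction binning and
# event-aligned averages.

fs <- 488

test_that("areal velocity of analytic circles matches the closed form", {
  # unit circle at 3 Hz: |v| = r^2 * 2 pi f / 2 = 3 pi
  traj <- circleTrajectory(3, 1)
  v <- arealVelocity(traj)
  mid <- 200:2000
  expect_equal(sqrt(rowSums(v@v[mid, ]^2)), rep(3 * pi, length(mid)),
               tolerance = 1e-3)
  expect_gt(min(v@v[mid, 3]), 0)  # anticlockwise positive

  # radius/frequency scaling, Hz convention
  traj2 <- circleTrajectory(2.5, 1.7)
  v2 <- arealVelocity(traj2)
  expect_equal(mean(sqrt(rowSums(v2@v[mid, ]^2))),
               0.5 * 1.7^2 * 2 * pi * 2.5, tolerance = 1e-3)

  # parallel x and xdot: zero cross product
  t <- seq(0, 2, by = 1 / fs)
  radial <- stateTrajectory(cbind(exp(t), 2 * exp(t)), fs)
  vr <- arealVelocity(radial)
  expect_lt(max(abs(vr@v[, 3])) / max(rowSums(radial@x^2)), 1e-3)
})

test_that("rotation frequency inverts the areal-velocity relation", {
  traj <- circleTrajectory(3, 0.8)
  f <- rotationFrequency(traj)
  expect_equal(f[200:2000], rep(3, 1801), tolerance = 1e-3)

  # elliptical orbit: pointwise frequency varies but the orbit average
  # matches the phase-unwrapping oracle
  t <- seq(0, 5, by = 1 / fs)
  ell <- stateTrajectory(cbind(2 * cos(2 * pi * 3 * t), sin(2 * pi * 3 * t)), fs)
  fEll <- rotationFrequency(ell)
  expect_gt(diff(range(fEll[200:2000])), 0.5)  # genuinely time-varying
  ang <- unwrap(atan2(ell@x[, 2] / 1, ell@x[, 1] / 2))
  oracleMean <- (ang[2001] - ang[201]) / (1800 / fs) / (2 * pi)
  # time average of dtheta/dt over whole cycles equals the orbit frequency
  cycle <- round(fs / 3)
  win <- 201:(201 + 5 * cycle)
  expect_equal(mean(fEll[win], na.rm = TRUE),
               mean(diff(unwrap(atan2(ell@x[win, 2], ell@x[win, 1]))) * fs / (2 * pi)),
               tolerance = 0.02)
  expect_equal(oracleMean, 3, tolerance = 0.01)

  # near-static samples are masked as undefined
  zeroTraj <- stateTrajectory(cbind(c(1, rep(0, 299)), rep(0, 300)), fs)
  expect_true(all(is.na(rotationFrequency(zeroTraj)[3:300])))
})

test_that("rotation-sense invariance: plane rotation leaves |v| and f unchanged", {
  traj <- circleTrajectory(3, 1.2, phase0 = 0)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  rot <- stateTrajectory(traj@x %*% t(R), fs)
  expect_equal(arealVelocity(rot)@v[, 3], arealVelocity(traj)@v[, 3],
               tolerance = 1e-9)
  expect_equal(rotationFrequency(rot), rotationFrequency(traj),
               tolerance = 1e-9)
})

test_that("resampling at twice the rate changes |v| by < 1%", {
  t1 <- seq(0, 5, by = 1 / fs)
  t2 <- seq(0, 5, by = 1 / (2 * fs))
  a <- arealVelocity(stateTrajectory(cbind(cos(2 * pi * 3 * t1),
                                           sin(2 * pi * 3 * t1)), fs))
  b <- arealVelocity(stateTrajectory(cbind(cos(2 * pi * 3 * t2),
                                           sin(2 * pi * 3 * t2)), 2 * fs))
  expect_lt(abs(mean(sqrt(rowSums(a@v[300:2000, ]^2))) /
                mean(sqrt(rowSums(b@v[600:4000, ]^2))) - 1), 0.01)
})

test_that("speed binning gives equal-count monotone groups with time tie-break", {
  ev <- data.frame(peakSpeed = c(90, 30, 50, 70, 40, 60, 35, 45, 55, 65,
                                 75, 80, 85, 95, 100, 110, 32, 120),
                   peakTime = seq_len(18))
  g <- binEventsBySpeed(ev, 9)
  expect_equal(as.numeric(table(g)), rep(2, 9))
  ord <- order(ev$peakSpeed)
  expect_true(all(diff(g[ord]) >= 0))

  ties <- data.frame(peakSpeed = rep(50, 9), peakTime = c(5, 3, 8, 1, 9, 2, 7, 4, 6))
  gt <- binEventsBySpeed(ties, 9)
  expect_equal(gt[order(ties$peakTime)], 1:9)
  expect_error(binEventsBySpeed(ties[1:5, ], 9), "at least")
})

test_that("direction binning uses six 60-degree bins centered at 0", {
  ev <- data.frame(direction = c(0, 0.4, -0.4, pi / 3, 2 * pi / 3, pi - 0.01,
                                 -pi / 3, -2 * pi / 3))
  expect_equal(binEventsByDirection(ev),
               c(1L, 1L, 1L, 2L, 3L, 4L, 6L, 5L))
})

test_that("group-mean areal velocity increases with cursor speed", {
  ses <- taskSession()
  traj <- cachedFixture("traj3_task", {
    rec <- meanReference(lowpassDelta(ses@lfp))
    projectRecording(rec, fitPCA(rec, 3))
  })
  ev <- detectSubmovements(ses@kinematics)
  av <- lfpdyn:::eventArealVelocityMatrix(traj, ev)
  ev <- ev[av$kept, ]
  g <- binEventsBySpeed(ev, 9)
  mags <- vapply(1:9, function(k)
    mean(sqrt(rowSums(av$v[g == k, , drop = FALSE]^2))), numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("event-aligned averages preserve locked oscillations and shrink random ones", {
  t <- seq(0, 60, by = 1 / fs)
  sig <- cos(2 * pi * 3 * t)
  traj <- stateTrajectory(cbind(sig, sin(2 * pi * 3 * t)), fs)
  locked <- data.frame(peakTime = seq(1, 59, by = 1 / 3))
  avgL <- averageEventTrajectories(traj, locked)[[1]]
  expect_equal(max(abs(avgL$meanX[, 1])), 1, tolerance = 1e-3)

  single <- averageEventTrajectories(traj, data.frame(peakTime = 10))[[1]]
  ctr <- round(10 * fs) + 1L
  h <- round(0.2 * fs)
  expect_equal(single$meanX, traj@x[(ctr - h):(ctr + h), ])

  shrink <- withr::with_seed(4, {
    vapply(c(25, 100, 400), function(n) {
      ev <- data.frame(peakTime = runif(n, 1, 59))
      max(abs(averageEventTrajectories(traj, ev)[[1]]$meanX[, 1]))
    }, numeric(1))
  })
  # ~1/sqrt(n): quadrupling n roughly halves the residual amplitude
  expect_lt(shrink[3], shrink[1])
  expect_lt(shrink[3], 3 / sqrt(400) * 3)

  expect_error(averageEventTrajectories(traj, data.frame(peakTime = 0.01)),
               "full windows")
})

test_that("event areal-velocity vectors are antisymmetric under time reversal", {
  ses <- noiseFreeSession()
  traj <- stateTrajectory(ses@groundTruth@latents, fs)
  tt <- ses@groundTruth@submovements$time[3]
  v <- eventArealVelocityVector(traj, tt)
  rev <- stateTrajectory(ses@groundTruth@latents[nrow(traj@x):1, ], fs)
  vRev <- eventArealVelocityVector(rev, (nrow(traj@x) - 1) / fs - tt)
  expect_equal(vRev, -v, tolerance = 1e-6)
  expect_error(eventArealVelocityVector(traj, 0.01), "clipped")
  expect_error(eventArealVelocityVector(circleTrajectory(), 1), "3-component")
})
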