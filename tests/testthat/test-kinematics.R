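test_that("coincident frames give zero kinematics", {
  fem <- makeFemur(seed = 1)
  tib <- makeTibia(seed = 1)
  ## poses chosen so both anatomical frames coincide in the world
  femPose <- rigidIdentity()
  tibPose <- compose(frameTransform(fem$frame),
                     rigidInverse(frameTransform(tib$frame)))
  s <- jointKinematics(fem$frame, tib$frame, femPose, tibPose)
  expect_equal(s$flexion, 0, tolerance = 1e-9)
  expect_equal(s$internalRotation, 0, tolerance = 1e-9)
  expect_equal(s$ap, 0, tolerance = 1e-9)
})

test_that("a pure anterior offset reads as AP translation only", {
  fem <- makeFemur(seed = 1)
  tib <- makeTibia(seed = 1)
  Ff <- frameTransform(fem$frame)
  Ft <- frameTransform(tib$frame)
  joint <- rigidTransform(diag(3), c(3, 0, 0))
  tibPose <- compose(Ff, compose(joint, rigidInverse(Ft)))
  s <- jointKinematics(fem$frame, tib$frame, rigidIdentity(), tibPose)
  expect_equal(s$ap, 3, tolerance = 1e-9)
  expect_equal(s$flexion, 0, tolerance = 1e-9)
  expect_equal(s$adduction, 0, tolerance = 1e-9)
  expect_equal(s$internalRotation, 0, tolerance = 1e-9)
})

test_that("true poses of a squat reproduce the trajectory samples", {
  fem <- makeFemur(seed = 2)
  tib <- makeTibia(seed = 2)
  traj <- squatTrajectory(femur = fem, tibia = tib)
  for (k in c(1, 11, 21, 31)) {
    s <- jointKinematics(fem$frame, tib$frame, traj$femurPoses[[k]],
                         traj$tibiaPoses[[k]])
    expect_equal(s$flexion, traj$frames$flexion[k], tolerance = 1e-6)
    expect_equal(s$ap, traj$frames$ap[k], tolerance = 1e-6)
    expect_equal(s$internalRotation, traj$frames$rotation[k],
                 tolerance = 1e-6)
  }
})

test_that("phase split lands on the flexion apex", {
  f <- c(seq(0, 100, 20), seq(80, 0, -20))
  samples <- data.frame(flexion = f, ap = 0, internalRotation = 0,
                        timestamp = seq_along(f))
  ph <- splitPhases(samples)
  expect_named(ph, c("descent", "ascent"))
  expect_equal(max(ph$descent$flexion), 100)
  expect_equal(ph$descent$flexion[nrow(ph$descent)], 100)
  expect_equal(ph$ascent$flexion[1], 100)
})

test_that("phase split tolerates noise near a triangle-wave apex", {
  set.seed(71)
  for (rep in 1:10) {
    up <- seq(0, 100, by = 5)
    down <- seq(95, 0, by = -5)
    f <- c(up, down) + rnorm(length(up) + length(down), 0, 0.3)
    samples <- data.frame(flexion = f, ap = 0, internalRotation = 0,
                          timestamp = seq_along(f))
    ph <- splitPhases(samples)
    expect_lt(abs(nrow(ph$descent) - length(up)), 2)
  }
})

test_that("monotone flexion gives a single phase with a warning", {
  samples <- data.frame(flexion = seq(0, 90, 10), ap = 0,
                        internalRotation = 0, timestamp = 1:10)
  expect_warning(ph <- splitPhases(samples), "monotone")
  expect_named(ph, "descent")
})

test_that("spline resampling reproduces polynomials up to its degree", {
  f <- seq(0, 100, by = 4)
  for (fn in list(function(x) 2 + 0.3 * x,                 # linear
                  function(x) 1 - 0.02 * x + 3e-4 * x^2,   # quadratic
                  function(x) 0.5 + 1e-5 * x^3 - 0.01 * x)) {  # cubic
    samples <- data.frame(flexion = f, ap = fn(f),
                          internalRotation = fn(f) / 2,
                          timestamp = seq_along(f))
    cu <- smoothResample(samples)
    g <- flexionGrid()
    expect_equal(cu@ap, fn(g), tolerance = 1e-9)
    expect_equal(cu@rotation, fn(g) / 2, tolerance = 1e-9)
  }
})

test_that("spline smoothing of a noisy sinusoid stays within 0.3 mm RMSE", {
  truth <- function(x) 3 - 2.6 * (1 - cos(pi * x / 85)) / 2
  rmse <- vapply(1:15, function(s) {
    set.seed(700 + s)
    t <- seq(0, 4, by = 0.2)  # 5 Hz descent
    f <- 100 * (1 - cos(pi * t / 4)) / 2
    samples <- data.frame(flexion = f,
                          ap = truth(f) + rnorm(length(f), 0, 0.3),
                          internalRotation = 0, timestamp = t)
    cu <- smoothResample(samples)
    sqrt(mean((cu@ap - truth(flexionGrid()))^2))
  }, numeric(1))
  expect_lt(mean(rmse), 0.3)
})

test_that("nodes outside the sampled span are missing, not extrapolated", {
  f <- seq(20, 72, by = 4)
  samples <- data.frame(flexion = f, ap = f * 0.1, internalRotation = 0,
                        timestamp = seq_along(f))
  cu <- smoothResample(samples)
  g <- flexionGrid()
  expect_true(all(is.na(cu@ap[g < 20 | g > 70])))
  expect_true(all(!is.na(cu@ap[g >= 20 & g <= 70])))
})

test_that("fewer than four samples is an insufficient-data error", {
  samples <- data.frame(flexion = c(0, 40, 80), ap = 1:3,
                        internalRotation = 0, timestamp = 1:3)
  expect_error(smoothResample(samples), "at least 4")
})

test_that("curve magnitude is max minus min per channel", {
  g <- flexionGrid()
  cu <- new("KinematicCurve", grid = g, ap = rep(2, 18),
            rotation = seq(0, 17, length.out = 18), phase = "descent",
            subject = "s1", side = "right", condition = "test")
  mag <- curveMagnitude(cu)
  expect_equal(mag$apRange, 0)
  expect_equal(mag$rotationRange, 17)
  cu2 <- new("KinematicCurve", grid = g,
             ap = seq(0, 10, length.out = 18), rotation = rep(1, 18),
             phase = "descent", subject = "s1", side = "right",
             condition = "test")
  expect_equal(curveMagnitude(cu2)$apRange, 10)
})

test_that("all-missing curves cannot yield a magnitude", {
  cu <- new("KinematicCurve", grid = flexionGrid(),
            ap = rep(NA_real_, 18), rotation = rep(NA_real_, 18),
            phase = "descent", subject = "s1", side = "right",
            condition = "test")
  expect_error(curveMagnitude(cu), "non-missing")
})

test_that("the grid is bit-exactly 0 to 85 by 5 in every curve", {
  ds <- simulateCohort(cohortParams(nSubjects = 2), seed = 3)
  for (cu in cohortCurves(ds))
    expect_identical(cu@grid, seq(0, 85, by = 5))
  expect_error(new("KinematicCurve", grid = seq(0, 90, by = 5),
                   ap = rep(0, 19), rotation = rep(0, 19)),
               "grid")
})

test_that("left-knee curves are mirrored to the right-knee convention", {
  cu <- new("KinematicCurve", grid = flexionGrid(), ap = rep(1, 18),
            rotation = rep(5, 18), phase = "descent", subject = "s1",
            side = "left", condition = "ACLD")
  m <- mirrorToRight(cu)
  expect_equal(m@rotation, rep(-5, 18))
  expect_equal(m@ap, cu@ap)
  ## right knees pass through untouched
  cu@side <- "right"
  expect_identical(mirrorToRight(cu), cu)
})

test_that("cohort AP magnitudes sit near the configured 5.2 mm range", {
  ds <- simulateCohort(seed = 8)
  mags <- vapply(cohortCurves(ds, "true"), function(cu)
    curveMagnitude(cu)$apRange, numeric(1))
  expect_equal(mean(mags), 5.2, tolerance = 0.05)
  magsMeasured <- vapply(cohortCurves(ds), function(cu)
    curveMagnitude(cu)$apRange, numeric(1))
  expect_lt(abs(mean(magsMeasured) - 5.2), 1)
})
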