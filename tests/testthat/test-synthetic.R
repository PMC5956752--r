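test_that("bone generation is deterministic per seed with seed-dependent
           tessellation and invariant ground truth", {
  f1 <- makeFemur(seed = 1)
  f1b <- makeFemur(seed = 1)
  f2 <- makeFemur(seed = 2)
  expect_identical(vertices(f1$mesh), vertices(f1b$mesh))
  expect_false(isTRUE(all.equal(vertices(f1$mesh), vertices(f2$mesh))))
  expect_equal(origin(f1$frame), origin(f2$frame))
  expect_equal(axes(f1$frame), axes(f2$frame))
})

test_that("invalid bone parameters are rejected", {
  expect_error(boneParams(condyleRadius = 0), "positive")
  expect_error(boneParams(plateauSemiAP = -3), "positive")
  expect_error(boneParams(fibularHeadLevel = 60), "fibularHeadLevel")
})

test_that("the condylar region of the synthetic femur lies exactly on the
           declared cylinder", {
  fem <- makeFemur(seed = 6)
  fit <- fitCondylarCylinder(fem$mesh)
  expect_lt(abs(fit@radius - fem$params$condyleRadius), 1e-6)
  expect_lt(fit@rmsResidual, 1e-9)
})

test_that("the tibial tangent rectangle equals twice the plateau
           semi-axes", {
  tib <- makeTibia(seed = 6)
  apex <- max(vertices(tib$mesh)[, 2])
  sec <- sliceCrossSection(tib$mesh, apex - 15, axis = c(0, 1, 0))
  post2d <- c(sum(c(-1, 0, 0) * sec$basis[, 1]),
              sum(c(-1, 0, 0) * sec$basis[, 2]))
  rect <- tangentRectangle(sec, post2d / sqrt(sum(post2d^2)))
  expect_equal(rect@depth, 2 * tib$params$plateauSemiAP,
               tolerance = 2 * tib$params$plateauSemiAP * 0.005)
  expect_equal(rect@width, 2 * tib$params$plateauSemiML,
               tolerance = 2 * tib$params$plateauSemiML * 0.005)
})

test_that("zero motion ranges give constant true curves", {
  traj <- squatTrajectory(trajectoryParams(apRange = 0,
                                           rotationRange = 0))
  expect_equal(diff(range(traj$trueCurve@ap)), 0)
  expect_equal(diff(range(traj$trueCurve@rotation)), 0)
})

test_that("condition offsets shift the true curve by a constant at every
           node", {
  base <- squatTrajectory()
  shifted <- squatTrajectory(conditionOffsets = c(ap = 3, rotation = 5))
  expect_equal(shifted$trueCurve@ap - base$trueCurve@ap, rep(3, 18))
  expect_equal(shifted$trueCurve@rotation - base$trueCurve@rotation,
               rep(5, 18))
})

test_that("the configured ranges are attained over the analysis window", {
  traj <- squatTrajectory()
  expect_equal(diff(range(traj$trueCurve@ap)), 5.2, tolerance = 1e-9)
  expect_equal(diff(range(traj$trueCurve@rotation)), 14.9,
               tolerance = 1e-9)
})

test_that("the full pipeline on true poses reproduces the emitted true
           curve", {
  fem <- makeFemur(seed = 3)
  tib <- makeTibia(seed = 3)
  traj <- squatTrajectory(femur = fem, tibia = tib)
  out <- trialKinematics(fem, tib, traj$femurPoses, traj$tibiaPoses,
                         traj$frames$time)
  cu <- out$curves$descent
  expect_lt(max(abs(cu@ap - traj$trueCurve@ap)), 0.2)
  expect_lt(max(abs(cu@rotation - traj$trueCurve@rotation)), 0.3)
})

test_that("cohort simulation is byte-identical under a fixed seed", {
  d1 <- simulateCohort(seed = 4)
  d2 <- simulateCohort(seed = 4)
  expect_identical(cohortCurveTable(d1), cohortCurveTable(d2))
  expect_identical(d1@subjects[["s03"]]$boneParams,
                   d2@subjects[["s03"]]$boneParams)
  expect_error(simulateCohort(cohortParams(nSubjects = 1)),
               "at least 2")
})

test_that("rendered trials have one frame per trajectory sample and flag
           out-of-view bones", {
  fem <- makeFemur(seed = 1)
  tib <- makeTibia(seed = 1)
  cam <- cameraModel(imageSize = 128)
  traj <- squatTrajectory(trajectoryParams(phaseDuration = 1),
                          femur = fem, tibia = tib, camera = cam)
  expect_equal(nrow(traj$frames),
               2 * 1 * trajectoryParams()$frameRate + 1)
  trial <- renderTrial(fem, tib, traj, cam, frames = 1:3)
  expect_length(trial$frames, 3)
  expect_s4_class(trial$frames[[1]]$femur, "SilhouetteImage")
  expect_s4_class(trial$frames[[1]]$tibia, "SilhouetteImage")
  expect_false(trial$frames[[1]]$outOfView)
  ## push the femur far out of the field of view
  trajBad <- traj
  trajBad$femurPoses <- lapply(traj$femurPoses, function(p)
    rigidTransform(rotation(p), translation(p) + c(500, 0, 0)))
  bad <- renderTrial(fem, tib, trajBad, cam, frames = 1)
  expect_true(bad$frames[[1]]$outOfView)
})

test_that("contour noise perturbs silhouettes at the requested scale", {
  fem <- makeFemur(seed = 1)
  cam <- cameraModel(imageSize = 256)
  traj <- squatTrajectory(femur = fem, camera = cam)
  clean <- renderTrial(fem, NULL, traj, cam, frames = 5,
                       bones = "femur")$frames[[1]]$femur
  noisy <- renderTrial(fem, NULL, traj, cam, frames = 5,
                       bones = "femur", contourNoiseSd = 1,
                       seed = 2)$frames[[1]]$femur
  diffPx <- sum(mask(clean) != mask(noisy))
  perim <- nrow(extractContour(clean))
  expect_gt(diffPx / perim, 0.2)   # noise visibly moved the boundary
  expect_lt(diffPx / perim, 3)     # but only by about a pixel
})

test_that("combined rendering is the union of the two bone silhouettes", {
  fem <- makeFemur(seed = 1)
  tib <- makeTibia(seed = 1)
  cam <- cameraModel(imageSize = 128)
  traj <- squatTrajectory(femur = fem, tibia = tib, camera = cam)
  trial <- renderTrial(fem, tib, traj, cam, frames = 10, combined = TRUE)
  fr <- trial$frames[[1]]
  expect_identical(mask(fr$combined),
                   pmax(mask(fr$femur), mask(fr$tibia)))
})
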