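## circle contour fixture
circleContour <- function(r, center = c(0, 0), n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

test_that("silhouette cost is zero for identical contours and errors on
           empty ones", {
  ct <- circleContour(40)
  expect_equal(silhouetteCost(ct, ct, 0.5), 0)
  expect_error(silhouetteCost(ct[0, ], ct, 0.5), "nonempty")
})

test_that("silhouette cost of a slightly shifted circle is 2d/pi", {
  r <- 100; d <- 2
  c0 <- circleContour(r, n = 2000)
  c1 <- circleContour(r, center = c(d, 0), n = 2000)
  ## analytic mean projected distance of a shifted circle, d << r
  expect_equal(silhouetteCost(c0, c1, 1), 2 * d / pi,
               tolerance = 0.05 * 2 * d / pi)
})

test_that("silhouette cost of concentric circles is the radial offset", {
  c0 <- circleContour(100, n = 1500)
  c1 <- circleContour(103, n = 1500)
  expect_equal(silhouetteCost(c0, c1, 1), 3, tolerance = 0.01)
})

## small, fast registration fixture shared by the scenarios below
regFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cam <- cameraModel(imageSize = 256)
      fem <- makeFemur(seed = 1)
      traj <- squatTrajectory(femur = fem, camera = cam)
      cache <<- list(cam = cam, fem = fem, traj = traj)
    }
    cache
  }
})

test_that("registration from the true pose stays at the true pose", {
  fx <- regFixture()
  truePose <- fx$traj$femurPoses[[10]]
  img <- projectSilhouette(fx$fem$mesh, truePose, fx$cam)
  res <- registerFrame(fx$fem$mesh, img, fx$cam, truePose)
  expect_true(converged(res))
  expect_lt(finalCost(res), 0.25)
  tErr <- translation(pose(res)) - translation(truePose)
  expect_lt(max(abs(tErr[1:2])), 0.5)
  expect_lt(rotationAngleError(rotation(pose(res)), rotation(truePose)),
            0.8)
})

test_that("registration recovers a perturbed pose on noise-free frames", {
  fx <- regFixture()
  set.seed(61)
  for (k in c(6, 20)) {
    truePose <- fx$traj$femurPoses[[k]]
    img <- projectSilhouette(fx$fem$mesh, truePose, fx$cam)
    init <- rigidTransform(cardanRotation(runif(3, -5, 5)) %*%
                             rotation(truePose),
                           translation(truePose) + runif(3, -5, 5))
    res <- registerFrame(fx$fem$mesh, img, fx$cam, init)
    expect_true(converged(res))
    tErr <- translation(pose(res)) - translation(truePose)
    expect_lt(sqrt(mean(tErr[1:2]^2)), 0.5)  # 256 px rendering
  }
})

test_that("a grossly wrong initialization is flagged, not silently
           accepted", {
  fx <- regFixture()
  truePose <- fx$traj$femurPoses[[10]]
  img <- projectSilhouette(fx$fem$mesh, truePose, fx$cam)
  bad <- rigidTransform(cardanRotation(c(30, 25, 20)) %*%
                          rotation(truePose),
                        translation(truePose) + c(15, -10, 40))
  res <- registerFrame(fx$fem$mesh, img, fx$cam, bad,
                       control = registrationControl(
                         maxEvaluations = 1500L, retryCost = 0.25))
  rotErr <- rotationAngleError(rotation(pose(res)), rotation(truePose))
  expect_true(!converged(res) || rotErr < 2)
})

test_that("tracking a static pose keeps all frames at that pose", {
  fx <- regFixture()
  truePose <- fx$traj$femurPoses[[10]]
  img <- projectSilhouette(fx$fem$mesh, truePose, fx$cam)
  res <- trackSequence(fx$fem$mesh, rep(list(img), 4), fx$cam, truePose)
  expect_true(all(vapply(res, converged, logical(1))))
  for (r in res) {
    expect_lt(max(abs(translation(pose(r))[1:2] -
                        translation(truePose)[1:2])), 0.5)
  }
})

test_that("a corrupted frame is flagged and the sequence recovers", {
  fx <- regFixture()
  idx <- c(8, 9, 10)
  imgs <- lapply(idx, function(k)
    projectSilhouette(fx$fem$mesh, fx$traj$femurPoses[[k]], fx$cam))
  imgs[[2]] <- silhouetteImage(matrix(0L, 256, 256), fx$cam@pixelPitch)
  res <- trackSequence(fx$fem$mesh, imgs, fx$cam,
                       fx$traj$femurPoses[[idx[1]]])
  expect_true(converged(res[[1]]))
  expect_false(converged(res[[2]]))
  expect_match(res[[2]]@message, "failed")
  expect_true(converged(res[[3]]))
  tErr <- translation(pose(res[[3]])) -
    translation(fx$traj$femurPoses[[idx[3]]])
  expect_lt(max(abs(tErr[1:2])), 0.8)
})

test_that("registration error is invariant under a common in-plane shift
           of principal point and initialization", {
  fx <- regFixture()
  truePose <- fx$traj$femurPoses[[14]]
  img <- projectSilhouette(fx$fem$mesh, truePose, fx$cam)
  set.seed(62)
  pert <- c(runif(2, -3, 3), 0)
  init <- rigidTransform(rotation(truePose), translation(truePose) + pert)
  res1 <- registerFrame(fx$fem$mesh, img, fx$cam, init)
  ## shift the principal point and compensate the world: the bone must
  ## shift by the same in-plane offset for an identical image
  dPx <- c(6, -4)
  cam2 <- cameraModel(imageSize = 256,
                      principalPoint = fx$cam@principalPoint + dPx)
  dObj <- -dPx * fx$cam@pixelPitch * translation(truePose)[3] /
    fx$cam@sourceToDetector
  shift <- rigidTransform(diag(3), c(dObj, 0))
  img2 <- projectSilhouette(fx$fem$mesh, compose(shift, truePose), cam2)
  expect_equal(sum(mask(img2)), sum(mask(img)), tolerance = 0.01)
  res2 <- registerFrame(fx$fem$mesh, img2, cam2, compose(shift, init))
  err1 <- translation(pose(res1))[1:2] - translation(truePose)[1:2]
  err2 <- translation(pose(res2))[1:2] -
    (translation(truePose)[1:2] + dObj)
  expect_lt(max(abs(err1 - err2)), 0.25)
})

test_that("registration tables expose the six degrees of freedom", {
  fx <- regFixture()
  truePose <- fx$traj$femurPoses[[10]]
  img <- projectSilhouette(fx$fem$mesh, truePose, fx$cam)
  res <- trackSequence(fx$fem$mesh, list(img), fx$cam, truePose)
  tab <- registrationTable(res)
  expect_named(tab, c("frame", "tx", "ty", "tz", "r1", "r2", "r3",
                      "cost", "converged"))
  expect_equal(nrow(tab), 1)
  expect_true(is.finite(tab$r1))
})
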