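test_that("an isocentric sphere projects to a disc at SID/SOD magnification", {
  cam <- smallCamera(512)
  sph <- meshSphere(20, nU = 64, nV = 32)
  img <- projectSilhouette(sph, rigidTransform(diag(3), c(0, 0, 800)), cam)
  ct <- extractContour(img)
  mom <- FluoroKin:::contourMoments(ct)
  rExpected <- 20 * (1100 / 800) / cam@pixelPitch
  expect_lt(abs(sqrt(mom$area / pi) - rExpected), 0.5)
})

test_that("in-plane translation shifts the silhouette centroid by the
           magnified pixel distance", {
  cam <- smallCamera(512)
  sph <- meshSphere(20, nU = 64, nV = 32)
  c0 <- FluoroKin:::contourMoments(extractContour(projectSilhouette(
    sph, rigidTransform(diag(3), c(0, 0, 800)), cam)))$centroid
  c1 <- FluoroKin:::contourMoments(extractContour(projectSilhouette(
    sph, rigidTransform(diag(3), c(3, 0, 800)), cam)))$centroid
  expected <- 3 * (1100 / 800) / cam@pixelPitch
  ## the projected sphere outline is slightly elliptical off-axis, so
  ## allow a few percent on top of pixel quantization
  expect_lt(abs((c1[1] - c0[1]) - expected), 0.05 * expected + 0.3)
  expect_lt(abs(c1[2] - c0[2]), 0.3)
})

test_that("translation along the source axis follows the perspective law", {
  cam <- smallCamera(512)
  sph <- meshSphere(20, nU = 64, nV = 32)
  radiusAt <- function(z) {
    mom <- FluoroKin:::contourMoments(extractContour(projectSilhouette(
      sph, rigidTransform(diag(3), c(0, 0, z)), cam)))
    sqrt(mom$area / pi)
  }
  r800 <- radiusAt(800)
  r900 <- radiusAt(900)
  expect_equal(r900 / r800, 800 / 900, tolerance = 0.01)
})

test_that("mesh fully outside the view raises an empty-silhouette error", {
  cam <- smallCamera(128)
  sph <- meshSphere(5, nU = 16, nV = 8)
  expect_error(projectSilhouette(
    sph, rigidTransform(diag(3), c(500, 0, 800)), cam), "outside")
})

test_that("zero-coefficient distortion is the identity", {
  m <- distortionModel(numeric(0), c(256, 256), 256)
  pts <- cbind(runif(50, 0, 512), runif(50, 0, 512))
  expect_identical(applyDistortion(pts, m), pts)
  img <- silhouetteImage(matrix(c(0, 1, 1, 0), 2, 2), 1)
  expect_identical(mask(distortImage(img, m)), mask(img))
})

test_that("a cubic radial model displaces grid nodes by the closed-form
           polynomial", {
  m <- distortionModel(c(0.001, -0.002, 0.008), c(256, 256), 256)
  g <- as.matrix(expand.grid(x = seq(16, 496, 60), y = seq(16, 496, 60)))
  out <- applyDistortion(g, m)
  dx <- g[, 1] - 256; dy <- g[, 2] - 256
  r <- sqrt(dx^2 + dy^2)
  rn <- r / 256
  f <- 1 + 0.001 * rn - 0.002 * rn^2 + 0.008 * rn^3
  expect_equal(out[, 1], 256 + dx * f, tolerance = 1e-12)
  expect_equal(out[, 2], 256 + dy * f, tolerance = 1e-12)
})

test_that("distortion correction inverts the mapping within 0.05 px", {
  m <- distortionModel(c(0, 0.004, 0.008), c(256, 256), 256)
  g <- as.matrix(expand.grid(x = seq(8, 504, 31), y = seq(8, 504, 31)))
  back <- correctDistortion(applyDistortion(g, m), m)
  expect_lt(max(abs(back - g)), 0.05)
})

test_that("grid calibration recovers known coefficients without noise", {
  cam <- smallCamera(512)
  true <- distortionModel(c(0, -0.003, 0.008), cam@principalPoint, 256)
  tgt <- syntheticGridTarget(cam, true, spacingMM = 25)
  cal <- calibrateFromGrid(tgt$detected, tgt$truthMM, cam@principalPoint,
                           nCoef = 3, normRadius = 256)
  expect_lt(max(abs(cal$model@coefficients - true@coefficients)), 1e-6)
  expect_equal(cal$pixelPitch, cam@pixelPitch, tolerance = 1e-8)
  expect_lt(cal$rmsResidual, 1e-6)
})

test_that("calibration under 0.2 px node noise leaves sub-0.3 px
           round-trip residuals", {
  cam <- smallCamera(512)
  true <- distortionModel(c(0, 0, 0.008), cam@principalPoint, 256)
  resids <- vapply(1:20, function(s) {
    set.seed(400 + s)
    tgt <- syntheticGridTarget(cam, true, spacingMM = 25, noiseSD = 0.2)
    cal <- calibrateFromGrid(tgt$detected, tgt$truthMM,
                             cam@principalPoint, nCoef = 3,
                             normRadius = 256)
    ## round trip on the noise-free grid
    clean <- syntheticGridTarget(cam, true, spacingMM = 25)
    corr <- correctDistortion(clean$detected, cal$model)
    ideal <- cbind(clean$truthMM[, 1] / cal$pixelPitch +
                     cam@principalPoint[1],
                   clean$truthMM[, 2] / cal$pixelPitch +
                     cam@principalPoint[2])
    sqrt(mean((corr - ideal)^2))
  }, numeric(1))
  expect_lt(max(resids), 0.3)
})

test_that("underdetermined calibration is an error", {
  expect_error(
    calibrateFromGrid(cbind(1:3, 1:3), cbind(1:3, 1:3), c(0, 0),
                      nCoef = 4),
    "underdetermined")
})

test_that("contour of a rendered disc is circular to sub-pixel spread", {
  cam <- smallCamera(512)
  sph <- meshSphere(20, nU = 96, nV = 48)
  ct <- extractContour(projectSilhouette(
    sph, rigidTransform(diag(3), c(0, 0, 800)), cam))
  mom <- FluoroKin:::contourMoments(ct)
  d <- sqrt(rowSums(sweep(ct, 2, mom$centroid)^2))
  expect_lt(sd(d), 0.5)
  ## counterclockwise in image coordinates (positive shoelace area)
  n <- nrow(ct)
  signedArea <- sum(ct[, 1] * ct[c(2:n, 1), 2] -
                    ct[c(2:n, 1), 1] * ct[, 2]) / 2
  expect_gt(signedArea, 0)
})

test_that("rendering at doubled resolution halves contour
           discretization error", {
  errAt <- function(px) {
    cam <- smallCamera(px)
    sph <- meshSphere(20, nU = 128, nV = 64)
    ct <- extractContour(projectSilhouette(
      sph, rigidTransform(diag(3), c(0, 0, 800)), cam))
    mom <- FluoroKin:::contourMoments(ct)
    d <- sqrt(rowSums(sweep(ct, 2, mom$centroid)^2))
    sd(d) * cam@pixelPitch  # mm
  }
  e256 <- errAt(256)
  e512 <- errAt(512)
  expect_lt(e512 / e256, 0.7)
})

test_that("a single pixel yields a one-pixel contour", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  ct <- extractContour(silhouetteImage(m, 1))
  expect_equal(nrow(ct), 4)  # marching squares diamond around the pixel
  expect_true(all(abs(ct[, 1] - 4.5) <= 0.5 & abs(ct[, 2] - 4.5) <= 0.5))
})

test_that("two disjoint blobs return the largest with a warning", {
  m <- matrix(0L, 32, 32)
  m[4:6, 4:6] <- 1L         # small blob
  m[12:26, 12:26] <- 1L     # large blob
  expect_warning(ct <- extractContour(silhouetteImage(m, 1)),
                 "largest")
  expect_true(all(ct[, 1] > 10 & ct[, 2] > 10))
})

test_that("empty images have no contour", {
  expect_error(extractContour(silhouetteImage(matrix(0L, 8, 8), 1)),
               "empty")
})

test_that("silhouettes survive a PNG round trip", {
  set.seed(50)
  m <- matrix(rbinom(256, 1, 0.3), 16, 16)
  img <- silhouetteImage(m, 0.42, timestamp = 1.2)
  path <- tempfile(fileext = ".png")
  writeSilhouette(img, path)
  back <- readSilhouette(path, 0.42, timestamp = 1.2)
  expect_identical(mask(back), mask(img))
})
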