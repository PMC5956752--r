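test_that("cylinder fit is exact on noise-free cylinder samples", {
  cyl <- meshCylinder(20, c(3, -2, -25), c(6, 1, 25), nTheta = 60)
  fit <- fitCondylarCylinder(regionPoints(cyl, "side"))
  axisTrue <- c(6, 1, 25) - c(3, -2, -25)
  axisTrue <- axisTrue / sqrt(sum(axisTrue^2))
  angErr <- acos(min(1, abs(sum(fit@axisDirection * axisTrue)))) * 180 / pi
  expect_lt(angErr, 1e-6)
  expect_lt(abs(fit@radius - 20), 1e-6)
  expect_lt(fit@rmsResidual, 1e-9)
})

test_that("cylinder fit recovers parameters under 0.1 mm noise", {
  ## generate-and-fit over seeded repeats
  axisTrue <- c(0, 0, 1)
  angErrs <- radErrs <- numeric(20)
  for (s in seq_len(20)) {
    set.seed(200 + s)
    th <- runif(400, 0, 2 * pi)
    z <- runif(400, -25, 25)
    pts <- cbind(20 * cos(th), 20 * sin(th), z) +
      matrix(rnorm(1200, 0, 0.1), ncol = 3)
    fit <- fitCondylarCylinder(pts)
    angErrs[s] <- acos(min(1, abs(fit@axisDirection[3]))) * 180 / pi
    radErrs[s] <- abs(fit@radius - 20)
  }
  expect_lt(max(angErrs), 0.5)
  expect_lt(max(radErrs), 0.2)
})

test_that("collinear points raise a degenerate-fit error", {
  line <- cbind(seq(0, 10, length.out = 30), 0, 0) +
    matrix(0, 30, 3)
  expect_error(fitCondylarCylinder(line), "collinear|degenerate")
  expect_error(fitCondylarCylinder(cbind(1:5, 0, 0)), "at least 20")
})

test_that("femoral frame matches the generator's analytic ground truth", {
  fem <- makeFemur(seed = 7)
  frame <- buildFemoralFrame(fem$mesh)
  expect_lt(frameOriginError(frame, fem$frame), 0.1)
  expect_lt(frameAxisError(frame, fem$frame), 0.1)
})

test_that("femoral frame construction is equivariant under rigid motion", {
  set.seed(31)
  fem <- makeFemur(seed = 3)
  for (i in 1:3) {
    tr <- randomTransform()
    moved <- transformMesh(fem$mesh, tr)
    frame <- buildFemoralFrame(
      moved,
      lateralHint = as.numeric(rotation(tr) %*% c(0, 0, 1)),
      proximalHint = as.numeric(rotation(tr) %*% c(0, 1, 0)))
    expected <- transformFrame(fem$frame, tr)
    expect_lt(frameOriginError(frame, expected), 0.1)
    expect_lt(frameAxisError(frame, expected), 0.1)
  }
})

test_that("mirrored femur still yields a right-handed frame with the
           configured lateral convention", {
  fem <- makeFemur(seed = 5)
  mir <- mirrorMesh(fem$mesh, "z")
  frame <- buildFemoralFrame(mir, lateralHint = c(0, 0, -1))
  ax <- axes(frame)
  expect_equal(det(ax), 1, tolerance = 1e-9)
  expect_lt(sum(ax[, 3] * c(0, 0, 1)), 0)  # Z follows the hint
  expect_gt(sum(ax[, 2] * c(0, 1, 0)), 0.9)  # Y still proximal
})

test_that("tangent rectangle of an axis-aligned square is its bounding box", {
  sq <- as.matrix(expand.grid(x = seq(-1, 1, 0.25), y = seq(-1, 1, 0.25)))
  rect <- tangentRectangle(sq, posteriorDirection = c(0, -1))
  expect_equal(rect@width, 2, tolerance = 1e-12)
  expect_equal(rect@depth, 2, tolerance = 1e-12)
  expect_equal(rect@center2d, c(0, 0), tolerance = 1e-12)
})

test_that("tangent rectangle of an ellipse matches analytic tangents", {
  pts <- ellipsePoints(25, 18)
  rect <- tangentRectangle(pts, posteriorDirection = c(-1, 0))
  expect_equal(rect@depth, 50, tolerance = 50 * 0.005)
  expect_equal(rect@width, 36, tolerance = 36 * 0.005)
})

test_that("tangent rectangle rotates with the section", {
  pts <- ellipsePoints(25, 18, 360)
  rect0 <- tangentRectangle(pts, c(0, -1))
  phi <- 25 * pi / 180
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rect1 <- tangentRectangle(pts %*% t(Rm), as.numeric(Rm %*% c(0, -1)))
  expect_equal(rect1@width, rect0@width, tolerance = 1e-6)
  expect_equal(rect1@depth, rect0@depth, tolerance = 1e-6)
  expect_equal(rect1@center2d, as.numeric(Rm %*% rect0@center2d),
               tolerance = 1e-6)
})

test_that("tangent rectangle is a supporting rectangle: contains every
           point, each edge touching one", {
  set.seed(33)
  pts <- ellipsePoints(22, 15, 200)
  pts <- pts + matrix(rnorm(400, 0, 0.5), ncol = 2)
  rect <- tangentRectangle(pts, c(0.3, -0.95) / sqrt(0.3^2 + 0.95^2))
  e1 <- rect@corners2d[2, ] - rect@corners2d[1, ]
  e2 <- rect@corners2d[4, ] - rect@corners2d[1, ]
  rel <- sweep(pts, 2, rect@corners2d[1, ])
  u <- rel %*% e1 / sum(e1^2)
  v <- rel %*% e2 / sum(e2^2)
  expect_true(all(u >= -1e-9 & u <= 1 + 1e-9))
  expect_true(all(v >= -1e-9 & v <= 1 + 1e-9))
  ## each edge touches at least one point
  expect_lt(min(u), 1e-6); expect_gt(max(u), 1 - 1e-6)
  expect_lt(min(v), 1e-6); expect_gt(max(v), 1 - 1e-6)
})

test_that("collinear sections are rejected", {
  expect_error(tangentRectangle(cbind(1:30, 2 * (1:30)), c(0, -1)),
               "collinear")
})

test_that("tibial frame matches the generator's analytic ground truth", {
  tib <- makeTibia(seed = 9)
  frame <- buildTibialFrame(tib$mesh, fibularLevel = 15)
  expect_lt(frameOriginError(frame, tib$frame), 0.1)
  expect_lt(frameAxisError(frame, tib$frame), 0.1)
})

test_that("tibial frame construction is equivariant under rigid motion", {
  set.seed(35)
  tib <- makeTibia(seed = 2)
  tr <- randomTransform()
  moved <- transformMesh(tib$mesh, tr)
  frame <- buildTibialFrame(
    moved, fibularLevel = 15,
    longAxis = as.numeric(rotation(tr) %*% c(0, 1, 0)),
    posteriorHint = as.numeric(rotation(tr) %*% c(-1, 0, 0)))
  expected <- transformFrame(tib$frame, tr)
  expect_lt(frameOriginError(frame, expected), 0.1)
  expect_lt(frameAxisError(frame, expected), 0.1)
})

test_that("every constructed frame is an exact right-handed triad", {
  fem <- makeFemur(seed = 4)
  tib <- makeTibia(seed = 4)
  for (fr in list(buildFemoralFrame(fem$mesh),
                  buildTibialFrame(tib$mesh, fibularLevel = 15))) {
    ax <- axes(fr)
    expect_lt(abs(sum(ax[, 1] * ax[, 3])), 1e-9)
    expect_lt(sqrt(sum((cross3v(ax[, 1], ax[, 2]) - ax[, 3])^2)), 1e-9)
  }
})
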