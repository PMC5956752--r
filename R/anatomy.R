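#' @include AllClasses.R AllGenerics.R mesh.R
NULL

#' Construct an anatomical frame
#'
#' @param origin 3-vector, mm.
#' @param x,y,z unit axis vectors; must form a right-handed orthonormal
#'   triad.
#' @return An [AnatomicalFrame-class].
#' @export
anatomicalFrame <- function(origin, x, y, z) {
  new("AnatomicalFrame", origin = as.numeric(origin), axes = cbind(x, y, z))
}

#' @rdname accessors
#' @export
setMethod("origin", "AnatomicalFrame", function(object) object@origin)

#' @rdname accessors
#' @export
setMethod("axes", "AnatomicalFrame", function(object) object@axes)

setMethod("show", "AnatomicalFrame", function(object) {
  cat("AnatomicalFrame\n  origin (mm):",
      paste(round(object@origin, 4), collapse = ", "), "\n")
  for (k in 1:3)
    cat(sprintf("  %s-axis: %s\n", c("X", "Y", "Z")[k],
                paste(round(object@axes[, k], 6), collapse = ", ")))
})

#' Rigid transform from anatomical-frame coordinates to mesh coordinates
#'
#' @param frame an [AnatomicalFrame-class].
#' @return A [RigidTransform-class] mapping frame coordinates into the
#'   mesh's coordinates.
#' @export
frameTransform <- function(frame) {
  rigidTransform(frame@axes, frame@origin)
}

#' Transform an anatomical frame by a rigid motion
#' @param frame an [AnatomicalFrame-class].
#' @param transform a [RigidTransform-class].
#' @return The moved [AnatomicalFrame-class].
#' @export
transformFrame <- function(frame, transform) {
  new("AnatomicalFrame",
      origin = transformPoints(transform, frame@origin),
      axes = transform@rotation %*% frame@axes)
}

#' Mirror a mesh across a coordinate plane
#'
#' Used to derive left-knee geometry from the right-knee convention. Face
#' winding is reversed so surface orientation stays consistent.
#'
#' @param mesh a [BoneMesh-class].
#' @param axis which coordinate to negate ("x", "y" or "z").
#' @return The mirrored [BoneMesh-class].
#' @export
mirrorMesh <- function(mesh, axis = "z") {
  k <- match(axis, c("x", "y", "z"))
  v <- mesh@vertices
  v[, k] <- -v[, k]
  boneMesh(v, mesh@faces[, c(1, 3, 2)], mesh@regions)
}

## ---------------------------------------------------------------------------
## condylar cylinder fit
## ---------------------------------------------------------------------------

#' Least-squares cylinder through the femoral condyles
#'
#' Treats the medial and lateral condylar surfaces as a single cylinder and
#' fits it by minimizing orthogonal point-to-surface residuals
#' (Levenberg-Marquardt via \pkg{minpack.lm}, initialized from the
#' principal axis of the selected points).
#'
#' @param x a [BoneMesh-class] or an n x 3 matrix of surface points, mm.
#' @param region region label or vertex indices selecting the condylar
#'   points when `x` is a mesh (default `"condyle"`).
#' @param directionHint optional 3-vector; the fitted axis is flipped to
#'   have positive dot product with it (medial-to-lateral convention).
#' @return A [CylinderFit-class].
#' @examples
#' cyl <- meshCylinder(20, c(0, 0, -25), c(0, 0, 25))
#' fitCondylarCylinder(regionPoints(cyl, "side"))
#' @export
fitCondylarCylinder <- function(x, region = "condyle",
                                directionHint = NULL) {
  pts <- if (is(x, "BoneMesh")) regionPoints(x, region) else as.matrix(x)
  if (nrow(pts) < 20L)
    stop("cylinder fit needs at least 20 points spanning both condyles")
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  sv <- svd(pc, nu = 0)
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1))
    stop("degenerate point set: points are (near-)collinear, cannot fit ",
         "a cylinder")
  resFun <- function(par) {
    th <- par[1]; ph <- par[2]
    d <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    u <- unitize(cross3(d, if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    w <- cross3(d, u)
    a <- ctr + par[3] * u + par[4] * w
    rel <- sweep(pts, 2, a)
    ax <- rel %*% d
    sqrt(rowSums((rel - ax %*% t(d))^2)) - par[5]
  }
  ## a cylinder of length comparable to its diameter has no dominant
  ## principal direction, so try each principal axis as the starting
  ## axis and keep the best-fitting solution
  fits <- lapply(1:3, function(k) {
    d0 <- sv$v[, k]
    perp <- pc - (pc %*% d0) %*% t(d0)
    r0 <- mean(sqrt(rowSums(perp^2)))
    sph0 <- c(acos(max(-1, min(1, d0[3]))), atan2(d0[2], d0[1]))
    minpack.lm::nls.lm(par = c(sph0, 0, 0, r0), fn = resFun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  })
  dev <- vapply(fits, function(f) sum(resFun(f$par)^2), numeric(1))
  p <- fits[[which.min(dev)]]$par
  d <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
  u <- unitize(cross3(d, if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  w <- cross3(d, u)
  a <- ctr + p[3] * u + p[4] * w
  if (!is.null(directionHint) && sum(d * directionHint) < 0) d <- -d
  res <- resFun(p)
  new("CylinderFit", axisPoint = as.numeric(a), axisDirection = as.numeric(d),
      radius = abs(p[5]), rmsResidual = sqrt(mean(res^2)))
}

## ---------------------------------------------------------------------------
## femoral frame
## ---------------------------------------------------------------------------

#' Femoral anatomical frame from the condylar cylinder
#'
#' Z is the condylar cylinder axis (oriented medial to lateral by
#' `lateralHint`); the origin is the midpoint of the axis segment clipped
#' by the bony surfaces; Y is the femoral shaft centerline projected onto
#' the sagittal plane (the plane through the origin perpendicular to Z),
#' oriented proximally; X = Y x Z completes the right-handed triad
#' (anterior for a right knee under the default hints).
#'
#' @param mesh a [BoneMesh-class] femur.
#' @param cylinder a [CylinderFit-class]; fitted from `condyleRegion` when
#'   missing.
#' @param shaftRegion region label or vertex indices of the shaft surface.
#' @param condyleRegion region label for the condylar surface (used only
#'   when `cylinder` is missing).
#' @param lateralHint 3-vector orienting Z medial-to-lateral.
#' @param proximalHint 3-vector orienting the shaft direction proximally.
#' @return An [AnatomicalFrame-class] in mesh coordinates.
#' @export
buildFemoralFrame <- function(mesh, cylinder = NULL, shaftRegion = "shaft",
                              condyleRegion = "condyle",
                              lateralHint = c(0, 0, 1),
                              proximalHint = c(0, 1, 0)) {
  if (is.null(cylinder))
    cylinder <- fitCondylarCylinder(mesh, condyleRegion)
  z <- cylinder@axisDirection
  if (sum(z * lateralHint) < 0) z <- -z
  ts <- lineMeshIntersections(mesh, cylinder@axisPoint, z)
  if (length(ts) < 2L)
    stop("condylar cylinder axis does not intersect the bone surface; ",
         "cannot clip the axis segment")
  orig <- cylinder@axisPoint + (min(ts) + max(ts)) / 2 * z
  shaftPts <- regionPoints(mesh, shaftRegion)
  if (nrow(shaftPts) < 3L) stop("shaft region is empty or too small")
  sc <- sweep(shaftPts, 2, colMeans(shaftPts))
  sdir <- svd(sc, nu = 0)$v[, 1]
  if (sum(sdir * proximalHint) < 0) sdir <- -sdir
  yProj <- sdir - sum(sdir * z) * z
  if (vnorm(yProj) < 1e-9)
    stop("shaft direction is parallel to the condylar axis")
  y <- unitize(yProj)
  x <- cross3(y, z)
  anatomicalFrame(orig, x, y, z)
}

## ---------------------------------------------------------------------------
## tibial plateau rectangle and frame
## ---------------------------------------------------------------------------

#' Tangent rectangle of a tibial cross-section
#'
#' Builds the four supporting lines of the section: the posterior tangent
#' (line 1, perpendicular to `posteriorDirection` and touching the section
#' on its posterior side), the medial and lateral tangents perpendicular to
#' it (lines 2-3), and the anterior tangent (line 4), and returns their
#' enclosing rectangle. Every section point lies inside or on the
#' rectangle, each edge touching at least one point.
#'
#' @param section output of [sliceCrossSection()], or an n x 2 matrix of
#'   in-plane points.
#' @param posteriorDirection unit 2-vector in slice coordinates pointing
#'   posteriorly.
#' @return A [PlateauRectangle-class].
#' @export
tangentRectangle <- function(section, posteriorDirection) {
  if (is.list(section)) {
    pts <- section$points2d
    basis <- section$basis
    planePoint <- section$planePoint
  } else {
    pts <- as.matrix(section)
    basis <- rbind(diag(2), c(0, 0))
    planePoint <- c(0, 0, 0)
  }
  if (nrow(pts) < 3L) stop("need at least 3 section points")
  sv <- svd(sweep(pts, 2, colMeans(pts)), nu = 0)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("degenerate section: points are collinear")
  p <- unitize(as.numeric(posteriorDirection))
  q <- c(-p[2], p[1])  # transverse (medial-lateral) direction
  projP <- as.numeric(pts %*% p)
  projQ <- as.numeric(pts %*% q)
  pMax <- max(projP); pMin <- min(projP)
  qMax <- max(projQ); qMin <- min(projQ)
  corner <- function(a, b) a * p + b * q
  corners <- rbind(corner(pMax, qMin), corner(pMax, qMax),
                   corner(pMin, qMax), corner(pMin, qMin))
  new("PlateauRectangle",
      corners2d = corners,
      center2d = corner((pMax + pMin) / 2, (qMax + qMin) / 2),
      basis = basis, planePoint = as.numeric(planePoint),
      width = qMax - qMin, depth = pMax - pMin)
}

#' Tibial anatomical frame from the plateau tangent rectangle
#'
#' Slices the tibia perpendicular to its long axis at the fibular-head
#' level, builds the tangent rectangle there, translates it along the long
#' axis to the plateau (the mesh's most proximal extent), and embeds the
#' frame: origin at the rectangle midpoint, X along the anteroposterior
#' bisector (anterior), Z along the transverse bisector, Y perpendicular
#' to the X-Z plane (proximal).
#'
#' @param mesh a [BoneMesh-class] tibia.
#' @param rectangle optionally a precomputed [PlateauRectangle-class]; when
#'   missing it is constructed from the slice at `fibularLevel`.
#' @param fibularLevel level of the fibular head, mm below the plateau
#'   apex (per-subject metadata; the fibula itself need not be meshed).
#' @param longAxis unit 3-vector of the tibial long axis, oriented
#'   proximally.
#' @param posteriorHint 3-vector pointing posteriorly (projected into the
#'   slice plane to direct the posterior tangent).
#' @return An [AnatomicalFrame-class] in mesh coordinates.
#' @export
buildTibialFrame <- function(mesh, rectangle = NULL, fibularLevel = 15,
                             longAxis = c(0, 1, 0),
                             posteriorHint = c(-1, 0, 0)) {
  longAxis <- unitize(longAxis)
  apex <- max(mesh@vertices %*% longAxis)
  if (is.null(rectangle)) {
    section <- sliceCrossSection(mesh, apex - fibularLevel, axis = longAxis)
    post2d <- c(sum(posteriorHint * section$basis[, 1]),
                sum(posteriorHint * section$basis[, 2]))
    if (vnorm(post2d) < 1e-9)
      stop("posteriorHint is parallel to the long axis")
    rectangle <- tangentRectangle(section, unitize(post2d))
  }
  ctr3 <- rectangle@planePoint +
    as.numeric(rectangle@basis %*% rectangle@center2d)
  ## translate purely along the long axis up to the plateau level
  orig <- ctr3 + (apex - sum(ctr3 * longAxis)) * longAxis
  postEdge <- rectangle@corners2d[1, ] - rectangle@corners2d[4, ]
  post3 <- as.numeric(rectangle@basis %*% unitize(postEdge))
  x <- -post3  # anterior
  x <- unitize(x - sum(x * longAxis) * longAxis)  # keep exactly in-plane
  y <- longAxis
  z <- cross3(x, y)
  anatomicalFrame(orig, x, y, z)
}
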