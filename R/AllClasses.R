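#' @import methods
NULL

#' Proper rigid motion
#'
#' A rotation plus translation mapping points from one Cartesian frame into
#' another. The rotation slot is a 3x3 orthonormal matrix with determinant
#' +1 (checked to 1e-9 by the validity method); the translation is in mm.
#'
#' @slot rotation 3x3 orthonormal rotation matrix (dimensionless).
#' @slot translation numeric 3-vector, mm.
#' @seealso [rigidTransform()], [compose()], [rigidInverse()],
#'   [transformPoints()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  if (!isOrthonormal(object@rotation))
    return("rotation must be orthonormal with determinant +1 (tol 1e-9)")
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    return("translation must be a finite 3-vector")
  TRUE
})

#' Cardan (Tait-Bryan) angles
#'
#' An ordered triple of rotations about three distinct body-fixed axes.
#' Angles are stored in degrees; the sequence records which axis each angle
#' rotates about (default z-x-y: flexion about the femoral mediolateral
#' axis, then ad/abduction, then internal-external rotation about the
#' tibial long axis).
#'
#' @slot angles numeric 3-vector, degrees, in sequence order.
#' @slot sequence character 3-vector of axis labels, a permutation of
#'   `c("x","y","z")`.
#' @export
setClass("CardanAngles",
  representation(angles = "numeric", sequence = "character"),
  prototype(angles = c(0, 0, 0), sequence = c("z", "x", "y")))

setValidity("CardanAngles", function(object) {
  if (length(object@angles) != 3L || !all(is.finite(object@angles)))
    return("angles must be a finite 3-vector (degrees)")
  if (!identical(sort(object@sequence), c("x", "y", "z")))
    return("sequence must be a permutation of x, y, z")
  TRUE
})

#' Triangulated bone surface mesh
#'
#' Vertices in mm with triangular faces; watertightness is not required.
#' Optional named region labels (integer vertex indices) mark anatomical
#' point selections such as the condylar surface or the shaft.
#'
#' @slot vertices n x 3 numeric matrix, mm.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @slot regions named list of integer vertex-index vectors.
#' @export
setClass("BoneMesh",
  representation(vertices = "matrix", faces = "matrix", regions = "list"),
  prototype(regions = list()))

setValidity("BoneMesh", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 3L || nrow(v) < 4L)
    return("vertices must be an n x 3 numeric matrix with n >= 4")
  if (ncol(object@faces) != 3L)
    return("faces must be an m x 3 index matrix")
  if (nrow(object@faces) > 0L) {
    idx <- range(object@faces)
    if (idx[1] < 1L || idx[2] > nrow(v))
      return("face indices out of range")
  }
  ## require >= 4 non-coplanar vertices
  ctr <- colMeans(v)
  s <- svd(sweep(v, 2, ctr), nu = 0, nv = 0)$d
  if (s[3] <= 1e-9 * max(s[1], 1))
    return("vertices are (near-)coplanar; need >= 4 non-coplanar points")
  TRUE
})

#' Anatomical coordinate system embedded in a bone mesh
#'
#' Origin plus a right-handed orthonormal X/Y/Z triad, expressed in the
#' mesh's own coordinates (mm). For the femur: Z is the condylar cylinder
#' axis (medial to lateral by convention), Y the shaft direction projected
#' onto the sagittal plane (proximal), X = Y x Z (anterior). For the tibia:
#' X is the anteroposterior bisector of the plateau tangent rectangle
#' (anterior), Z its transverse bisector, Y the proximal normal of the
#' plateau plane.
#'
#' @slot origin numeric 3-vector, mm.
#' @slot axes 3x3 matrix whose columns are the X, Y, Z unit axes.
#' @export
setClass("AnatomicalFrame",
  representation(origin = "numeric", axes = "matrix"),
  prototype(origin = c(0, 0, 0), axes = diag(3)))

setValidity("AnatomicalFrame", function(object) {
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    return("origin must be a finite 3-vector")
  if (!isOrthonormal(object@axes))
    return("axes must be orthonormal and right-handed (tol 1e-9)")
  TRUE
})

#' Least-squares cylinder fit
#'
#' @slot axisPoint point on the fitted axis, mm.
#' @slot axisDirection unit 3-vector along the axis.
#' @slot radius cylinder radius, mm (> 0).
#' @slot rmsResidual root-mean-square orthogonal residual, mm.
#' @export
setClass("CylinderFit",
  representation(axisPoint = "numeric", axisDirection = "numeric",
                 radius = "numeric", rmsResidual = "numeric"))

setValidity("CylinderFit", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  if (object@rmsResidual < 0) return("rmsResidual must be >= 0")
  if (abs(vnorm(object@axisDirection) - 1) > 1e-9)
    return("axisDirection must be unit length")
  TRUE
})

#' Tangent rectangle of a tibial plateau cross-section
#'
#' The enclosing rectangle built from four supporting lines of the
#' cross-section: the posterior tangent, two perpendicular medial/lateral
#' tangents, and the anterior tangent. Corners are stored in the 2D slice
#' coordinates together with the 3D basis that lifts them back to mesh
#' coordinates.
#'
#' @slot corners2d 4 x 2 matrix of corner coordinates in the slice plane,
#'   ordered posterior-medial, posterior-lateral, anterior-lateral,
#'   anterior-medial (for the default hints).
#' @slot center2d rectangle midpoint in slice coordinates.
#' @slot basis 3 x 2 matrix of in-plane unit vectors (columns u, v).
#' @slot planePoint 3D point on the slice plane, mm.
#' @slot width extent along the posterior tangent direction's perpendicular, mm.
#' @slot depth extent along the posterior direction (AP), mm.
#' @export
setClass("PlateauRectangle",
  representation(corners2d = "matrix", center2d = "numeric",
                 basis = "matrix", planePoint = "numeric",
                 width = "numeric", depth = "numeric"))

setValidity("PlateauRectangle", function(object) {
  if (!all(dim(object@corners2d) == c(4L, 2L)))
    return("corners2d must be 4 x 2")
  e1 <- object@corners2d[2, ] - object@corners2d[1, ]
  e2 <- object@corners2d[3, ] - object@corners2d[2, ]
  e3 <- object@corners2d[4, ] - object@corners2d[3, ]
  if (abs(sum(e1 * e2)) > 1e-6 * vnorm(e1) * vnorm(e2))
    return("adjacent edges must be perpendicular (tol 1e-6 rad)")
  if (vnorm(e1 + e3) > 1e-6 * vnorm(e1))
    return("opposite edges must be parallel")
  if (object@width <= 0 || object@depth <= 0)
    return("width and depth must be positive")
  TRUE
})

#' Single-plane cone-beam camera geometry
#'
#' X-ray source at the origin looking along +z; the detector plane sits at
#' z = `sourceToDetector` (SID) and the isocenter at z = `sourceToIsocenter`
#' (SOD). Projection magnification at the isocenter is SID/SOD. Pixel
#' coordinates run x in [0, nx], y in [0, ny] with the principal point at
#' the image centre by default.
#'
#' @slot sourceToDetector SID, mm.
#' @slot sourceToIsocenter SOD, mm.
#' @slot pixelPitch detector pixel pitch, mm/px.
#' @slot imageSize integer 2-vector (nx, ny), px.
#' @slot principalPoint numeric 2-vector, px.
#' @export
setClass("CameraModel",
  representation(sourceToDetector = "numeric", sourceToIsocenter = "numeric",
                 pixelPitch = "numeric", imageSize = "integer",
                 principalPoint = "numeric"))

setValidity("CameraModel", function(object) {
  if (object@sourceToDetector <= 0 || object@sourceToIsocenter <= 0 ||
      object@pixelPitch <= 0)
    return("distances and pitch must be positive")
  if (object@sourceToIsocenter >= object@sourceToDetector)
    return("sourceToIsocenter must be < sourceToDetector")
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    return("imageSize must be two positive integers")
  TRUE
})

#' Radial lens/panel distortion model
#'
#' Radial polynomial about the principal point:
#' `r_d = r * (1 + k1*(r/rn) + k2*(r/rn)^2 + k3*(r/rn)^3 + ...)` where
#' `rn` is a normalization radius (px). All-zero coefficients give the
#' identity mapping.
#'
#' @slot coefficients numeric vector k1..kn (dimensionless).
#' @slot center distortion centre, px.
#' @slot normRadius normalization radius, px.
#' @export
setClass("DistortionModel",
  representation(coefficients = "numeric", center = "numeric",
                 normRadius = "numeric"))

setValidity("DistortionModel", function(object) {
  if (object@normRadius <= 0) return("normRadius must be positive")
  if (length(object@center) != 2L) return("center must be a 2-vector (px)")
  TRUE
})

#' Binary fluoroscopic silhouette image
#'
#' @slot mask ny x nx integer matrix (0 background, 1 bone silhouette).
#' @slot pixelPitch mm/px at the detector.
#' @slot timestamp frame time, s.
#' @export
setClass("SilhouetteImage",
  representation(mask = "matrix", pixelPitch = "numeric",
                 timestamp = "numeric"),
  prototype(timestamp = 0))

setValidity("SilhouetteImage", function(object) {
  if (!is.matrix(object@mask)) return("mask must be a matrix")
  if (object@pixelPitch <= 0) return("pixelPitch must be positive")
  TRUE
})

#' Result of a single-frame 2D/3D registration
#'
#' @slot pose recovered [RigidTransform-class] (bone to camera frame).
#' @slot finalCost symmetric mean contour distance at the solution, mm.
#' @slot iterations cost-function evaluations used.
#' @slot converged logical convergence flag.
#' @slot message diagnostic note (e.g. why a frame was flagged).
#' @export
setClass("RegistrationResult",
  representation(pose = "RigidTransform", finalCost = "numeric",
                 iterations = "numeric", converged = "logical",
                 message = "character"),
  prototype(message = ""))

setValidity("RegistrationResult", function(object) {
  if (object@finalCost < 0) return("finalCost must be >= 0")
  TRUE
})

#' Tibiofemoral kinematic curve on the 5-degree flexion grid
#'
#' AP position (mm, anterior positive) and internal rotation (degrees,
#' internal positive) at the 18 flexion nodes 0, 5, ..., 85 degrees.
#' Nodes outside the sampled flexion span are NA (missing), never
#' extrapolated.
#'
#' @slot grid the flexion grid, exactly `seq(0, 85, by = 5)`.
#' @slot ap numeric 18-vector, mm (NA = missing node).
#' @slot rotation numeric 18-vector, degrees (NA = missing node).
#' @slot phase "descent" or "ascent".
#' @slot subject subject identifier.
#' @slot side "right" or "left".
#' @slot condition e.g. "ACLD", "contralateral", "reconstructed".
#' @export
setClass("KinematicCurve",
  representation(grid = "numeric", ap = "numeric", rotation = "numeric",
                 phase = "character", subject = "character",
                 side = "character", condition = "character"),
  prototype(grid = seq(0, 85, by = 5), phase = "descent",
            subject = "s1", side = "right", condition = "unknown"))

setValidity("KinematicCurve", function(object) {
  if (!identical(object@grid, seq(0, 85, by = 5)))
    return("grid must be exactly seq(0, 85, by = 5)")
  if (length(object@ap) != 18L || length(object@rotation) != 18L)
    return("ap and rotation must have one value per grid node")
  if (any(is.infinite(object@ap)) || any(is.infinite(object@rotation)))
    return("curve values must be finite or NA")
  TRUE
})

#' Synthetic cohort dataset with retained ground truth
#'
#' Per-subject, per-condition trials: bone parameters, squat trajectories
#' (world poses), true and measured kinematic curves. Everything a test
#' oracle needs is stored at generation time.
#'
#' @slot subjects named list; each element holds `boneParams`,
#'   `femur`/`tibia` frames, and per-condition trials.
#' @slot params the [cohortParams()] list used.
#' @slot trajectory the [trajectoryParams()] list used.
#' @slot seed integer seed the dataset was generated from.
#' @export
setClass("CohortDataset",
  representation(subjects = "list", params = "list", trajectory = "list",
                 seed = "integer"))
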