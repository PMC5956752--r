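#' @include AllGenerics.R
NULL

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal rotation matrix (determinant +1).
#' @param translation numeric 3-vector, mm.
#' @return A [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Identity rigid transform
#' @return The identity [RigidTransform-class].
#' @export
rigidIdentity <- function() rigidTransform()

#' @describeIn compose rigid-transform composition
#' @export
setMethod("compose", signature("RigidTransform", "RigidTransform"),
  function(a, b) {
    rigidTransform(a@rotation %*% b@rotation,
                   as.numeric(a@rotation %*% b@translation) + a@translation)
  })

#' @describeIn rigidInverse rigid-transform inverse
#' @export
setMethod("rigidInverse", "RigidTransform", function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% transform@translation))
})

#' @describeIn transformPoints apply to an n x 3 matrix or 3-vector
#' @export
setMethod("transformPoints", signature("RigidTransform", "ANY"),
  function(transform, points) {
    if (is.null(dim(points))) {
      stopifnot(length(points) == 3L)
      return(as.numeric(transform@rotation %*% points) + transform@translation)
    }
    stopifnot(ncol(points) == 3L)
    sweep(points %*% t(transform@rotation), 2, -transform@translation)
  })

#' @rdname accessors
#' @export
setMethod("rotation", "RigidTransform", function(object) object@rotation)

#' @rdname accessors
#' @export
setMethod("translation", "RigidTransform", function(object) object@translation)

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation (mm):", paste(round(object@translation, 4),
                                   collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## cardan (Tait-Bryan) angles
## ---------------------------------------------------------------------------

axisIndex <- function(sequence) {
  idx <- match(sequence, c("x", "y", "z"))
  if (anyNA(idx) || length(idx) != 3L || anyDuplicated(idx))
    stop("cardan sequence must be a permutation of x, y, z")
  idx
}

elementaryRotation <- function(axis, angleRad) {
  c_ <- cos(angleRad); s_ <- sin(angleRad)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Rotation matrix from cardan angles
#'
#' Composes three intrinsic elementary rotations
#' `R = R_s1(a1) %*% R_s2(a2) %*% R_s3(a3)` in the stated sequence.
#'
#' @param anglesDeg numeric 3-vector of angles, degrees, in sequence order.
#' @param sequence axis labels, default `c("z","x","y")` (flexion,
#'   ad/abduction, internal-external rotation).
#' @return 3x3 rotation matrix.
#' @export
cardanRotation <- function(anglesDeg, sequence = c("z", "x", "y")) {
  axisIndex(sequence)  # validation
  a <- deg2rad(anglesDeg)
  elementaryRotation(sequence[1], a[1]) %*%
    elementaryRotation(sequence[2], a[2]) %*%
    elementaryRotation(sequence[3], a[3])
}

#' Construct a CardanAngles object
#' @param anglesDeg numeric 3-vector, degrees.
#' @param sequence axis label permutation, default z-x-y.
#' @return A [CardanAngles-class].
#' @export
cardanAngles <- function(anglesDeg, sequence = c("z", "x", "y")) {
  new("CardanAngles", angles = as.numeric(anglesDeg), sequence = sequence)
}

#' @rdname accessors
#' @export
setMethod("angles", "CardanAngles", function(object) object@angles)

#' @rdname accessors
#' @export
setMethod("cardanSequence", "CardanAngles", function(object) object@sequence)

setMethod("show", "CardanAngles", function(object) {
  cat(sprintf("CardanAngles (%s): %s deg\n",
              paste(object@sequence, collapse = "-"),
              paste(round(object@angles, 4), collapse = ", ")))
})

#' Decompose a rigid transform into cardan angles and translation
#'
#' Recovers the three intrinsic rotation angles of the stated sequence such
#' that [cardanRotation()] of the result reproduces the rotation. The
#' decomposition is undefined at gimbal lock (middle angle at +/-90
#' degrees); inputs within the guard band (1e-6 degrees of +/-90) raise an
#' error rather than returning an unstable split.
#'
#' @param transform a [RigidTransform-class] (or a bare 3x3 rotation
#'   matrix).
#' @param sequence axis label permutation, default z-x-y.
#' @param guardDeg gimbal guard band, degrees (default 1e-6).
#' @return A list with elements `angles` (a [CardanAngles-class]) and
#'   `translation` (mm; zero when a bare rotation is supplied).
#' @examples
#' R <- cardanRotation(c(85, 3, -12))
#' cardanDecompose(rigidTransform(R))$angles
#' @export
cardanDecompose <- function(transform, sequence = c("z", "x", "y"),
                            guardDeg = 1e-6) {
  if (is.matrix(transform)) transform <- rigidTransform(transform)
  stopifnot(is(transform, "RigidTransform"))
  validObject(transform)
  R <- transform@rotation
  idx <- axisIndex(sequence)
  i <- idx[1]; j <- idx[2]; k <- idx[3]
  ## +1 when (i, j, k) is a cyclic permutation of (x, y, z)
  eps <- if (((j - i) %% 3L) == 1L) 1 else -1
  sinb <- eps * R[i, k]
  sinb <- max(-1, min(1, sinb))
  b <- asin(sinb)
  if (abs(abs(b) - pi / 2) < deg2rad(guardDeg))
    stop("gimbal lock: middle cardan angle within ", guardDeg,
         " degrees of +/-90; decomposition is degenerate")
  a <- atan2(-eps * R[j, k], R[k, k])
  c_ <- atan2(-eps * R[i, j], R[i, i])
  list(angles = cardanAngles(rad2deg(c(a, b, c_)), sequence),
       translation = transform@translation)
}

#' Relative pose of the tibia in the femoral frame
#'
#' Given world poses of two bones (transforms from bone coordinates to a
#' common world frame), returns the transform expressing the second bone's
#' frame in the first's. The result is invariant to any rigid motion
#' applied jointly to both inputs.
#'
#' @param femurWorld,tibiaWorld [RigidTransform-class] world poses.
#' @return A [RigidTransform-class]: tibia frame in femur frame.
#' @export
relativePose <- function(femurWorld, tibiaWorld) {
  compose(rigidInverse(femurWorld), tibiaWorld)
}

## ---------------------------------------------------------------------------
## JSON serialization
## ---------------------------------------------------------------------------

#' Serialize / restore rigid transforms as JSON
#'
#' Transforms are stored row-major with millimetre translations and a
#' convention field recording the cardan sequence in force.
#'
#' @param transform a [RigidTransform-class].
#' @param path file path; when `NULL`, `transformToJSON` returns the JSON
#'   string.
#' @param sequence cardan sequence recorded in the convention field.
#' @return `transformToJSON`: path or JSON string; `transformFromJSON`: a
#'   [RigidTransform-class].
#' @export
transformToJSON <- function(transform, path = NULL,
                            sequence = c("z", "x", "y")) {
  obj <- list(
    rotation = as.vector(t(transform@rotation)),
    translation = transform@translation,
    units = "mm",
    convention = list(storage = "row-major",
                      cardan_sequence = paste(sequence, collapse = "-")))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transformToJSON
#' @param json JSON string or file path to read.
#' @export
transformFromJSON <- function(json) {
  obj <- jsonlite::fromJSON(json)
  rigidTransform(matrix(obj$rotation, 3, 3, byrow = TRUE),
                 obj$translation)
}
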