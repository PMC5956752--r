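#' @include AllClasses.R
NULL

#' Compose two rigid transforms
#'
#' `compose(a, b)` returns the transform that maps a point first through
#' `b`, then through `a` (matrix convention `a %*% b`).
#'
#' @param a,b [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @examples
#' t1 <- rigidTransform(cardanRotation(c(30, 10, -5)), c(1, 2, 3))
#' compose(t1, rigidInverse(t1))  # identity
#' @export
setGeneric("compose", function(a, b) standardGeneric("compose"))

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param points n x 3 numeric matrix (or length-3 vector), mm.
#' @return Transformed points, same shape as the input.
#' @export
setGeneric("transformPoints",
  function(transform, points) standardGeneric("transformPoints"))

#' Inverse of a rigid transform
#' @param transform a [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
setGeneric("rigidInverse", function(transform) standardGeneric("rigidInverse"))

#' @rdname accessors
#' @export
setGeneric("rotation", function(object) standardGeneric("rotation"))

#' @rdname accessors
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))

#' Accessors for FluoroKin objects
#'
#' Small read-only accessors: `rotation()`/`translation()` for
#' [RigidTransform-class], `origin()`/`axes()` for
#' [AnatomicalFrame-class], `angles()`/`cardanSequence()` for
#' [CardanAngles-class], `mask()` and `pixelPitch()` for
#' [SilhouetteImage-class], `vertices()`/`faces()`/`regions()` for
#' [BoneMesh-class].
#'
#' @param object the object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' @rdname accessors
#' @export
setGeneric("axes", function(object) standardGeneric("axes"))

#' @rdname accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))

#' @rdname accessors
#' @export
setGeneric("cardanSequence", function(object) standardGeneric("cardanSequence"))

#' @rdname accessors
#' @export
setGeneric("mask", function(object) standardGeneric("mask"))

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))

#' @rdname accessors
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("pose", function(object) standardGeneric("pose"))

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("finalCost", function(object) standardGeneric("finalCost"))
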