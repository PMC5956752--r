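#' @include AllClasses.R AllGenerics.R mesh.R
NULL

#' Construct a cone-beam camera model
#'
#' Defaults describe a 17-inch flat-panel detector (431.8 mm square) read
#' out at the given matrix size, with source-to-detector distance (SID)
#' 1100 mm and source-to-isocenter distance (SOD) 800 mm. SID/SOD are rig
#' configuration, not detector properties, and should be set from the
#' calibration of the actual installation.
#'
#' @param sourceToDetector SID, mm.
#' @param sourceToIsocenter SOD, mm.
#' @param imageSize image matrix (nx, ny), px. A single value is used for
#'   both dimensions.
#' @param detectorSize physical detector edge length, mm (default 17 in).
#' @param pixelPitch mm/px; computed from `detectorSize`/`imageSize` when
#'   missing.
#' @param principalPoint px; defaults to the image centre.
#' @return A [CameraModel-class].
#' @export
cameraModel <- function(sourceToDetector = 1100, sourceToIsocenter = 800,
                        imageSize = c(1024L, 1024L), detectorSize = 431.8,
                        pixelPitch = NULL, principalPoint = NULL) {
  if (length(imageSize) == 1L) imageSize <- rep(imageSize, 2L)
  imageSize <- as.integer(imageSize)
  if (is.null(pixelPitch)) pixelPitch <- detectorSize / imageSize[1]
  if (is.null(principalPoint)) principalPoint <- imageSize / 2
  new("CameraModel", sourceToDetector = sourceToDetector,
      sourceToIsocenter = sourceToIsocenter, pixelPitch = pixelPitch,
      imageSize = imageSize, principalPoint = as.numeric(principalPoint))
}

setMethod("show", "CameraModel", function(object) {
  cat(sprintf(paste0("CameraModel: SID %.0f mm, SOD %.0f mm, %d x %d px, ",
                     "pitch %.4f mm/px\n"),
              object@sourceToDetector, object@sourceToIsocenter,
              object@imageSize[1], object@imageSize[2], object@pixelPitch))
})

#' Construct a silhouette image
#' @param mask ny x nx matrix (nonzero = foreground).
#' @param pixelPitch mm/px.
#' @param timestamp frame time, s.
#' @return A [SilhouetteImage-class].
#' @export
silhouetteImage <- function(mask, pixelPitch, timestamp = 0) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  new("SilhouetteImage", mask = m, pixelPitch = pixelPitch,
      timestamp = timestamp)
}

#' @rdname accessors
#' @export
setMethod("mask", "SilhouetteImage", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("pixelPitch", "SilhouetteImage", function(object)
  object@pixelPitch)

setMethod("show", "SilhouetteImage", function(object) {
  cat(sprintf("SilhouetteImage: %d x %d px, pitch %.4f mm/px, %d fg px\n",
              ncol(object@mask), nrow(object@mask), object@pixelPitch,
              sum(object@mask)))
})

#' Project 3D points through the cone-beam geometry
#'
#' Points are in camera coordinates (source at the origin, detector normal
#' along +z). Returns detector pixel coordinates.
#'
#' @param points n x 3 matrix, mm (camera frame).
#' @param camera a [CameraModel-class].
#' @return n x 2 matrix of pixel coordinates.
#' @export
projectPoints <- function(points, camera) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  z <- points[, 3]
  if (any(z <= 1e-6))
    stop("points at or behind the X-ray source cannot be projected")
  s <- camera@sourceToDetector / z
  cbind(points[, 1] * s / camera@pixelPitch + camera@principalPoint[1],
        points[, 2] * s / camera@pixelPitch + camera@principalPoint[2])
}

#' Render the cone-beam silhouette of a mesh
#'
#' Projects every triangle of the posed mesh onto the detector and
#' rasterizes their union into a binary image. Silhouettes are binary by
#' design: registration matches contours, not attenuation.
#'
#' @param mesh a [BoneMesh-class] in bone coordinates.
#' @param pose a [RigidTransform-class] mapping bone to camera
#'   coordinates.
#' @param camera a [CameraModel-class].
#' @param timestamp frame time, s.
#' @return A [SilhouetteImage-class].
#' @export
projectSilhouette <- function(mesh, pose, camera, timestamp = 0) {
  pts <- transformPoints(pose, mesh@vertices)
  px <- projectPoints(pts, camera)
  m <- cppRasterizeTriangles(px, mesh@faces, camera@imageSize[1],
                             camera@imageSize[2])
  if (sum(m) == 0L)
    stop("mesh projects entirely outside the field of view: ",
         "empty silhouette")
  silhouetteImage(m, camera@pixelPitch, timestamp)
}

#' Extract the outer silhouette contour
#'
#' Marching-squares iso-0.5 boundary of the binary silhouette, returned as
#' ordered subpixel positions, counterclockwise (in the image's x-right,
#' y-down pixel convention, counterclockwise means positive shoelace
#' area). When the silhouette has several connected components the largest
#' loop is returned with a warning.
#'
#' @param image a [SilhouetteImage-class] or binary matrix.
#' @return n x 2 matrix of (x, y) pixel coordinates.
#' @export
extractContour <- function(image) {
  m <- if (is(image, "SilhouetteImage")) image@mask else
    matrix(as.integer(image != 0), nrow(image), ncol(image))
  if (sum(m) == 0L) stop("empty silhouette: no contour to extract")
  loops <- cppMarchingSquares(m)
  if (length(loops) == 0L) stop("no contour found")
  areas <- vapply(loops, function(L) {
    n <- nrow(L)
    abs(sum(L[, 1] * L[c(2:n, 1), 2] - L[c(2:n, 1), 1] * L[, 2])) / 2
  }, numeric(1))
  if (length(loops) > 1L) {
    big <- sum(areas > 2)  # ignore sub-pixel speckle loops
    if (big > 1L)
      warning("silhouette has ", big, " boundary loops; ",
              "returning the largest component")
  }
  L <- loops[[which.max(areas)]]
  n <- nrow(L)
  signedArea <- sum(L[, 1] * L[c(2:n, 1), 2] - L[c(2:n, 1), 1] * L[, 2]) / 2
  if (signedArea < 0) L <- L[n:1, , drop = FALSE]
  colnames(L) <- c("x", "y")
  L
}

#' Contour centroid and enclosed area
#' @param contour n x 2 matrix of ordered contour points.
#' @return list(centroid = 2-vector, area = scalar), pixel units.
#' @keywords internal
contourMoments <- function(contour) {
  x <- contour[, 1]; y <- contour[, 2]
  n <- length(x)
  x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(list(centroid = colMeans(contour), area = 0))
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  list(centroid = c(cx, cy), area = abs(a))
}

#' Read and write silhouette images
#'
#' Silhouettes are stored as 8-bit grayscale PNG (or TIFF when the
#' \pkg{tiff} package is available); any nonzero pixel is foreground.
#'
#' @param image a [SilhouetteImage-class].
#' @param path file path ending in `.png` or `.tif`/`.tiff`.
#' @param pixelPitch mm/px to attach on read.
#' @param timestamp frame time to attach on read, s.
#' @return `readSilhouette` returns a [SilhouetteImage-class].
#' @name silhouette-io
NULL

#' @rdname silhouette-io
#' @export
writeSilhouette <- function(image, path) {
  arr <- image@mask * 1.0
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is needed to write TIFF images")
    tiff::writeTIFF(arr, path)
  } else {
    png::writePNG(arr, path)
  }
  invisible(path)
}

#' @rdname silhouette-io
#' @export
readSilhouette <- function(path, pixelPitch, timestamp = 0) {
  arr <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is needed to read TIFF images")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  silhouetteImage(arr > 0.5, pixelPitch, timestamp)
}
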