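#' @include AllClasses.R camera.R
NULL

#' Construct a radial distortion model
#'
#' Flat-panel detectors are nearly distortion free, so the default model is
#' the identity; image-intensifier data can supply pincushion/barrel
#' coefficients. The mapping is
#' `r_d = r * (1 + sum_i k_i (r/rn)^i)` about `center`.
#'
#' @param coefficients numeric vector `k1..kn` (all zero = identity).
#' @param center distortion centre, px.
#' @param normRadius normalization radius `rn`, px.
#' @return A [DistortionModel-class].
#' @export
distortionModel <- function(coefficients = numeric(0),
                            center = c(512, 512),
                            normRadius = 512) {
  new("DistortionModel", coefficients = as.numeric(coefficients),
      center = as.numeric(center), normRadius = normRadius)
}

setMethod("show", "DistortionModel", function(object) {
  if (length(object@coefficients) == 0 || all(object@coefficients == 0)) {
    cat("DistortionModel: identity\n")
  } else {
    cat("DistortionModel: k =",
        paste(signif(object@coefficients, 4), collapse = ", "),
        " (rn =", object@normRadius, "px)\n")
  }
})

radialFactor <- function(r, model) {
  if (length(model@coefficients) == 0) return(rep(1, length(r)))
  rn <- r / model@normRadius
  f <- rep(1, length(r))
  p <- rn
  for (k in model@coefficients) {
    f <- f + k * p
    p <- p * rn
  }
  f
}

#' Apply radial distortion to points
#'
#' @param points n x 2 matrix of pixel coordinates (ideal).
#' @param model a [DistortionModel-class].
#' @return n x 2 matrix of distorted pixel coordinates.
#' @export
applyDistortion <- function(points, model) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  dx <- points[, 1] - model@center[1]
  dy <- points[, 2] - model@center[2]
  f <- radialFactor(sqrt(dx^2 + dy^2), model)
  cbind(model@center[1] + dx * f, model@center[2] + dy * f)
}

#' Undistort points (numeric inverse of the radial map)
#'
#' Inverts the radial polynomial per point with Newton iterations on the
#' radius; converges to well below 0.05 px for mild distortion.
#'
#' @param points n x 2 matrix of distorted pixel coordinates.
#' @param model a [DistortionModel-class].
#' @param iterations Newton iterations (default 8).
#' @return n x 2 matrix of corrected (ideal) pixel coordinates.
#' @export
correctDistortion <- function(points, model, iterations = 8L) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  if (length(model@coefficients) == 0) return(points)
  dx <- points[, 1] - model@center[1]
  dy <- points[, 2] - model@center[2]
  rd <- sqrt(dx^2 + dy^2)
  r <- rd  # initial guess
  h <- 1e-4
  for (it in seq_len(iterations)) {
    fr <- r * radialFactor(r, model) - rd
    dfr <- ((r + h) * radialFactor(r + h, model) -
            (r - h) * radialFactor(r - h, model)) / (2 * h)
    r <- pmax(0, r - fr / dfr)
  }
  scale <- ifelse(rd > 1e-12, r / rd, 1)
  cbind(model@center[1] + dx * scale, model@center[2] + dy * scale)
}

#' Distort or correct a whole image
#'
#' `distortImage` resamples an ideal image onto the distorted grid (what a
#' real intensifier would record); `correctImage` inverts that, producing
#' the distortion-corrected image registration runs on. Nearest-neighbour
#' sampling, adequate for binary silhouettes.
#'
#' @param image a [SilhouetteImage-class].
#' @param model a [DistortionModel-class].
#' @return A [SilhouetteImage-class].
#' @export
distortImage <- function(image, model) {
  resampleImage(image, model, inverseMap = TRUE)
}

#' @rdname distortImage
#' @export
correctImage <- function(image, model) {
  resampleImage(image, model, inverseMap = FALSE)
}

resampleImage <- function(image, model, inverseMap) {
  if (length(model@coefficients) == 0) return(image)
  m <- image@mask
  ny <- nrow(m); nx <- ncol(m)
  gx <- rep(seq_len(nx) - 0.5, each = ny)
  gy <- rep(seq_len(ny) - 0.5, times = nx)
  src <- if (inverseMap) correctDistortion(cbind(gx, gy), model)
         else applyDistortion(cbind(gx, gy), model)
  sj <- floor(src[, 1]) + 1L  # pixel column containing x
  si <- floor(src[, 2]) + 1L
  ok <- sj >= 1L & sj <= nx & si >= 1L & si <= ny
  out <- matrix(0L, ny, nx)
  out[cbind(((seq_along(gx) - 1L) %% ny) + 1L,
            ((seq_along(gx) - 1L) %/% ny) + 1L)[ok, , drop = FALSE]] <-
    m[cbind(si[ok], sj[ok])]
  silhouetteImage(out, image@pixelPitch, image@timestamp)
}

#' Calibrate distortion and pixel pitch from a grid target
#'
#' Least-squares fit of the radial distortion coefficients and the
#' detector pixel pitch from detected grid-target nodes and their true
#' physical positions. The distortion centre is taken at the supplied
#' principal point (grid targets constrain the radial profile well but the
#' centre poorly at mild distortion).
#'
#' @param detectedNodes n x 2 matrix of detected node positions, px.
#' @param trueGrid n x 2 matrix of true node positions on the target, mm
#'   (origin at the ray through the principal point).
#' @param center principal point, px.
#' @param nCoef number of radial coefficients to fit (default 3, a cubic
#'   radial model).
#' @param normRadius normalization radius, px.
#' @return list(model = [DistortionModel-class], pixelPitch = mm/px,
#'   rmsResidual = px).
#' @export
calibrateFromGrid <- function(detectedNodes, trueGrid, center,
                              nCoef = 3L, normRadius = NULL) {
  detectedNodes <- as.matrix(detectedNodes)
  trueGrid <- as.matrix(trueGrid)
  stopifnot(nrow(detectedNodes) == nrow(trueGrid))
  if (nrow(detectedNodes) < nCoef + 3L)
    stop("underdetermined calibration: need at least ", nCoef + 3L,
         " nodes for ", nCoef, " radial coefficients plus pitch")
  if (is.null(normRadius)) normRadius <- max(abs(center)) %||% 512
  rMM <- sqrt(rowSums(trueGrid^2))
  rPX <- sqrt(rowSums(sweep(detectedNodes, 2, center)^2))
  ## rank check: nodes must span a range of radii
  if (stats::sd(rMM) < 1e-9)
    stop("rank-deficient calibration design: nodes at a single radius")
  pitch0 <- stats::median(rMM[rMM > 1e-9] / rPX[rMM > 1e-9])
  resFun <- function(par) {
    pitch <- par[1]
    mdl <- distortionModel(par[-1], center, normRadius)
    ideal <- cbind(trueGrid[, 1] / pitch + center[1],
                   trueGrid[, 2] / pitch + center[2])
    pred <- applyDistortion(ideal, mdl)
    as.numeric(pred - detectedNodes)
  }
  fit <- minpack.lm::nls.lm(par = c(pitch0, rep(0, nCoef)), fn = resFun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  res <- resFun(fit$par)
  list(model = distortionModel(fit$par[-1], center, normRadius),
       pixelPitch = fit$par[1],
       rmsResidual = sqrt(mean(res^2)))
}

#' Synthetic calibration grid target
#'
#' Regular grid of nodes on the detector with known physical spacing,
#' projected through a known distortion, optionally with detection noise.
#' Used to exercise [calibrateFromGrid()].
#'
#' @param camera a [CameraModel-class].
#' @param model the true [DistortionModel-class].
#' @param spacingMM physical node spacing, mm.
#' @param noiseSD node detection noise, px.
#' @param margin fraction of the half-field to leave free at the border.
#' @return list(detected = n x 2 px, truthMM = n x 2 mm).
#' @export
syntheticGridTarget <- function(camera, model, spacingMM = 20,
                                noiseSD = 0, margin = 0.05) {
  half <- camera@imageSize * camera@pixelPitch / 2 * (1 - margin)
  xs <- seq(-half[1], half[1], by = spacingMM)
  ys <- seq(-half[2], half[2], by = spacingMM)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  ideal <- cbind(g[, 1] / camera@pixelPitch + camera@principalPoint[1],
                 g[, 2] / camera@pixelPitch + camera@principalPoint[2])
  det <- applyDistortion(ideal, model)
  if (noiseSD > 0)
    det <- det + matrix(stats::rnorm(length(det), 0, noiseSD), ncol = 2)
  list(detected = det, truthMM = g)
}
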