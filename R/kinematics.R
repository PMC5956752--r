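#' @include AllClasses.R AllGenerics.R geometry.R anatomy.R
NULL

#' The 5-degree flexion grid
#' @return `seq(0, 85, by = 5)` — the 18 analysis nodes, degrees.
#' @export
flexionGrid <- function() seq(0, 85, by = 5)

#' Joint kinematics of one frame
#'
#' Expresses the tibial anatomical frame in the femoral anatomical frame
#' and decomposes it with the configured cardan sequence: flexion is the
#' first angle (about the femoral mediolateral axis), internal rotation
#' the third (about the tibial long axis), and the AP position is the
#' X-component (femoral anteroposterior axis) of the tibial origin in the
#' femoral frame.
#'
#' @param femurFrame,tibiaFrame [AnatomicalFrame-class] objects in their
#'   respective bone coordinates.
#' @param femurPose,tibiaPose [RigidTransform-class] world poses of the
#'   two bones.
#' @param sequence cardan sequence (default z-x-y).
#' @param timestamp frame time, s.
#' @return data.frame row: flexion (deg), adduction (deg),
#'   internalRotation (deg), ap (mm), timestamp.
#' @export
jointKinematics <- function(femurFrame, tibiaFrame, femurPose, tibiaPose,
                            sequence = c("z", "x", "y"), timestamp = 0) {
  femWorld <- compose(femurPose, frameTransform(femurFrame))
  tibWorld <- compose(tibiaPose, frameTransform(tibiaFrame))
  rel <- relativePose(femWorld, tibWorld)
  dec <- cardanDecompose(rel, sequence)
  a <- angles(dec$angles)
  data.frame(flexion = a[1], adduction = a[2], internalRotation = a[3],
             ap = dec$translation[1], timestamp = timestamp)
}

#' Split a squat cycle into descent and ascent phases
#'
#' Splits the time-ordered samples at the flexion maximum. Small flexion
#' reversals (below `hysteresisDeg`) around the apex are ignored. A
#' monotone recording is returned as a single phase with a warning.
#'
#' @param samples data.frame with at least `flexion`, time ordered (as
#'   from [jointKinematics()]).
#' @param hysteresisDeg reversals smaller than this are not treated as a
#'   phase change (default 2).
#' @return Named list of data.frames: `descent` (start to apex) and
#'   `ascent` (apex to end); `ascent` is absent for monotone input.
#' @export
splitPhases <- function(samples, hysteresisDeg = 2) {
  stopifnot(nrow(samples) >= 3L)
  f <- samples$flexion
  apex <- which.max(f)
  n <- length(f)
  if (apex == n || max(f[apex] - f[apex:n]) < hysteresisDeg) {
    warning("flexion is monotone (no descent/ascent apex); ",
            "returning a single phase")
    return(list(descent = samples))
  }
  if (apex == 1L || max(f[apex] - f[1:apex]) < hysteresisDeg) {
    warning("flexion is monotone decreasing; returning a single phase")
    return(list(descent = samples))
  }
  list(descent = samples[seq_len(apex), , drop = FALSE],
       ascent = samples[apex:n, , drop = FALSE])
}

#' B-spline smoothing and 5-degree resampling of one phase
#'
#' Fits a least-squares cubic B-spline of AP position and internal
#' rotation as functions of flexion and evaluates it on the 5-degree grid
#' 0-85. Nodes outside the sampled flexion span are NA (missing), never
#' extrapolated. The spline basis reproduces polynomials up to its degree
#' exactly.
#'
#' @param samples data.frame of one phase with columns `flexion`, `ap`,
#'   `internalRotation` (as from [jointKinematics()]).
#' @param knotSpacing interior knot spacing, degrees of flexion
#'   (default 15).
#' @param phase label for the returned curve.
#' @param subject,side,condition trial metadata carried into the curve.
#' @return A [KinematicCurve-class].
#' @export
smoothResample <- function(samples, knotSpacing = 15, phase = "descent",
                           subject = "s1", side = "right",
                           condition = "unknown") {
  if (nrow(samples) < 4L)
    stop("insufficient data: B-spline smoothing needs at least 4 samples")
  f <- samples$flexion
  span <- range(f)
  if (diff(span) < 1e-6) stop("flexion span is degenerate")
  inner <- seq(span[1] + knotSpacing, span[2] - knotSpacing / 2,
               by = knotSpacing)
  ## keep the fit overdetermined: at most n - 5 interior knots
  while (length(inner) + 4L > nrow(samples) - 1L && length(inner) > 0L)
    inner <- inner[-length(inner)]
  grid <- flexionGrid()
  inside <- grid >= span[1] - 1e-9 & grid <= span[2] + 1e-9
  fitChan <- function(y) {
    basis <- splines::bs(f, knots = inner, degree = 3, intercept = TRUE,
                         Boundary.knots = span)
    co <- stats::lm.fit(basis, y)$coefficients
    co[is.na(co)] <- 0
    pred <- rep(NA_real_, length(grid))
    if (any(inside)) {
      pb <- splines::bs(grid[inside], knots = inner, degree = 3,
                        intercept = TRUE, Boundary.knots = span)
      pred[inside] <- as.numeric(pb %*% co)
    }
    pred
  }
  new("KinematicCurve", grid = grid, ap = fitChan(samples$ap),
      rotation = fitChan(samples$internalRotation),
      phase = phase, subject = as.character(subject),
      side = side, condition = as.character(condition))
}

#' Range (max - min) of a kinematic curve
#'
#' The curve magnitude reported per trial: the range from minimum to
#' maximum AP position (mm) and rotational position (degrees) over the
#' non-missing grid nodes.
#'
#' @param curve a [KinematicCurve-class].
#' @return list(apRange = mm, rotationRange = degrees).
#' @export
curveMagnitude <- function(curve) {
  okA <- !is.na(curve@ap)
  okR <- !is.na(curve@rotation)
  if (sum(okA) < 2L || sum(okR) < 2L)
    stop("curve magnitude needs at least 2 non-missing nodes per channel")
  list(apRange = max(curve@ap[okA]) - min(curve@ap[okA]),
       rotationRange = max(curve@rotation[okR]) - min(curve@rotation[okR]))
}

setMethod("show", "KinematicCurve", function(object) {
  cat(sprintf("KinematicCurve: %s / %s / %s / %s phase, %d of 18 nodes\n",
              object@subject, object@side, object@condition, object@phase,
              sum(!is.na(object@ap))))
})

#' Tidy a set of kinematic curves
#'
#' @param curves list of [KinematicCurve-class] objects.
#' @return Long data.frame: subject, side, condition, phase, flexion,
#'   ap_mm, rot_deg.
#' @export
curvesToTable <- function(curves) {
  do.call(rbind, lapply(curves, function(cu) {
    data.frame(subject = cu@subject, side = cu@side,
               condition = cu@condition, phase = cu@phase,
               flexion = cu@grid, ap_mm = cu@ap, rot_deg = cu@rotation)
  }))
}

#' Mirror a curve to the right-knee sign convention
#'
#' Left knees are mirrored before pooling so that internal rotation is
#' sign-consistent across sides; AP translation is unaffected.
#'
#' @param curve a [KinematicCurve-class].
#' @return The curve with rotation negated when `side == "left"`, side
#'   relabelled "right (mirrored)".
#' @export
mirrorToRight <- function(curve) {
  if (!identical(curve@side, "left")) return(curve)
  new("KinematicCurve", grid = curve@grid, ap = curve@ap,
      rotation = -curve@rotation, phase = curve@phase,
      subject = curve@subject, side = "right (mirrored)",
      condition = curve@condition)
}
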