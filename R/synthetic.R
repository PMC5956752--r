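#' @include AllClasses.R mesh.R anatomy.R camera.R distortion.R geometry.R
#' @include kinematics.R
NULL

#' Parametric bone parameters
#'
#' Geometry of the synthetic femur and tibia. The femoral condyles lie
#' exactly on a cylinder of the given radius; the tibial cross-section at
#' the fibular-head level is exactly the given ellipse, so the anatomical
#' frame constructions have closed-form ground truth. Dimensions are
#' typical adult values (mm).
#'
#' @param condyleRadius femoral condylar cylinder radius.
#' @param condyleWidthMedial,condyleWidthLateral extents of the condylar
#'   cylinder on the medial (-Z) and lateral (+Z) side of its midplane.
#' @param femurShaftRadius,femurShaftLength femoral shaft cylinder.
#' @param femurShaftDirection shaft direction (unit vector, mostly
#'   proximal +Y with a slight posterior/lateral tilt).
#' @param plateauSemiAP,plateauSemiML tibial plateau ellipse semi-axes
#'   (anteroposterior, mediolateral).
#' @param plateauDepth depth of the elliptical metaphysis below the
#'   plateau.
#' @param tibiaShaftRadius,tibiaShaftLength tibial shaft cylinder.
#' @param fibularHeadLevel level of the fibular head below the plateau
#'   apex (the tibial frame's slice level).
#' @return Named list of validated parameters.
#' @export
boneParams <- function(condyleRadius = 21, condyleWidthMedial = 24,
                       condyleWidthLateral = 26, femurShaftRadius = 14,
                       femurShaftLength = 150,
                       femurShaftDirection = c(-0.06, 0.99, 0.08),
                       plateauSemiAP = 24, plateauSemiML = 35,
                       plateauDepth = 45, tibiaShaftRadius = 12,
                       tibiaShaftLength = 150, fibularHeadLevel = 15) {
  p <- list(condyleRadius = condyleRadius,
            condyleWidthMedial = condyleWidthMedial,
            condyleWidthLateral = condyleWidthLateral,
            femurShaftRadius = femurShaftRadius,
            femurShaftLength = femurShaftLength,
            femurShaftDirection = unitize(femurShaftDirection),
            plateauSemiAP = plateauSemiAP, plateauSemiML = plateauSemiML,
            plateauDepth = plateauDepth,
            tibiaShaftRadius = tibiaShaftRadius,
            tibiaShaftLength = tibiaShaftLength,
            fibularHeadLevel = fibularHeadLevel)
  scalars <- p[setdiff(names(p), "femurShaftDirection")]
  if (any(unlist(scalars) <= 0))
    stop("all bone dimensions must be positive")
  if (p$fibularHeadLevel >= p$plateauDepth)
    stop("fibularHeadLevel must lie within the elliptical metaphysis ",
         "(< plateauDepth)")
  p
}

#' Scale the linear dimensions of bone parameters
#' @param params a [boneParams()] list.
#' @param factor linear scale factor.
#' @return The scaled parameter list.
#' @keywords internal
scaleBoneParams <- function(params, factor) {
  for (nm in setdiff(names(params), "femurShaftDirection"))
    params[[nm]] <- params[[nm]] * factor
  params
}

#' Synthetic parametric femur
#'
#' Canonical (right-knee) frame: X anterior, Y proximal, Z
#' medial-to-lateral, origin at the condylar-axis midpoint between the
#' medial and lateral surfaces. The condylar region lies exactly on the
#' specified cylinder. The seed only rotates the tessellation phase (the
#' surface, frame and fit are unchanged).
#'
#' @param params a [boneParams()] list.
#' @param seed integer tessellation seed.
#' @param nTheta angular tessellation of the condylar cylinder.
#' @return list(mesh = [BoneMesh-class] with regions `condyle` and
#'   `shaft`, frame = ground-truth [AnatomicalFrame-class], params).
#' @export
makeFemur <- function(params = boneParams(), seed = 1L, nTheta = 96L) {
  set.seed(stageSeed(seed, "femur"))
  phase <- stats::runif(1, 0, 2 * pi)
  uDir <- c(cos(phase), sin(phase), 0)
  wMed <- params$condyleWidthMedial
  wLat <- params$condyleWidthLateral
  condyle <- meshCylinder(params$condyleRadius, c(0, 0, -wMed),
                          c(0, 0, wLat), nTheta = nTheta, nLen = 6L,
                          uDir = uDir)
  d <- params$femurShaftDirection
  start <- c(0, params$condyleRadius * 0.4, 0)
  shaft <- meshCylinder(params$femurShaftRadius, start,
                        start + params$femurShaftLength * d,
                        nTheta = 48L, nLen = 10L)
  flange <- meshBox(c(params$condyleRadius * 0.85,
                      params$condyleRadius * 0.4, 2),
                    c(14, 34, 0.9 * (wMed + wLat)))
  mesh <- mergeMeshes(condyle, shaft, flange)
  regs <- mesh@regions
  mesh <- boneMesh(mesh@vertices, mesh@faces,
                   list(condyle = regs[["part1.side"]],
                        shaft = regs[["part2.side"]]))
  originZ <- (wLat - wMed) / 2
  yTruth <- unitize(c(d[1], d[2], 0))
  frame <- anatomicalFrame(c(0, 0, originZ),
                           cross3(yTruth, c(0, 0, 1)), yTruth, c(0, 0, 1))
  list(mesh = mesh, frame = frame, params = params)
}

#' Synthetic parametric tibia
#'
#' Canonical (right-knee) frame: origin at the plateau centre, X
#' anterior, Y proximal (the long axis), Z lateral. The cross-section at
#' the fibular-head level is exactly the plateau ellipse, so the tangent
#' rectangle is analytically 2 x the semi-axes.
#'
#' @inheritParams makeFemur
#' @return list(mesh = [BoneMesh-class] with region `plateau`, frame =
#'   ground-truth [AnatomicalFrame-class], params).
#' @export
makeTibia <- function(params = boneParams(), seed = 1L, nTheta = 96L) {
  set.seed(stageSeed(seed, "tibia"))
  phase <- stats::runif(1, 0, 2 * pi)
  uDir <- c(cos(phase), 0, sin(phase))
  meta <- meshCylinder(c(params$plateauSemiAP, params$plateauSemiML),
                       c(0, -params$plateauDepth, 0), c(0, 0, 0),
                       nTheta = nTheta, nLen = 8L, uDir = c(1, 0, 0))
  s0 <- c(0, -params$plateauDepth + 10, 0)
  shaft <- meshCylinder(params$tibiaShaftRadius, s0,
                        s0 + c(0, -params$tibiaShaftLength, 0),
                        nTheta = 48L, nLen = 10L, uDir = uDir)
  mesh <- mergeMeshes(meta, shaft)
  regs <- mesh@regions
  mesh <- boneMesh(mesh@vertices, mesh@faces,
                   list(plateau = regs[["part1.side"]]))
  frame <- anatomicalFrame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  list(mesh = mesh, frame = frame, params = params)
}

#' Squat trajectory parameters
#'
#' Defaults emulate the study conditions: squats flex to about 100
#' degrees at 5 Hz imaging, tibial AP translation range about 5.2 mm and
#' internal rotation range about 14.9 degrees over the analyzed 0-85
#' degree window.
#'
#' @param flexionPeak peak knee flexion, degrees.
#' @param apRange AP translation range over the 0-85 degree window, mm.
#' @param rotationRange internal-rotation range over the window, degrees.
#' @param phaseDuration duration of each phase (descent, ascent), s.
#' @param frameRate imaging rate, Hz.
#' @param apStart AP position at full extension, mm (anterior positive).
#' @param rotationStart internal rotation at full extension, degrees.
#' @return Named list of validated parameters.
#' @export
trajectoryParams <- function(flexionPeak = 100, apRange = 5.2,
                             rotationRange = 14.9, phaseDuration = 4,
                             frameRate = 5, apStart = 3,
                             rotationStart = -5) {
  stopifnot(flexionPeak > 0, apRange >= 0, rotationRange >= 0,
            phaseDuration > 0, frameRate > 0)
  list(flexionPeak = flexionPeak, apRange = apRange,
       rotationRange = rotationRange, phaseDuration = phaseDuration,
       frameRate = frameRate, apStart = apStart,
       rotationStart = rotationStart)
}

## smooth 0->1 profile over the analyzed flexion window
flexionProfile <- function(flexDeg, windowDeg = 85) {
  (1 - cos(pi * flexDeg / windowDeg)) / 2
}

#' Ground-truth squat trajectory
#'
#' Generates time-stamped world poses of femur and tibia over one squat
#' cycle (extension to peak flexion and back) plus the true kinematic
#' curve on the 5-degree grid. Flexion follows a raised-cosine profile;
#' AP position decreases and internal rotation increases smoothly with
#' flexion, reaching the configured ranges over the 0-85 degree window;
#' condition offsets shift AP and rotation by a constant at all flexion
#' angles. The femur leans with half the knee flexion in the image plane
#' and drifts a few millimetres over the cycle, as a squatting knee does
#' in the fluoroscope's field.
#'
#' @param traj a [trajectoryParams()] list.
#' @param conditionOffsets numeric: `ap` (mm, anterior) and `rotation`
#'   (degrees, internal) added at all flexion angles.
#' @param femur,tibia outputs of [makeFemur()] / [makeTibia()] (their
#'   frames place the joint).
#' @param camera a [CameraModel-class]; the knee is centred near its
#'   isocenter.
#' @param sequence cardan sequence used to compose the joint rotation.
#' @return list with `frames` (data.frame: frame, time, flexion, ap,
#'   rotation), `femurPoses`, `tibiaPoses` (lists of
#'   [RigidTransform-class]), and `trueCurve` (a
#'   [KinematicCurve-class]).
#' @export
squatTrajectory <- function(traj = trajectoryParams(),
                            conditionOffsets = c(ap = 0, rotation = 0),
                            femur = makeFemur(), tibia = makeTibia(),
                            camera = cameraModel(),
                            sequence = c("z", "x", "y")) {
  tEnd <- 2 * traj$phaseDuration
  times <- seq(0, tEnd, by = 1 / traj$frameRate)
  flex <- traj$flexionPeak * (1 - cos(2 * pi * times / tEnd)) / 2
  apOf <- function(f) traj$apStart + conditionOffsets[["ap"]] -
    traj$apRange * flexionProfile(f)
  rotOf <- function(f) traj$rotationStart + conditionOffsets[["rotation"]] +
    traj$rotationRange * flexionProfile(f)
  Ff <- frameTransform(femur$frame)
  Ft <- frameTransform(tibia$frame)
  FtInv <- rigidInverse(Ft)
  iso <- c(0, 0, camera@sourceToIsocenter)
  R0 <- cardanRotation(c(4, 3, -2), sequence)
  femurPoses <- vector("list", length(times))
  tibiaPoses <- vector("list", length(times))
  for (k in seq_along(times)) {
    f <- flex[k]
    lean <- f / 2
    s <- f / traj$flexionPeak
    drift <- c(8 * s, -5 * s, 12 * s)
    Rw <- elementaryRotation("z", deg2rad(-lean)) %*% R0
    Wf <- rigidTransform(Rw, iso + drift)
    Tj <- rigidTransform(cardanRotation(c(f, 0, rotOf(f)), sequence),
                         c(apOf(f), -25, 0))
    femurPoses[[k]] <- Wf
    tibiaPoses[[k]] <- compose(Wf, compose(Ff, compose(Tj, FtInv)))
  }
  grid <- flexionGrid()
  trueCurve <- new("KinematicCurve", grid = grid, ap = apOf(grid),
                   rotation = rotOf(grid), phase = "descent",
                   subject = "truth", side = "right",
                   condition = "truth")
  list(frames = data.frame(frame = seq_along(times), time = times,
                           flexion = flex, ap = apOf(flex),
                           rotation = rotOf(flex)),
       femurPoses = femurPoses, tibiaPoses = tibiaPoses,
       trueCurve = trueCurve, sequence = sequence)
}

#' Cohort simulation parameters
#'
#' Defaults emulate the study design: 10 subjects, each measured in three
#' conditions (ACL-deficient, contralateral, reconstructed), with the
#' ACLD knee shifted anteriorly and internally rotated at all flexion
#' angles and the reconstructed knee slightly overcorrected posteriorly.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param acldAP,acldRotation ACLD offsets vs contralateral (mm anterior,
#'   degrees internal).
#' @param reconAP,reconRotation residual offsets of the reconstructed
#'   knee vs contralateral.
#' @param subjectSdAP,subjectSdRotation between-subject SD of the AP and
#'   rotation baselines.
#' @param nodeSdAP,nodeSdRotation measurement noise SD per curve node
#'   (emulates per-frame registration error after smoothing).
#' @param boneScaleSd between-subject SD of the linear bone scale factor.
#' @return Named list of validated parameters.
#' @export
cohortParams <- function(nSubjects = 10L, acldAP = 3, acldRotation = 5,
                         reconAP = -0.8, reconRotation = 0.5,
                         subjectSdAP = 2.5, subjectSdRotation = 3,
                         nodeSdAP = 0.5, nodeSdRotation = 0.7,
                         boneScaleSd = 0.04) {
  if (nSubjects < 2L) stop("cohort needs at least 2 subjects")
  stopifnot(subjectSdAP >= 0, subjectSdRotation >= 0, nodeSdAP >= 0,
            nodeSdRotation >= 0, boneScaleSd >= 0)
  list(nSubjects = as.integer(nSubjects), acldAP = acldAP,
       acldRotation = acldRotation, reconAP = reconAP,
       reconRotation = reconRotation, subjectSdAP = subjectSdAP,
       subjectSdRotation = subjectSdRotation, nodeSdAP = nodeSdAP,
       nodeSdRotation = nodeSdRotation, boneScaleSd = boneScaleSd)
}

#' Simulate a three-condition cohort with known ground truth
#'
#' Per subject: bone dimensions drawn around the default parametric
#' bones, per-subject AP/rotation baselines, and one trial per condition
#' (contralateral, ACLD, reconstructed) with the condition's constant
#' offsets. True curves come from the trajectory generator; measured
#' curves add independent per-node noise emulating smoothed measurement
#' error. Meshes are not built here (see [makeFemur()] and
#' [renderTrial()] for imaging experiments); everything needed as a test
#' oracle — parameters, offsets, true curves — is retained.
#'
#' @param cohort a [cohortParams()] list.
#' @param traj a [trajectoryParams()] list.
#' @param seed integer seed; fixed seed gives an identical dataset.
#' @return A [CohortDataset-class].
#' @export
simulateCohort <- function(cohort = cohortParams(),
                           traj = trajectoryParams(), seed = 1L) {
  set.seed(stageSeed(seed, "cohort"))
  grid <- flexionGrid()
  conds <- list(
    contralateral = c(ap = 0, rotation = 0),
    ACLD = c(ap = cohort$acldAP, rotation = cohort$acldRotation),
    reconstructed = c(ap = cohort$reconAP, rotation = cohort$reconRotation))
  subjects <- vector("list", cohort$nSubjects)
  names(subjects) <- sprintf("s%02d", seq_len(cohort$nSubjects))
  for (si in seq_len(cohort$nSubjects)) {
    scale <- max(0.7, 1 + stats::rnorm(1, 0, cohort$boneScaleSd))
    bp <- scaleBoneParams(boneParams(), scale)
    apBase <- stats::rnorm(1, 0, cohort$subjectSdAP)
    rotBase <- stats::rnorm(1, 0, cohort$subjectSdRotation)
    trialList <- list()
    for (cn in names(conds)) {
      off <- conds[[cn]] + c(ap = apBase, rotation = rotBase)
      subjTraj <- traj
      subjTraj$apStart <- traj$apStart + off[["ap"]]
      subjTraj$rotationStart <- traj$rotationStart + off[["rotation"]]
      trueAP <- subjTraj$apStart - traj$apRange * flexionProfile(grid)
      trueRot <- subjTraj$rotationStart +
        traj$rotationRange * flexionProfile(grid)
      subj <- names(subjects)[si]
      trueCurve <- new("KinematicCurve", grid = grid, ap = trueAP,
                       rotation = trueRot, phase = "descent",
                       subject = subj, side = "right", condition = cn)
      measured <- new("KinematicCurve", grid = grid,
                      ap = trueAP + stats::rnorm(length(grid), 0,
                                                 cohort$nodeSdAP),
                      rotation = trueRot +
                        stats::rnorm(length(grid), 0,
                                     cohort$nodeSdRotation),
                      phase = "descent", subject = subj, side = "right",
                      condition = cn)
      trialList[[cn]] <- list(offsets = conds[[cn]],
                              trajectoryParams = subjTraj,
                              trueCurve = trueCurve, measured = measured)
    }
    subjects[[si]] <- list(boneParams = bp, boneScale = scale,
                           apBaseline = apBase, rotationBaseline = rotBase,
                           trials = trialList)
  }
  new("CohortDataset", subjects = subjects, params = cohort,
      trajectory = traj, seed = as.integer(seed))
}

setMethod("show", "CohortDataset", function(object) {
  cat(sprintf("CohortDataset: %d subjects x %d conditions (seed %d)\n",
              length(object@subjects),
              length(object@subjects[[1]]$trials), object@seed))
})

#' Measured curves of a cohort as a list or tidy table
#'
#' @param dataset a [CohortDataset-class].
#' @param what `"measured"` (default) or `"true"` curves.
#' @return `cohortCurves`: list of [KinematicCurve-class];
#'   `cohortCurveTable`: long data.frame via [curvesToTable()].
#' @export
cohortCurves <- function(dataset, what = c("measured", "true")) {
  what <- match.arg(what)
  key <- if (what == "measured") "measured" else "trueCurve"
  out <- list()
  for (s in dataset@subjects)
    for (tr in s$trials)
      out[[length(out) + 1L]] <- tr[[key]]
  out
}

#' @rdname cohortCurves
#' @export
cohortCurveTable <- function(dataset, what = c("measured", "true")) {
  curvesToTable(cohortCurves(dataset, what))
}

## ---------------------------------------------------------------------------
## silhouette rendering of a trial
## ---------------------------------------------------------------------------

## displace contour points along their local outward normal
perturbContour <- function(contour, sdPx) {
  n <- nrow(contour)
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  tx <- contour[nxt, 1] - contour[prv, 1]
  ty <- contour[nxt, 2] - contour[prv, 2]
  len <- pmax(sqrt(tx^2 + ty^2), 1e-9)
  nxv <- ty / len
  nyv <- -tx / len
  d <- stats::rnorm(n, 0, sdPx)
  cbind(contour[, 1] + d * nxv, contour[, 2] + d * nyv)
}

#' Render the fluoroscopic frames of a trial
#'
#' One binary silhouette per bone per frame at the configured rate and
#' size, optionally degraded with Gaussian normal-direction contour noise
#' (plus the pixel quantization of re-rasterization) and a radial
#' distortion, as an image intensifier would record. Per-bone images are
#' the default (registration matches one bone model at a time); a
#' combined two-bone image with occlusion can be requested for stress
#' tests.
#'
#' @param femur,tibia outputs of [makeFemur()] / [makeTibia()].
#' @param trajectory output of [squatTrajectory()].
#' @param camera a [CameraModel-class].
#' @param distortion optional [DistortionModel-class] applied to the
#'   recorded images.
#' @param contourNoiseSd Gaussian contour perturbation, px (0 = off).
#' @param seed noise seed.
#' @param frames which frame indices to render (default all).
#' @param bones character subset of c("femur", "tibia").
#' @param combined also return the union image of both bones.
#' @return list with `frames`: per rendered frame a list(femur =, tibia =,
#'   combined = [SilhouetteImage-class] or NULL, frame, time, outOfView
#'   flag), plus `truth` (the trajectory) and the rendering settings.
#' @export
renderTrial <- function(femur, tibia, trajectory, camera = cameraModel(),
                        distortion = NULL, contourNoiseSd = 0, seed = 1L,
                        frames = NULL, bones = c("femur", "tibia"),
                        combined = FALSE) {
  set.seed(stageSeed(seed, "render"))
  idx <- frames %||% trajectory$frames$frame
  out <- vector("list", length(idx))
  degrade <- function(img) {
    if (contourNoiseSd > 0) {
      ct <- extractContour(img)
      noisy <- perturbContour(ct, contourNoiseSd)
      m <- cppRasterizePolygon(noisy, camera@imageSize[1],
                               camera@imageSize[2])
      img <- silhouetteImage(m, img@pixelPitch, img@timestamp)
    }
    if (!is.null(distortion)) img <- distortImage(img, distortion)
    img
  }
  for (k in seq_along(idx)) {
    fr <- idx[k]
    t <- trajectory$frames$time[fr]
    rec <- list(frame = fr, time = t, femur = NULL, tibia = NULL,
                combined = NULL, outOfView = FALSE)
    renderBone <- function(mesh, poseList) {
      tryCatch(degrade(projectSilhouette(mesh, poseList[[fr]], camera,
                                         timestamp = t)),
               error = function(e) NULL)
    }
    if ("femur" %in% bones)
      rec$femur <- renderBone(femur$mesh, trajectory$femurPoses)
    if ("tibia" %in% bones)
      rec$tibia <- renderBone(tibia$mesh, trajectory$tibiaPoses)
    rec$outOfView <- ("femur" %in% bones && is.null(rec$femur)) ||
      ("tibia" %in% bones && is.null(rec$tibia))
    if (combined && !is.null(rec$femur) && !is.null(rec$tibia)) {
      m <- pmax(rec$femur@mask, rec$tibia@mask)
      rec$combined <- silhouetteImage(m, camera@pixelPitch, t)
    }
    out[[k]] <- rec
  }
  list(frames = out, truth = trajectory, camera = camera,
       distortion = distortion, contourNoiseSd = contourNoiseSd,
       seed = seed)
}
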