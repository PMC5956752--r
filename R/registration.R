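#' @include AllClasses.R AllGenerics.R camera.R geometry.R
NULL

#' @rdname accessors
#' @export
setMethod("pose", "RegistrationResult", function(object) object@pose)

#' @rdname accessors
#' @export
setMethod("converged", "RegistrationResult", function(object)
  object@converged)

#' @rdname accessors
#' @export
setMethod("finalCost", "RegistrationResult", function(object)
  object@finalCost)

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf(paste0("RegistrationResult: cost %.4f mm, %d evaluations, ",
                     "converged: %s%s\n"),
              object@finalCost, as.integer(object@iterations),
              object@converged,
              if (nzchar(object@message)) paste0(" (", object@message, ")")
              else ""))
})

#' Symmetric mean contour distance
#'
#' The registration cost: mean over each contour's points of the distance
#' to the nearest point of the other contour, averaged over both
#' directions, scaled to millimetres at the detector. Zero iff the
#' contours coincide up to sampling.
#'
#' @param modelContour,imageContour n x 2 matrices of contour points, px.
#' @param pitch detector pixel pitch, mm/px.
#' @return Scalar cost, mm.
#' @export
silhouetteCost <- function(modelContour, imageContour, pitch) {
  if (is.null(modelContour) || nrow(modelContour) == 0L ||
      is.null(imageContour) || nrow(imageContour) == 0L)
    stop("silhouetteCost requires two nonempty contours")
  cppSymmetricContourDist(modelContour, imageContour) * pitch
}

#' Registration control parameters
#'
#' @param maxEvaluations cost-evaluation budget per frame (default 6000).
#' @param maxCost final cost (mm) above which a frame is flagged as not
#'   converged (basin-of-attraction failure guard).
#' @param parscale Nelder-Mead parameter scales for
#'   (tx, ty, tz, rx, ry, rz) in (mm, mm, mm, deg, deg, deg).
#' @param prealign run the mask-centroid / area pre-alignment before the
#'   local search.
#' @param polish run the pattern-search polish after the simplex stages.
#' @param retryCost final contour cost (mm) above which the staged search
#'   is re-run from rotation-jittered starts (set near the expected cost
#'   floor: about 0.15 for noise-free silhouettes, about 1.0 with 1 px
#'   contour noise).
#' @return A named list of control values.
#' @export
registrationControl <- function(maxEvaluations = 6000L, maxCost = 2.0,
                                parscale = c(2, 2, 6, 1, 1, 1),
                                prealign = TRUE, polish = TRUE,
                                retryCost = 0.15) {
  list(maxEvaluations = as.integer(maxEvaluations), maxCost = maxCost,
       parscale = parscale, prealign = prealign, polish = polish,
       retryCost = retryCost)
}

## pose update: cardan-angle increments about the current bone origin
perturbPose <- function(pose, par) {
  Rinc <- cardanRotation(par[4:6])
  rigidTransform(Rinc %*% pose@rotation, pose@translation + par[1:3])
}

#' Register a bone model to one fluoroscopic silhouette
#'
#' Iteratively adjusts the 6-DOF pose of the bone model until its
#' projected silhouette matches the image silhouette. The pose is
#' parameterized as translation plus cardan-angle increments about the
#' current pose, which keeps the search well-conditioned at large squat
#' flexion angles.
#'
#' The search minimizes the pixelwise symmetric-difference area of the
#' two silhouettes (equivalent, up to the perimeter scale, to the mean
#' contour offset, and free of the wrong-correspondence local minima a
#' nearest-neighbour contour metric exhibits), proceeding in stages: a
#' centroid pre-alignment; an in-plane simplex search; a depth reset from
#' the area magnification law; a small multistart over the out-of-plane
#' rotations; simplex refinement; and a cyclic pattern-search polish.
#' The reported `finalCost` is the symmetric mean contour distance
#' ([silhouetteCost()]) at the solution.
#'
#' Single-plane geometry determines in-plane translation and rotations
#' well but source-axis (out-of-plane) translation only weakly; consumers
#' should report out-of-plane error separately.
#'
#' @param mesh the [BoneMesh-class] to register.
#' @param image observed [SilhouetteImage-class].
#' @param camera the [CameraModel-class].
#' @param initial initial [RigidTransform-class] pose guess.
#' @param control a [registrationControl()] list.
#' @return A [RegistrationResult-class]. Non-convergence within the
#'   budget is flagged, not raised.
#' @export
registerFrame <- function(mesh, image, camera, initial,
                          control = registrationControl()) {
  validObject(initial)
  if (sum(image@mask) == 0L)
    stop("empty silhouette image: nothing to register")
  ## coarse-to-fine pyramid: global stages run at half resolution (which
  ## also smooths the cost surface), precision stages at full resolution
  cam1 <- camera
  cam2 <- cameraModel(sourceToDetector = camera@sourceToDetector,
                      sourceToIsocenter = camera@sourceToIsocenter,
                      imageSize = pmax(camera@imageSize %/% 2L, 1L),
                      pixelPitch = camera@pixelPitch * 2,
                      principalPoint = camera@principalPoint / 2)
  masks <- list(image@mask, downsampleMask(image@mask))
  cams <- list(cam1, cam2)
  moms <- lapply(masks, cppMaskMoments)
  if (moms[[2]][3] == 0) stop("silhouette lost at coarse resolution")
  evalCount <- 0L
  penalty <- .Machine$double.xmax / 4
  renderMask <- function(p, lvl) {
    cam <- cams[[lvl]]
    pts <- transformPoints(p, mesh@vertices)
    if (any(pts[, 3] <= 1)) return(NULL)
    px <- projectPoints(pts, cam)
    m <- cppRasterizeTriangles(px, mesh@faces, cam@imageSize[1],
                               cam@imageSize[2])
    if (sum(m) == 0L) return(NULL)
    m
  }
  ## in-plane shift from mask centroids; depth from the area
  ## magnification law (only once the orientation is approximately right,
  ## since rotation also changes silhouette area)
  prealign <- function(p, lvl, fitDepth = TRUE) {
    m <- renderMask(p, lvl)
    if (is.null(m)) return(p)
    mm <- cppMaskMoments(m)
    if (mm[3] == 0) return(p)
    cam <- cams[[lvl]]
    z <- p@translation[3]
    zNew <- if (fitDepth) {
      min(max(z * sqrt(mm[3] / moms[[lvl]][3]), z - 30), z + 30)
    } else z
    dPix <- moms[[lvl]][1:2] - mm[1:2]
    dObj <- dPix * cam@pixelPitch * z / cam@sourceToDetector
    rigidTransform(p@rotation, p@translation + c(dObj, zNew - z))
  }
  imageContourCache <- NULL
  silhouetteCostOf <- function(p) {
    tryCatch({
      if (is.null(imageContourCache))
        imageContourCache <<- suppressWarnings(extractContour(image))
      m <- renderMask(p, 1L)
      if (is.null(m)) Inf
      else silhouetteCost(
        suppressWarnings(extractContour(silhouetteImage(m,
                                                        cam1@pixelPitch))),
        imageContourCache, cam1@pixelPitch)
    }, error = function(e) Inf)
  }
  budget <- control$maxEvaluations
  runSearch <- function(jitter) {
    pose0 <- prealign(perturbPose(initial, jitter), 2L, fitDepth = FALSE)
    lvl <- 2L
    costFun <- function(par) {
      evalCount <<- evalCount + 1L
      m <- renderMask(perturbPose(pose0, par), lvl)
      if (is.null(m)) return(penalty)
      cppMaskMismatch(m, masks[[lvl]])
    }
    ## joint (depth, out-of-plane rotations) cost with the in-plane
    ## centroid alignment folded into each evaluation: follows the curved
    ## valley these degrees of freedom form
    valleyCost <- function(par3) {
      p <- perturbPose(pose0, c(0, 0, par3[1], 0, par3[2], par3[3]))
      p <- prealign(p, lvl, fitDepth = FALSE)
      evalCount <<- evalCount + 1L
      m <- renderMask(p, lvl)
      if (is.null(m)) return(penalty)
      cppMaskMismatch(m, masks[[lvl]])
    }
    valleyStage <- function(zGrid, maxit2 = 40) {
      evalAtZ <- function(dz) {
        o2 <- stats::optim(c(0, 0), function(p2)
          valleyCost(c(dz, p2[1], p2[2])), method = "Nelder-Mead",
          control = list(maxit = maxit2, reltol = 1e-5,
                         parscale = c(1, 1)))
        list(par = c(dz, o2$par), value = o2$value)
      }
      cands <- lapply(zGrid, evalAtZ)
      vals <- vapply(cands, `[[`, numeric(1), "value")
      bestC <- cands[[which.min(vals)]]
      ov <- stats::optim(bestC$par, valleyCost, method = "Nelder-Mead",
                         control = list(maxit = 60, reltol = 1e-6,
                                        parscale = c(2, 0.6, 0.6)))
      if (ov$value > bestC$value) ov <- bestC
      pose0 <<- prealign(perturbPose(pose0, c(0, 0, ov$par[1], 0,
                                              ov$par[2], ov$par[3])),
                         lvl, fitDepth = FALSE)
      ov
    }
    refine <- function(maxit, scale) {
      o <- stats::optim(rep(0, 6), costFun, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-7,
                                       parscale = control$parscale * scale))
      pose0 <<- perturbPose(pose0, o$par)
      o
    }
    ## ---- coarse level: global search -------------------------------
    ## in-plane degrees of freedom first (x, y, in-plane rotation)
    inPlane <- function(par3) costFun(c(par3[1], par3[2], 0, 0, 0,
                                        par3[3]))
    o <- stats::optim(c(0, 0, 0), inPlane, method = "Nelder-Mead",
                      control = list(maxit = 120, reltol = 1e-6,
                                     parscale = control$parscale[c(1, 2,
                                                                   4)]))
    pose0 <- perturbPose(pose0, c(o$par[1], o$par[2], 0, 0, 0, o$par[3]))
    pose0 <- prealign(pose0, lvl, fitDepth = TRUE)
    ## multistart over the out-of-plane rotations, the only degrees of
    ## freedom prone to secondary basins
    starts <- as.matrix(expand.grid(r2 = c(-4, 0, 4), r3 = c(-4, 0, 4)))
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      s0 <- c(0, 0, 0, 0, starts[k, 1], starts[k, 2])
      o <- stats::optim(s0, costFun, method = "Nelder-Mead",
                        control = list(maxit = 80, reltol = 1e-5,
                                       parscale = control$parscale * 0.4))
      if (is.null(best) || o$value < best$value) best <- o
      if (evalCount >= budget) break
    }
    pose0 <- perturbPose(pose0, best$par)
    valleyStage(seq(-12, 12, by = 4))
    opt <- refine(150, 0.2)
    ## single-plane mirror check: a silhouette is nearly invariant to
    ## reversing the out-of-plane tilt (the near/far mirror ambiguity),
    ## so evaluate the depth-reflected rotation explicitly and keep the
    ## better basin
    S <- diag(c(1, 1, -1))
    savePose <- pose0
    saveVal <- opt$value
    pose0 <- prealign(rigidTransform(S %*% pose0@rotation %*% S,
                                     pose0@translation),
                      lvl, fitDepth = TRUE)
    valleyStage(seq(-8, 8, by = 4))
    om <- refine(120, 0.2)
    if (om$value >= saveVal) {
      pose0 <- savePose
    }
    ## ---- fine level: precision -------------------------------------
    ## alternate full-pose refinement with valley passes: the residual
    ## error after each simplex run lies mostly along the (depth,
    ## out-of-plane) valley, which the scan re-centres
    lvl <- 1L
    pose0 <- prealign(pose0, lvl, fitDepth = FALSE)
    opt <- refine(200, 0.15)
    valleyStage(seq(-4, 4, by = 2))
    opt <- refine(150, 0.08)
    valleyStage(seq(-2, 2, by = 1))
    opt <- refine(150, 0.04)
    ## pattern-search polish: cyclic coordinate descent with shrinking
    ## steps resolves the last fraction of a pixel a collapsing simplex
    ## leaves behind
    if (isTRUE(control$polish)) {
      par <- rep(0, 6)
      fBest <- costFun(par)
      step <- c(0.3, 0.3, 1.0, 0.15, 0.15, 0.15)
      for (round in 1:5) {
        improved <- FALSE
        for (d in 1:6) {
          for (sgn in c(1, -1)) {
            cand <- par
            cand[d] <- cand[d] + sgn * step[d]
            fC <- costFun(cand)
            if (fC < fBest - 1e-9) {
              par <- cand
              fBest <- fC
              improved <- TRUE
            }
          }
        }
        if (!improved) step <- step / 2
        if (evalCount >= budget) break
      }
      if (fBest <= opt$value) {
        pose0 <- perturbPose(pose0, par)
        opt <- list(par = par, value = fBest)
      }
    }
    list(pose = pose0, xor = opt$value)
  }
  ## cost-triggered retries: the noise-free global optimum sits at a
  ## near-zero contour cost, so a high final cost flags a secondary
  ## basin; re-running the staged search from rotation-jittered starts
  ## recovers such frames
  jitters <- list(rep(0, 6),
                  c(0, 0, 0, 0, 3, 3), c(0, 0, 0, 0, -3, -3),
                  c(0, 0, 0, 0, 3, -3), c(0, 0, 0, 0, -3, 3),
                  c(0, 0, 0, 3, 0, 0), c(0, 0, 0, -3, 0, 0))
  sol <- NULL
  for (j in jitters) {
    s <- runSearch(j)
    if (is.null(sol) || s$xor < sol$xor) sol <- s
    cost <- silhouetteCostOf(s$pose)
    if (is.finite(cost) && cost <= control$retryCost) break
    if (evalCount >= budget) break
  }
  finalPose <- sol$pose
  ## report the contour-distance cost at the solution
  finalCost <- silhouetteCostOf(finalPose)
  conv <- is.finite(finalCost) && finalCost < control$maxCost
  msg <- if (!conv) sprintf("final cost %.3f mm above maxCost %.3f mm",
                            finalCost, control$maxCost) else ""
  new("RegistrationResult", pose = finalPose, finalCost = finalCost,
      iterations = as.numeric(evalCount), converged = conv, message = msg)
}

## union-downsample a binary mask by a factor of two
downsampleMask <- function(m) {
  ny <- nrow(m) %/% 2L * 2L
  nx <- ncol(m) %/% 2L * 2L
  m <- m[seq_len(ny), seq_len(nx)]
  pmax(m[seq(1, ny, 2), seq(1, nx, 2)], m[seq(2, ny, 2), seq(1, nx, 2)],
       m[seq(1, ny, 2), seq(2, nx, 2)], m[seq(2, ny, 2), seq(2, nx, 2)])
}


#' Track a bone through an image sequence
#'
#' Registers each frame, initializing frame k from frame k-1's pose
#' (optionally with a constant-velocity prediction). A frame that fails
#' (blank image, out-of-view, cost above the guard) is flagged and the
#' last good pose carries forward so later frames can recover. Large
#' inter-frame rotation jumps (> `maxJumpDeg`) are flagged as implausible
#' at 5 Hz, which also guards against the single-plane mirror ambiguity.
#'
#' @param mesh the [BoneMesh-class].
#' @param images list of [SilhouetteImage-class] frames, time ordered.
#' @param camera the [CameraModel-class].
#' @param initial first-frame initialization ([RigidTransform-class]).
#' @param control a [registrationControl()] list.
#' @param predictVelocity use constant-velocity initialization from the
#'   two previous poses.
#' @param maxJumpDeg inter-frame rotation jump flagged as implausible.
#' @return List of [RegistrationResult-class], one per frame.
#' @export
trackSequence <- function(mesh, images, camera, initial,
                          control = registrationControl(),
                          predictVelocity = FALSE, maxJumpDeg = 10) {
  results <- vector("list", length(images))
  prev <- initial
  prev2 <- NULL
  lastGood <- 0L
  for (k in seq_along(images)) {
    init <- prev
    if (predictVelocity && !is.null(prev2))
      init <- compose(prev, compose(rigidInverse(prev2), prev))
    res <- tryCatch(
      registerFrame(mesh, images[[k]], camera, init, control),
      error = function(e) {
        new("RegistrationResult", pose = init, finalCost = Inf,
            iterations = 0, converged = FALSE,
            message = paste("frame failed:", conditionMessage(e)))
      })
    if (res@converged && lastGood > 0L && is.finite(res@finalCost)) {
      ## plausibility vs the last converged frame, scaled by the gap
      dR <- t(results[[lastGood]]@pose@rotation) %*% res@pose@rotation
      jump <- rad2deg(acos(max(-1, min(1, (sum(diag(dR)) - 1) / 2))))
      if (jump > maxJumpDeg * (k - lastGood)) {
        res@converged <- FALSE
        res@message <- sprintf(
          "implausible inter-frame rotation jump (%.1f deg)", jump)
      }
    }
    results[[k]] <- res
    if (res@converged) {
      prev2 <- prev
      prev <- res@pose
      lastGood <- k
    }
  }
  results
}

#' Tabulate a registration sequence
#'
#' @param results list of [RegistrationResult-class] from
#'   [trackSequence()].
#' @param sequence cardan sequence for the pose angles.
#' @return data.frame: frame, 6 DOF (tx, ty, tz mm; r1, r2, r3 deg in the
#'   sequence order), cost, converged.
#' @export
registrationTable <- function(results, sequence = c("z", "x", "y")) {
  rows <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    ang <- tryCatch(angles(cardanDecompose(r@pose, sequence)$angles),
                    error = function(e) rep(NA_real_, 3))
    data.frame(frame = k, tx = r@pose@translation[1],
               ty = r@pose@translation[2], tz = r@pose@translation[3],
               r1 = ang[1], r2 = ang[2], r3 = ang[3],
               cost = r@finalCost, converged = r@converged)
  })
  do.call(rbind, rows)
}
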