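# FluoroKin

Model-based knee kinematics from single-plane fluoroscopy, in R.

Anterior-cruciate-ligament-deficient (ACLD) knees translate anteriorly
and rotate internally under weight-bearing flexion; measuring that in
vivo — and whether reconstruction restores it — requires bone-level
kinematics. The model-based 2D/3D registration technique estimates the
six-degree-of-freedom pose of a subject-specific 3D bone model by
iteratively matching its projected silhouette to the silhouette in each
frame of a calibrated single-plane fluoroscopic sequence. FluoroKin
implements that measurement chain for squat analyses of the
tibiofemoral joint, for biomechanics researchers who want a tested,
scriptable, fully synthetic-validatable implementation:

* **Anatomical frames** embedded in surface meshes: the femoral frame
  from a least-squares cylinder through both condyles (Z = cylinder
  axis, origin at its bone-clipped midpoint, Y = shaft centerline
  projected to the sagittal plane, X = Y × Z), and the tibial frame
  from the plateau tangent rectangle (posterior, medial/lateral and
  anterior supporting lines of the cross-section at the fibular-head
  level) translated to the plateau.
* **Projection model**: cone-beam geometry (source–detector distance
  SID, source–isocenter distance SOD, magnification SID/SOD), radial
  distortion with grid-target calibration and correction.
* **Registration**: staged derivative-free search over 6-DOF pose
  (coarse-to-fine pyramid, in-plane pre-alignment, depth from the area
  magnification law, multistart and an explicit mirror-twin check for
  the out-of-plane rotations, pattern-search polish), minimizing the
  silhouette mismatch; cost reported as the symmetric mean contour
  distance in mm.
* **Kinematics**: intrinsic z–x–y cardan angles of the tibia in the
  femoral frame (flexion; ad/abduction; internal rotation), tibial AP
  position as the X-component of the tibial origin; squat phases split
  at the flexion apex; cubic B-spline resampling onto the 5° flexion
  grid 0–85°.
* **Statistics**: paired and Welch t tests, and repeated-measures
  condition contrasts from a mixed linear model
  (`value ~ condition + flexionBin + (1 | subject)`, REML,
  Satterthwaite df).
* **Synthetic data**: parametric femur/tibia with closed-form frame
  ground truth, squat trajectories (0→100→0° at 5 Hz, AP range 5.2 mm,
  rotation range 14.9° over the 0–85° window), a three-condition cohort
  (ACLD +3 mm anterior / +5° internal vs contralateral; reconstructed
  knees near-restored), and silhouette rendering with optional contour
  noise and distortion.

## Worked example

```r
library(FluoroKin)

## synthetic subject: parametric bones with known anatomy
femur <- makeFemur(seed = 1)
tibia <- makeTibia(seed = 1)
buildFemoralFrame(femur$mesh)
#> AnatomicalFrame
#>   origin (mm): 0, 0, 1
#>   X-axis: 0.998168, 0.060495, 0
#>   Y-axis: -0.060495, 0.998168, 0
#>   Z-axis: 0, 0, 1
```

The recovered femoral frame matches the generator's ground truth: the
origin sits 1 mm lateral of the condylar midplane (the medial condyle
is 24 mm wide, the lateral 26 mm) and Y leans 3.5° posteriorly with the
shaft.

```r
## a squat trial rendered through the default fluoroscope at 512 x 512
camera <- cameraModel(imageSize = 512)
trial <- squatTrajectory(femur = femur, tibia = tibia, camera = camera)

## register one fluoroscopic frame of the femur from a perturbed guess
frame <- projectSilhouette(femur$mesh, trial$femurPoses[[15]], camera)
truth <- trial$femurPoses[[15]]
guess <- rigidTransform(cardanRotation(c(3, -4, 2)) %*% rotation(truth),
                        translation(truth) + c(3, -2, 4))
fit <- registerFrame(femur$mesh, frame, camera, guess)
fit
#> RegistrationResult: cost 0.0460 mm, 2070 evaluations, converged: TRUE
round(translation(pose(fit)) - translation(truth), 3)
#> [1] -0.009  0.104  0.656
```

From a guess 3–4 mm and 3–4° off, the registration recovers the pose
with ~0.1 mm in-plane error; the 0.66 mm residual is along the source
axis, the direction single-plane imaging determines only weakly.

```r
## kinematics from the true poses, resampled on the 5-degree grid
kin <- trialKinematics(femur, tibia, trial$femurPoses,
                       trial$tibiaPoses, trial$frames$time)
curve <- kin$curves$descent
round(curve@ap[1:6], 2)
#> [1] 3.00 2.96 2.82 2.61 2.32 1.97
curveMagnitude(curve)
#> $apRange
#> [1] 5.199693
#> $rotationRange
#> [1] 14.89912
```

The descent-phase curve reproduces the generator's AP range (5.2 mm)
and rotation range (14.9°) to within spline-approximation error.

```r
## three-condition cohort and the mixed-model contrast
cohort <- simulateCohort(seed = 1)
repeatedMeasuresCompare(cohortCurveTable(cohort), channel = "ap",
                        pairs = list(c("ACLD", "contralateral")))
#>      condition1 condition2    effect statistic  df             p significant
#> 1 contralateral       ACLD -2.920838 -55.75875 332 1.206149e-170        TRUE
```

The contralateral tibia sits 2.9 mm posterior of the ACLD tibia across
flexion bins (the generator's configured offset is 3 mm), significant
at any conventional level.

A full synthetic run — cohort synthesis, curves, per-condition means,
statistics tables and provenance — is one call:

```r
runPipeline(list(seed = 1, output = "fluorokin-run"))
```

or from a shell, `Rscript inst/scripts/fluorokin.R run-all --seed 1`.

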