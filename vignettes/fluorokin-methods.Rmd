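---
title: "Model-based knee kinematics from single-plane fluoroscopy: methods and validation"
author: "FluoroKin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based knee kinematics from single-plane fluoroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FluoroKin)
```

## The measurement problem

Anterior cruciate ligament (ACL) rupture destabilizes the tibiofemoral
joint: under weight-bearing flexion the tibia of an ACL-deficient (ACLD)
knee translates anteriorly and rotates internally relative to the femur.
Quantifying that in vivo, and whether reconstruction restores it,
requires bone-level kinematics that skin markers cannot deliver.
Model-based 2D/3D registration measures them radiographically: a
subject-specific 3D bone model (from CT) is posed in the projection
geometry of a calibrated single-plane fluoroscope until its projected
silhouette matches the silhouette in each fluoroscopic frame. The
six-degree-of-freedom poses of femur and tibia, expressed through
anatomical coordinate systems embedded in each bone, then yield the
joint kinematics: tibial anteroposterior (AP) position (mm, anterior
positive) and internal-external rotation (degrees, internal positive)
as functions of knee flexion.

FluoroKin implements this chain end to end — anatomical frame
embedding, projection and distortion modelling, silhouette
registration, cardan-angle kinematics with B-spline smoothing on a
5-degree flexion grid, and mixed-model group comparison — together with
a synthetic-data generator that renders squat trials with known ground
truth, so every stage can be validated quantitatively.

## Anatomical coordinate systems

**Femur.** The medial and lateral condyles are treated as a single
cylinder, fit by orthogonal least squares
(`fitCondylarCylinder()`; Levenberg–Marquardt, initialized from each
principal axis of the selected surface points and keeping the best
fit, since a condylar point patch has no dominant principal
direction). The cylinder axis is the femoral Z (medial to lateral by a
configurable convention), the origin is the midpoint of the axis
segment clipped by the bony surfaces, Y is the femoral shaft centerline
projected onto the sagittal plane through the origin (proximal), and
X = Y x Z (anterior). Condylar and shaft point selections come from
region labels on the mesh; synthetic bones always carry those labels.

**Tibia.** The bone is sliced perpendicular to its long axis at the
level of the fibular head; on that cross-section four supporting lines
are constructed — the posterior tangent, the medial and lateral
tangents perpendicular to it, and the anterior tangent — forming the
plateau tangent rectangle (`tangentRectangle()`). The rectangle is
translated along the long axis to the plateau's proximal extent; its
midpoint is the tibial origin, the AP bisector is X (anterior), the
transverse bisector Z, and Y completes the right-handed triad. Because
a meshed tibia need not include the fibula, the fibular-head level is a
per-subject scalar (mm below the plateau apex) supplied as metadata;
default 15 mm. The rectangle's in-plane translation to the plateau is
purely along the long axis, preserving its orientation — the reading
that keeps the construction deterministic.

Left knees are handled by mirroring flags: the hint vectors flip, the
constructed frame stays right-handed, and curves are mirrored to the
right-knee sign convention before pooling (`mirrorToRight()`).

## Cardan angles

The relative pose of the tibial frame in the femoral frame is
decomposed as intrinsic z–x–y cardan angles: flexion about the femoral
mediolateral axis, then ad/abduction about the floated axis, then
internal–external rotation about the tibial long axis. This sequence
follows from the frame definitions above (flexion must be the rotation
about the condylar cylinder axis, and tibial rotation the rotation
about the tibial long axis); it is a parameter everywhere and is
recorded in every serialized transform. Angles are degrees externally,
radians internally. Decomposition within 1e-6 degrees of the gimbal
singularity (middle angle at ±90°) raises an explicit error — far
outside physiological knee motion, where the middle (varus–valgus)
angle stays within a few degrees.

## Projection, distortion and calibration

The fluoroscope is modelled as a cone-beam camera: point source at the
origin, detector at the source-to-detector distance (SID), isocenter at
the source-to-object distance (SOD); magnification at the isocenter is
SID/SOD. Defaults are a 17-inch (431.8 mm) flat panel at 1024×1024
(so 0.42 mm/px), SID 1100 mm, SOD 800 mm — hardware-class values; SID
and SOD are rig configuration, not constants, and belong in the run
configuration. Radial distortion is a polynomial in normalized radius
about the principal point; flat panels are nearly distortion-free
(identity default), but the full path — grid-target calibration
(`calibrateFromGrid()`, jointly estimating pixel pitch and radial
coefficients), image correction, numeric inversion — exists and is
exercised so image-intensifier data can be processed. The distortion
centre is fixed at the principal point: a grid target constrains the
radial profile well but the centre poorly at mild distortion.

Silhouettes are binary by design: the registration below matches
outlines, not attenuation, so no X-ray transport is simulated.

## Silhouette registration

Each frame solves a 6-DOF pose estimation: adjust the bone pose until
the projected silhouette matches the image silhouette. The search
minimizes the pixelwise symmetric-difference area between the rendered
and observed silhouettes. Up to the boundary-length scale this equals
the mean contour offset, but unlike a nearest-neighbour contour
distance it cannot produce wrong-correspondence minima; the reported
`finalCost` is nevertheless the symmetric mean nearest-neighbour
contour distance in mm (`silhouetteCost()`), the interpretable
contour-matching metric.

The optimizer is derivative-free and staged, because single-plane
geometry makes the six degrees of freedom extremely anisotropic:

* in-plane translation and rotation are strongly observable;
* source-axis (out-of-plane) translation moves the cost only through
  the magnification law;
* out-of-plane rotations couple with in-plane shifts and with depth,
  forming narrow curved valleys with secondary basins (including the
  classic near/far mirror twin of the silhouette).

The stages: mask-centroid pre-alignment; a coarse-resolution pyramid
level (half the image size) for all global work; an in-plane-only
simplex; a depth reset from the area magnification law; a 3×3
multistart over the out-of-plane rotations; a scan along depth with the
out-of-plane rotations re-optimized at each depth (this walks down the
valley that axis-aligned moves cannot follow); an explicit evaluation
of the depth-reflected mirror pose; then, at full resolution,
alternating simplex refinement and valley passes, and a cyclic
pattern-search polish with shrinking steps (final steps 0.04 mm /
0.02°). Because the noise-free global optimum has near-zero contour
cost, a high final cost reliably flags a secondary basin; such frames
are re-run from rotation-jittered starts (`retryCost`, default
0.15 mm; around 1.0 mm is appropriate for silhouettes carrying ~1 px
contour noise, whose cost floor is higher). The default evaluation
budget (6000 renders per frame, typically ~1500 used) reflects this
retry headroom.

Out-of-plane translation error is reported separately from in-plane
error and never pooled with it: with one view it is 10–50× less
accurate, which is intrinsic to single-plane registration, and the
validity figures quoted for the technique are in-plane figures.
Sequences are tracked frame-to-frame with the previous converged pose
as initialization (optionally constant-velocity prediction), a failed
frame flagged and skipped, and an implausibility guard on inter-frame
rotation jumps (10°/frame at 5 Hz, scaled by the gap since the last
converged frame), which also pins down the mirror ambiguity across a
sequence.

## Kinematic curves

Per-frame joint kinematics (flexion, ad/abduction, internal rotation,
AP position) come from the cardan decomposition of the tibia-in-femur
transform; the AP position is the X-component of the tibial origin in
the femoral frame. A squat cycle is split at the flexion apex into
descent and ascent (reversals under 2° ignored); the descent phase is
the default analysis phase, matching the one-curve-per-knee
convention, and both phases are retained. Within a phase, AP and
rotation are modelled as functions of flexion by an unpenalized
least-squares cubic B-spline with interior knots every 15° of flexion
(configurable), evaluated on the fixed grid 0, 5, …, 85°. Grid nodes
outside the sampled flexion span are missing, never extrapolated. A
regression B-spline was chosen over a GCV smoothing spline because the
spline space then contains all cubics, making the stage exactly
polynomial-reproducing up to its degree — a property the validation
suite asserts — while still averaging frame-level measurement noise
(21 descent samples at 5 Hz against ~10 basis functions). The curve
magnitude per trial is max − min over the grid, per channel.

## Group statistics

Paired and Welch t tests wrap the classical formulas. The condition
comparison (ACLD vs contralateral vs reconstructed) is a mixed linear
model with repeated measures over flexion bins: for each condition
pair, `value ~ condition + flexionBin + (1 | subject)` fit by REML,
the condition contrast reported with Satterthwaite degrees of freedom
(**lmerTest**). Pairwise contrasts are reported unadjusted by
default (a Holm option exists). The estimation backend is a design
choice; the contract the package enforces by simulation is
calibration: type-I error within [0.03, 0.07] at α = 0.05 under the
null cohort generator (500 seeded replicates) and ≥ 80% detection of
the default ACLD effects at n = 10.

## The synthetic-data generator

The generator defines the study conditions the package is validated
under; its defaults are fixed, not tuning knobs.

* **Bones.** Parametric femur (condylar cylinder radius 21 mm, medial/
  lateral widths 24/26 mm, shaft 150 mm with a slight posterior-lateral
  tilt, an anterior flange block breaking silhouette symmetry) and
  tibia (plateau ellipse 24 mm AP × 35 mm ML semi-axes, fibular-head
  level 15 mm). The condylar surface lies exactly on the declared
  cylinder and the fibular-level section is exactly the declared
  ellipse, so frame constructions have closed-form truth. Seeds only
  rotate the tessellation phase.
* **Trajectory.** Squat cycles at 5 Hz flexing 0→100→0° (raised-cosine
  in time); AP moves posteriorly and rotation internally with flexion
  along smooth raised-cosine profiles attaining exactly 5.2 mm and
  14.9° of range over the analyzed 0–85° window — the magnitudes the
  clinical literature reports for squatting ACLD cohorts. The femur
  leans with half the knee flexion in the image plane and drifts ~10 mm
  over the cycle. The lateral (mediolateral) imaging direction is the
  default, so AP translation and flexion are in-plane.
* **Cohort.** n = 10 subjects × three conditions. ACLD knees are offset
  +3 mm anterior and +5° internal at all flexion angles versus
  contralateral; reconstructed knees −0.8 mm / +0.5° (slight AP
  overcorrection, rotation restored). Between-subject SDs: 2.5 mm AP
  baseline, 3° rotation baseline, 4% bone scale. Measured curves add
  independent per-node noise (0.5 mm / 0.7°), emulating smoothed
  per-frame measurement error. These effect sizes sit between the
  static-laxity differences (~6 mm) and per-bin kinematic differences
  such cohorts show, and give a comfortably powered design at n = 10,
  as the study's own power analysis intended.
* **Rendering.** One binary silhouette per bone per frame (a combined
  occluding image is available for stress tests); optional degradation
  by Gaussian contour displacement along local normals plus
  re-rasterization quantization, and by radial distortion resampling —
  the features a contour-based cost actually sees. No CT appearance,
  scatter or soft tissue is simulated: passing these tests demonstrates
  the geometry and inference chain, not robustness to segmentation
  error or occlusion-heavy imaging.

## Validation protocol and problem sizes

The validation experiments (also run by `scripts/acceptance.R`) use
512² rendering — the half-resolution detector matrix keeps a 50-frame
experiment within minutes on one CPU while staying well inside the
accuracy bounds, and the registration pyramid touches 256² internally:

* **Noise-free registration:** 50 frames spread over a squat, initial
  poses perturbed by up to ±5 mm per translation axis and ±5° per
  rotation axis; bounds: RMS in-plane ≤ 0.42 mm, RMS rotation (three
  cardan components pooled) ≤ 0.54° — the strictest accuracy figures
  quoted for the technique.
* **Noisy registration:** the same with 1 px contour noise and a mild
  cubic radial distortion (0.8% at the field corner) that is estimated
  from a synthetic 25 mm grid target (0.2 px node noise) and corrected
  before registration; bounds 0.53 mm / 1.3°.
* **Frame recovery:** femoral and tibial frames within 0.1° / 0.1 mm of
  analytic truth; exact cylinder fits on noise-free cylinders (≤ 1e-6).
* **Kinematics identity:** pipeline on true poses within 0.2 mm / 0.3°
  per grid node; spline exact on cubics.
* **Statistics:** the calibration and power contracts above.
* **Algebra:** cardan round trips below 1e-6° over 1000 random
  rotations; rigid-transform group and invariance properties at 1e-9.

## Numerical choices and degenerate inputs

Tolerances: orthonormality and right-handedness 1e-9; gimbal guard
1e-6°; distortion inversion by vectorized Newton iterations (≪ 0.05 px
for mild distortion). Degenerate inputs raise typed errors rather than
returning silently: collinear point sets for cylinder or rectangle
fits, empty silhouettes, slices outside the mesh, under-determined
calibrations, fewer than four samples for the spline, zero-variance t
tests, single-subject mixed models. Ties and ambiguities are resolved
deterministically (largest contour loop by area; supporting lines at
the extreme projections; the flexion apex at the global maximum with a
2° hysteresis).

## Pipeline defaults

`runPipeline()` defaults to kinematics from ground-truth poses
("true-poses" mode): registering a full cohort (10 subjects × 3
conditions × 41 frames × 2 bones) is an hours-long batch computation,
while curve-level statistics are what the default smoke run needs;
"register" mode exercises the silhouette-registration path on a
reduced frame set and the per-frame machinery is fully validated by
the accuracy experiments. One global seed fans out to per-stage seeds
by a stable hash, so stages are independently reproducible; each run
emits its resolved configuration, and re-running from that file
reproduces the curve outputs bit for bit.

## Known limitations

* Out-of-plane translation is weakly determined — by design of the
  imaging geometry, not the implementation; it is reported separately.
* The synthetic bones are piecewise-quadric phantoms. They exercise
  the full inference chain with known truth, but real condylar
  surfaces deviate from cylinders, and real silhouettes carry
  segmentation error, occlusion by the contralateral limb and
  intensity ambiguity that these tests do not probe.
* The mixed model assumes a shared subject intercept across conditions
  and independent node noise; strongly autocorrelated measurement
  error across flexion bins would make the reported p-values
  anti-conservative.
* The registration cost presumes one bone per silhouette; the combined
  two-bone rendering mode exists for stress testing, but two-bone
  segmentation is out of scope.
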