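Package: FluoroKin
Title: Model-Based Knee Kinematics from Single-Plane Fluoroscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for model-based tibiofemoral kinematics measured by
    single-plane fluoroscopic 2D/3D registration. Embeds anatomical
    coordinate systems in femoral and tibial surface meshes (condylar
    cylinder fit, tibial plateau tangent rectangle), models cone-beam
    projection with radial distortion and grid-target calibration,
    estimates six degree-of-freedom bone pose by iterative silhouette
    matching, converts pose sequences into cardan-angle joint kinematics
    (tibial anteroposterior translation and internal-external rotation
    versus knee flexion) with B-spline smoothing on a 5-degree flexion
    grid, and compares condition groups with mixed linear models with
    repeated measures. A synthetic-data module generates parametric
    bones, squat trajectories, rendered fluoroscopic silhouettes and
    three-condition cohorts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    png,
    splines,
    minpack.lm,
    lme4,
    lmerTest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'FluoroKin-package.R'
    'RcppExports.R'
    'mesh.R'
    'anatomy.R'
    'camera.R'
    'distortion.R'
    'geometry.R'
    'registration.R'
    'kinematics.R'
    'synthetic.R'
    'experiments.R'
    'stats.R'
    'pipeline.R'
    'utils.R'
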