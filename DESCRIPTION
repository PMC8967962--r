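Package: etecim
Title: Gross Tumor Volume Estimation by Equivalent Truncated Elliptical
    Cone Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates gross tumor volume (GTV) from 3-D binary
    segmentation masks by fitting the equivalent (inertia) ellipse of
    every axial slice from image second moments and integrating
    truncated elliptical cone (frustum) volumes between adjacent
    slices, alongside the conventional voxel-summation estimator and
    RECIST-style diameter extraction. Also provides the
    comparative-assessment toolbox for predicted versus ground-truth
    masks (Dice similarity coefficient, Hausdorff and mean surface
    distance, conformity index, degree of inclusion, center-of-mass
    motion vector), cohort-level statistics (Pearson correlation,
    paired and one-sample t-tests, quartile summaries, linear
    calibration), synthetic phantom generators with known analytic
    geometry, and NIfTI-1 mask input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'etecim-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'volume-io.R'
    'ellipse-fit.R'
    'gtv-estimation.R'
    'overlap-metrics.R'
    'cohort-stats.R'
    'phantoms.R'
    'cli.R'
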