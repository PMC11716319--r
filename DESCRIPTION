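Package: limbarch
Title: Muscle and Fascia Architecture from Volumetric and Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies longitudinal skeletal-muscle and deep-fascia structure
    from segmented magnetic resonance images. Provides labeled-mask volumetry
    with landmark-based slice alignment and anatomical compartment grouping; a
    thin-sheet fascia thickness pipeline (dual-echo subtraction contrast,
    per-slice centerline extraction, medial-axis distance-transform thickness
    sampling, histogram and pre/post shift analysis) with an algebraic
    volume/(length x width) cross-check; and a diffusion-tensor muscle
    architecture stage (log-linear tensor reconstruction, FA/MD maps,
    deterministic streamline tractography, polynomial tract extrapolation to
    muscle boundaries, fascicle length, pennation angle and physiological
    cross-sectional area). Includes analytic synthetic phantoms (irregular
    fascia tubes, labeled limb masks, unipennate fiber fields with simulated
    diffusion-weighted signal) with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'architecture.R'
    'skeleton.R'
    'fascia.R'
    'volumetry.R'
    'phantoms.R'
    'comparison.R'
    'io.R'
    'limbarch-package.R'
    'methods.R'
    'preprocess.R'
    'tensor.R'
    'tracking.R'
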