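Package: memriz
Title: Z-Score Activity Mapping for Manganese-Enhanced MRI of the Mouse Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for voxel-wise quantification of basal
    brain activity from manganese-enhanced T1-weighted MRI volumes. Provides
    digital mouse-brain phantom simulation with known ground truth, brain
    masking, non-linear denoising, 12-parameter affine atlas registration with
    label propagation, whole-brain Z-score normalization with suprathreshold
    censusing, atlas-based region-of-interest and hippocampal sub-region
    metrics, and homoscedastic two-group comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
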