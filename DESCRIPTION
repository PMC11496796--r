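Package: laoverlap
Title: Spatial Overlap of Left Atrial Epicardial Fat and Wall Fibrosis from
    Water-Fat LGE MRI Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial overlap between left atrial (LA)
    epicardial adipose tissue (EAT) and LA wall fibrosis from co-registered
    3D water/fat-separated late gadolinium enhancement MRI segmentations.
    Builds a triangulated wall surface from the intramural wall mask,
    assigns each wall voxel the outward normal of its closest mesh vertex,
    casts 6 mm orthogonal rays to flag EAT-adjacent wall voxels, classifies
    fibrosis by a mitral-valve signal-intensity threshold and by image
    intensity ratio (IIR) thresholds 1.2 and 1.32, and derives per-subject
    metrics (LA volume by transversal slice summation, EAT volume and area,
    relative and absolute fibrosis and overlap areas, body-surface-area
    indexed variants). Includes a synthetic LA phantom and cohort generator
    with known ground truth, and the cohort statistics stage: group
    comparisons across atrial fibrillation types, paired overlap-versus-
    fibrosis testing, proportional-odds ordinal regression of AF type, and
    LVEF median-split logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
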