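Package: strokeatlas
Title: Atlas-Assisted Analysis of Stroke Neuroimages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for atlas-assisted stroke image analysis: midsagittal-plane
    extraction from 3D scans by a symmetrized Kullback-Leibler intensity
    divergence (with a skull-fit pre-rotation extension for large head tilts),
    ellipse-based landmark estimation and piecewise-linear Talairach-style
    atlas-to-scan mapping (12- and 24-region forms), hemispheric-asymmetry
    lesion detection over paired atlas regions, white-matter-hyperintensity and
    diffusion-lesion segmentation, thrombolysis decision ratios, and
    construction, constraint and leave-one-out evaluation of probabilistic
    stroke atlases. A procedural head-phantom and cohort generator provides
    ground-truthed synthetic data so the whole pipeline is testable without
    clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    EBImage,
    igraph,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
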