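Package: neocca
Title: Multimodal Canonical Correlation Analysis for Neonatal Neuroimaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven pipeline linking multimodal voxelwise brain imaging
    to clinical and environmental factors in neonatal cohorts. Imaging blocks
    (e.g. Jacobian volume-change maps, T2-weighted intensities, white-matter
    fractional-anisotropy skeletons and gray-matter diffusivity skeletons) are
    reduced to multimodal components sharing a single subject course, the
    subject courses are related to an encoded clinical covariate matrix by
    canonical correlation analysis, and inference proceeds by max-statistic
    permutation testing and bootstrap resampling. Includes voxelwise loading
    maps with family-wise-error correction, linear-regression tests of
    neurodevelopmental outcome against canonical variates, and a synthetic
    multimodal cohort generator with known planted structure for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
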