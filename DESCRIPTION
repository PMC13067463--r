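Package: dazvlsm
Title: Voxel-Based Lesion-Symptom Mapping for Extra-Axial Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based lesion-symptom mapping (VLSM) adapted to extra-axial
    tumors such as meningiomas. Provides dural-attachment-zone (DAZ) masking by
    intersection of tumor masks with a labeled dural template, hemisphere
    mirroring, cohort lesion-frequency maps, voxel-wise univariable regression
    with a minimum-overlap filter, and multiple-comparison correction by
    Bonferroni, Benjamini-Hochberg FDR, and permutation-based inference with
    threshold-free cluster enhancement (TFCE). Includes a synthetic phantom
    cohort generator (dural geometry, attachment-seeded tumors, endpoint
    simulation with implanted location and volume effects) so that every
    pipeline stage can be exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
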