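Package: admodal
Title: Multimodal Quantification of Amyloid Pathology in the 5xFAD Mouse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements, as one tested pipeline over synthetic ground-truthed
    data, the three quantification arms of a multimodal 5xFAD mouse study:
    fluorescence immunohistochemistry marker quantification (positive-pixel
    percentage, mean grayscale intensity, DAPI nuclei density), 13C
    stable-isotope functional metabolic mapping (natural-abundance correction,
    molecular carbon labeling, M+X percentages), and diffusion kurtosis
    imaging (Rician floor adjustment, voxelwise DKI fit, MD/FA/MK maps, ROI
    volumetrics). Includes the study's statistical machinery: ROUT outlier
    removal, two-way ANOVA with Tukey post hoc, Student's t-tests, and a
    permutational three-way mixed ANOVA with simple main effects. Synthetic
    phantom generators with known ground truth stand in for the study's
    undeposited raw data.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    minpack.lm,
    pracma,
    car,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
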