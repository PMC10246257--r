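Package: petacval
Title: Validation of PET Attenuation Correction by Synthetic Lesion
    Insertion in Projection Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for assessing the quantitative impact
    of MR-based attenuation correction (MRAC) on brain PET, without patient
    data. Generates digital brain-like phantoms (activity, label atlas,
    ground-truth CT-derived attenuation map) and four MRAC-like degraded
    attenuation maps emulating DIXON, DIXONbone, UTE and deep-learning
    pseudo-CT behaviour; inserts spherical or atlas-defined lesions
    analytically into PET projection space (forward projection, attenuation,
    normalization, scatter, Poisson noise, add/replace composition with a
    background sinogram); reconstructs with ordered-subsets expectation
    maximization under each attenuation map; and quantifies regional
    MRAC-to-CTAC activity bias with cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
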