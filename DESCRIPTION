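Package: eigenbrain
Title: Eigenbrain Covariance Decomposition of FDG-PET Brain Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Spectral covariance decomposition of fluorodeoxyglucose positron
    emission tomography (FDG-PET) images for the study of neurodegenerative
    dementia syndromes. Implements reference-region (pons) normalization,
    Gaussian smoothing, robust per-subject scaling, participant-by-voxel
    singular value decomposition yielding "eigenbrain" spatial patterns and
    per-subject expression scores, component retention by Horn's parallel
    analysis, voxel-wise Z-score group contrast maps with age- and sex-matched
    control selection, regression-based linking of eigenbrain scores to
    cognitive and behavioural phenotypes, meta-analytic spatial decoding
    against topic maps, and multiclass linear discriminant diagnosis with
    log-transformed and robust variants. A synthetic-cohort generator with
    planted orthogonal metabolism patterns makes the full pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    car,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
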