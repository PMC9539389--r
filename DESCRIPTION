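Package: lesionmtr
Title: Within- and Between-Lesion MTR Treatment-Effect Analysis for
    Remyelination Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lesion-level analysis of magnetisation transfer ratio (MTR)
    change in two-arm remyelination trials. Computes MTR maps from
    magnetisation-transfer volume pairs, decomposes T2 lesions into a core,
    a rim and three perilesional cuffs by one-voxel-layer 3D morphology,
    bands white matter and cortex by Euclidean distance from the
    ventricular and outer CSF surfaces, stratifies lesions, segments and
    voxels by tissue-specific baseline MTR or T1-weighted intensity
    quartiles, fits baseline-adjusted linear mixed models with patient and
    lesion random intercepts to estimate adjusted treatment differences and
    treatment-by-subgroup interactions, and performs ANCOVA sample-size and
    remyelination-ceiling calculations. Includes a synthetic two-arm trial
    generator with plantable ground-truth effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
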