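Package: hspseg
Title: Semiautomated Segmentation and Volumetry of Carotid High-Signal Plaque
    on 3D Black-Blood Vessel-Wall MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomated segmentation of carotid high-signal plaque (HSP) on
    3D turbo spin-echo T1-weighted black-blood vessel-wall MRI. The plaque
    region is extracted by seeded region growing with a stepwise-decreasing
    intensity threshold after Gaussian smoothing; the HSP region is then
    segmented from the plaque by thresholding at a configurable multiple
    (default 1.3) of the mean signal of an adjacent-muscle reference region,
    and volumes are reported in cubic millimetres. Includes a synthetic
    vessel-wall phantom generator with ground-truth masks for validation,
    rater-agreement statistics (ICC(2,1), Bland-Altman limits of agreement,
    Spearman rank correlation), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
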