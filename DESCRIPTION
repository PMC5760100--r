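Package: punctatrack
Title: Tracking and Kinematic Quantification of Fluorescent Puncta in
    Photoreceptor Time-Lapse Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intracellular vesicle-associated particle dynamics in
    two-channel 2-D fluorescence time-lapse videos of polarized cells such as
    retinal photoreceptors. Provides translation registration, intensity
    segmentation into puncta, tracking-by-assignment with appearance and
    disappearance costs, per-particle kinematic statistics (displacement,
    trajectory length, maximum speed, rotation-corrected directionality,
    cross-sectional area, basal-body contacts), per-cell summaries and group
    comparisons, together with a ground-truthed synthetic video generator so
    the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    EBImage,
    readxl
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
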