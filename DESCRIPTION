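Package: subchondral
Title: Micro-CT Morphometry and Classification of Subchondral Bone
    Changes After Marrow Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Geometric analysis of calibrated two-dimensional micro-CT
    cross-sections of osteochondral defects treated by microfracture.
    Provides gray-value segmentation of bone, two-point bone mineral
    density calibration, measurement of the projected cement line, bone
    bridges, vertical (Vd1, Vd2) and horizontal (Hd1, Hd2) lesion
    diameters and osteophyte height, and a threshold-based decision
    algorithm that classifies each lesion as complete reconstitution,
    intra-lesional osteophyte, residual microfracture hole, peri-hole
    bone resorption, or subchondral bone cyst.  Includes a parametric
    synthetic-phantom generator with analytic ground truth, threshold
    sensitivity sweeps, inter-rater agreement statistics (percent
    agreement and Cohen's unweighted kappa), and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    e1071,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
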