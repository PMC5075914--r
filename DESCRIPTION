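Package: gliaband
Title: Distance-Banded Quantification of Peri-Implant Gliosis and Neuronal Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the foreign-body response around explanted neural
    implants from stained histological sections. A manually outlined electrode
    track with per-face surface labels is expanded into concentric 50 um
    distance bands (Euclidean distance transform); per-band, per-face mean
    stain intensity (GFAP-like) and neuron density (NeuN-like) profiles are
    computed and normalized to a 400-500 um background zone; the four surface
    groups are compared per band with tie-corrected Kruskal-Wallis and
    Dunn-Bonferroni post-hoc tests. Includes a synthetic-micrograph generator
    with analytic ground truth for validation, scale-space nucleus detection,
    and surface-morphology metrics (triangulated area-ratio roughness, pillar
    density and tilt-corrected pillar height).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mgcv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
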