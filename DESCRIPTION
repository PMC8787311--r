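Package: spindlemorph
Title: Synthetic Golgi Phantoms, 3D Dendritic Spine Reconstruction and
    Morphometry for Spindle-Shaped Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise spindle-shaped (putative von Economo)
    neurons from brightfield Golgi z-stacks: a synthetic Golgi phantom
    generator with full ground truth (spindle morphologies, class-labelled
    dendritic spines, rendered 8-bit image stacks), a 3D spine-reconstruction
    pipeline (outlier removal, unsharp and edge-aware enhancement, adaptive
    binarisation, false-positive pruning, per-slice flood fill, cubic z
    interpolation), rule-based spine classification (thin, stubby, wide,
    mushroom, ramified, transitional, atypical, with spinule detection), and
    cylinder-model SWC morphometry (soma metrics, branch counts, total
    dendritic length and frustum volume, spindle-phenotype qualifier).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
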