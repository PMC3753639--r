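Package: wbspcr
Title: Whole-Body Scanning PCR: Assay Design, Quantification and Spatial Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for whole-body scanning PCR (WBS-PCR), in which a frozen
    whole-body tissue section is extracted grid-wise into the wells of a
    1536-well plate, assayed by qPCR on a 384-well analysis plate, and the
    per-well signals are reassembled into a spatial biodistribution image.
    Provides plate geometry and well addressing, design rules for small-RNA
    RT-qPCR primers (target-recognition sequence selection with palindrome
    avoidance, anti-primer quenching architecture) and chemical-ligation qPCR
    ligator pairs, standard-curve fitting with linear-range and
    limit-of-detection estimation, noise filtering, genomic 18S normalization,
    cross-reactivity matrices, grid reconstruction and image rendering with
    optional photo overlay, and a synthetic section simulator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    oro.nifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
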