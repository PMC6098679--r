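Package: berrymorph
Title: Image-Based Fruit Morphometrics, Euler-Characteristic Shape
    Descriptors, and QTL Mapping in Four-Way Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation-backed pipeline for image-based fruit phenotyping
    and downstream quantitative genetics. Generates synthetic fruit scenes
    with known ground truth (superellipse and piriform silhouettes, size
    reference circles), segments scenes and measures basic descriptors
    (length, width, length-to-width ratio, projected area, eccentricity),
    computes persistent-homology shape signatures as Euler-characteristic
    curves of a pixel density filtration over concentric annuli, fits
    kinship-structured mixed models for BLUPs and genomic heritability,
    and maps quantitative trait loci in four-way crosses by Haley-Knott
    regression with permutation thresholds, additive stepwise model
    selection, 1.5-LOD support intervals, and cross-year collocation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
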