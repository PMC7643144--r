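Package: colocbox
Title: Object-Based Colocalization Analysis of Multichannel Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolbox for semi-automatic object-based colocalization
    analysis (OBCA) of multichannel fluorescence Z-stacks. Builds declarative
    grayscale and binary image elements (thresholding, Boolean AND/NOT,
    morphological filtering, small-particle and 3D edge-object removal,
    outlines), composites them into output channels under color-priority
    mixing rules, and produces an artifact-suppressing Z-projection that
    selects whole 3D objects by stack position so that objects stacked in Z
    never masquerade as colocalized. Includes prominence-based 2D and
    neighborhood-based 3D local-maxima spot detection with category-string
    bookkeeping, serial-section data organization with benchmark scoring,
    alpha-shape 3D scene reconstruction, and a synthetic labeled-tissue
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
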