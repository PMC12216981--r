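Package: topotrace
Title: Tracing and Topological Classification of DNA Molecules in AFM Height Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An automated pipeline for tracing individual DNA molecules in
    atomic force microscopy (AFM) height maps and determining their topology.
    Height maps are flattened and masked, molecules are reduced to single-pixel
    skeletons by a height-biased thinning algorithm, crossings are detected and
    the over-passing duplex at each crossing is called from the full width at
    half maximum (FWHM) of the height profile traced through the crossing.
    Ordered molecule traces with pseudo-height crossing codes are converted to
    planar knot diagrams and classified in Rolfsen notation via the Kauffman
    bracket / Jones polynomial, with a per-crossing reliability score and a
    combinatorial model of misclassification probability. Morphometric tools
    quantify contour length, replication intermediates (theta structures,
    reversed forks) and deposition conformation classes, and a seeded
    pseudo-AFM generator renders ground-truthed synthetic images of knots,
    catenanes and replication intermediates so the entire pipeline can be
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
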