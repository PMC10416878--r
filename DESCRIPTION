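Package: onionpeel
Title: Counting Oral Epithelium Cell Layers from Segmented Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counts the number of cell layers in stratified squamous
    (oral) epithelium from tables of segmented nuclei. Nuclei are joined
    into a neighbor graph by Delaunay triangulation with long-edge
    pruning; epithelial nuclei adjacent to stroma or to stratum
    corneum/background are classified as inner and outer edge points;
    small disconnected fragments are filtered; and a breadth-synchronous
    wave front peeled inward from the outer edge assigns each inner-edge
    nucleus a layer count, summarized per slide as a median and standard
    deviation. Also provides the fusion step that combines semantic label
    maps with instance-segmentation centroids into cell tables (tiling,
    overlap-discard, center-based reclassification), a seedable generator
    of layered epithelial point patterns and synthetic cohorts with known
    ground truth, and cohort-level statistics (one-way ANOVA across
    diagnosis groups, median-split Kaplan-Meier curves and Cox
    proportional-hazards regression on progression-free interval).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    igraph,
    jsonlite,
    png,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
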