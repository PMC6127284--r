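Package: dendrawave
Title: Pulse-Chase Wave Analysis of Dendritic Receptor Transport and 3D
    Puncta Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dendritic cargo transport from photoconversion
    pulse-chase time-lapse movies: bin-wise doubly normalised fluorescence
    wave matrices, time-to-peak (crest) and leading-edge velocity estimators,
    and two-population classification. Also provides 3D puncta segmentation
    with watershed splitting, puncta metrics normalised to dendrite volume,
    nanodomain detection and single-linkage cluster profiling, Pearson and
    Manders colocalization coefficients, the group-comparison statistics used
    for such assays (paired-by-timepoint t tests, ANOVA with Bonferroni
    post-tests, Kruskal-Wallis with Dunn's test), and hypergeometric plus
    permutation locus enrichment for differentially expressed gene lists.
    Includes synthetic-data generators with known ground truth for movies,
    two-channel 3D volumes and gene universes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
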