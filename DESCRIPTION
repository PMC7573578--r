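Package: gfoffset
Title: Gradient-Forest Genomic Offset and Assisted-Migration Planning for
    Monsoon-Adapted Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landscape-genomics toolkit linking pool-seq allele frequencies
    of georeferenced crop landraces to monsoon-aligned agro-climate metrics.
    Detects monsoon onset from daily rainfall, builds a 157-metric windowed
    climate catalog, fits per-SNP random-forest turnover models (gradient
    forest) of genotype-climate change, maps genomic vulnerability (offset)
    under multi-model future climate projections, validates offsets against
    common-garden yield, runs latent-factor association of SNP frequencies
    with flowering time, and solves optimal, near-optimal and sub-optimal
    assisted-migration plans with migration load. Includes a seeded
    synthetic-data generator emulating West African clinal structure so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest,
    geosphere,
    mclust
Config/testthat/edition: 3
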