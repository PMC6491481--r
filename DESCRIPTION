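Package: orchardphen
Title: Multi-Scale High-Throughput Orchard Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of multi-scale phenotyping data for fruit-tree
    orchards grown under contrasted watering regimes. Computes canopy
    architectural descriptors from terrestrial LiDAR point clouds (convex-hull
    and alpha-hull volumes via a built-in 3D Delaunay triangulation, convexity
    index, and the silhouette to total leaf area ratio STAR), per-tree
    vegetation indices (NDVI, GNDVI, MCARI2, PRI), canopy temperature
    statistics and the trapezoid-based Water Deficit Index from multispectral
    and thermal rasters, and a semi-empirical photosynthesis index (I_PL)
    calibrated from chlorophyll-fluorescence and gas-exchange records. A
    quantitative-genetics layer fits mixed models with a random genotype
    effect (BIC model selection, BLUPs, broad-sense heritability) and a
    multivariate layer derives correlation tables, PCA and Ward clustering of
    genotypes. A synthetic-data module generates all four input families with
    known ground truth so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    multcomp,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
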