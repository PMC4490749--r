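Package: osteoqtl
Title: Cortical Bone Microstructure Phenotyping and QTL Mapping on Synthetic Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 3D morphometric phenotyping of cortical bone microstructure
    (osteocyte lacunae, vascular canals, and the cortical shell) and for mapping the
    resulting phenotypes in an F2 intercross. Provides a synthetic phantom generator
    with voxel-exact ground truth, phase segmentation and pore labeling of grayscale
    tomographic volumes, per-object and per-specimen morphometry (radial cortical
    thickness, number densities, lacuna volume, stretch, and distribution oblateness),
    an F2 intercross simulator with planted quantitative trait loci, and a complete
    multiple-QTL mapping chain: broad-sense heritability screening, hidden-Markov
    genotype probabilities, extended Haley-Knott genome scans with an interactive sex
    covariate, permutation-derived significance thresholds and penalties, penalized
    stepwise model search, position refinement, support intervals, and per-term
    variance attribution.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
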