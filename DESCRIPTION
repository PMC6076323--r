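Package: gxegblup
Title: Multi-Environment Genomic Prediction with Reaction-Norm GBLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for multi-environment plant-breeding trials
    using reaction-norm GBLUP models with genotype-by-environment interaction
    kernels. Builds genomic relationship matrices from SNP dosage data (VCF or
    plain dosage matrices), enumerates a registry of thirteen models combining
    environment, line and genomic main effects with naive (line-by-environment)
    and marker-informed (genomic-by-environment) Hadamard-product interaction
    kernels, estimates variance components and genomic breeding values by a
    multi-kernel Gaussian Gibbs sampler, and assesses within-environment
    prediction accuracy under three cross-validation schemes: leave-one-
    environment-out (CV0), prediction of untested lines (CV1) and sparse
    testing (CV2). A synthetic-data generator with known variance components
    supports testing and parameter-recovery studies.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
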