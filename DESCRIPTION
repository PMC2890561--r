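Package: ldnr
Title: Linkage Disequilibrium Inference from Non-Random and Case-Control Samples
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the linkage-disequilibrium
    coefficient D between two biallelic loci from unphased genotype counts.
    Implements a conditional-likelihood estimator (disease genotype given
    marker genotype) that is robust to ascertained, truncated and
    case-control sampling designs, alongside the classical joint-likelihood
    estimator based on EM "chromosome counting" and the Weir-Cockerham cubic.
    Includes likelihood-ratio/LOD significance tests, a disease-allele
    frequency profile search, Monte-Carlo samplers for three sampling
    schemes (random, genotype-class truncated, case-control), a pairwise
    LD-scan driver for genotype matrices, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
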