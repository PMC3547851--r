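Package: breedscan
Title: Breed-Level Selection-Signature Scans from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome-wide scans for breed-specific targets of selection in
    multi-breed diploid SNP panels. Implements windowed pairwise
    Weir-Cockerham F_ST and the locus-specific divergence statistic d_i
    with empirical-percentile outlier calling, method-of-moments pi-hat
    relatedness estimation and greedy pruning, exact-match extended
    haplotype sharing across breeds with variant-haplotype concordance
    testing, and additive-genotype association of candidate variants with
    muscle fiber-type composition (MANOVA, multiple regression, LS-means
    with Fisher's LSD grouping). A Balding-Nichols multi-breed simulator
    with sweep injection, relative spiking and fiber-type phenotype
    generation provides fully reproducible synthetic datasets with known
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    data.table,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    jsonlite,
    withr
Config/testthat/edition: 3
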