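Package: divergescan
Title: Windowed Divergence, Selection and Copy-Number Scans for Diverging Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for population-genomic divergence scans between
    recently diverged populations. Implements invariant-site-aware windowed
    nucleotide diversity (pi), absolute divergence (dXY) and Weir-Cockerham
    FST from all-sites VCFs; the three-population branch statistic (PBS)
    selection scan with quantile outlier detection; copy-number variant
    differentiation (presence-allele FST and VST) with dual-caller
    cross-validation by length overlap; sex-chromosome-aware processing
    (Y haploidization, pseudoautosomal-region partitioning); genotype PCA;
    and AIC-based comparison of demographic-model fits with conversion of
    diffusion-scaled parameters to natural units. Ships a Balding-Nichols
    population simulator with known truth so every stage is testable
    without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
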