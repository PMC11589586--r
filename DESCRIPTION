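Package: hbdload
Title: Homozygosity-by-Descent Inference and Genetic-Load Statistics for
    Population Genomic Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based inference of homozygosity-by-descent (HBD) segments
    from biallelic SNP genotypes using a multi-class hidden Markov model with
    age-stratified segment-length classes, giving per-individual inbreeding
    coefficients (F_HBD), allele-sharing inbreeding coefficients (F_AS) and
    their contrast to diagnose the temporal origin of inbreeding. Also
    provides nucleotide diversity and effective population size with block
    bootstrap uncertainty, genome-wide autozygosity landscapes with HBD
    island/desert calling and gene-density association, and the R_XY family
    of minor-allele load ratios with block-jackknife standard errors. A
    synthetic genotype-panel generator with planted HBD tracts, population
    divergence, family structure and category-specific load asymmetries
    supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
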