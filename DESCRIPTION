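Package: bovfat
Title: Genomic Analysis of Visceral Fat and Metabolic Health in Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting additive and non-additive genetic effects on
    binary traits in dairy cattle. Implements a two-step mixed-model genome scan
    with additive, dominance, recessive and overdominance genotype codings;
    SNP-to-gene assignment and Fisher's exact gene-set overrepresentation;
    pedigree (A), genomic (G, VanRaden method 1) and combined single-step (H)
    relationship matrices; a Bayesian threshold (probit) animal model for
    repeated binary health records fitted by Gibbs sampling with
    latent-liability augmentation; back-solution of SNP effects from genomic
    breeding values and 2.0 Mb window variance decomposition. Includes a
    synthetic-data generator emulating extreme-group binary phenotypes, QTL with
    non-additive gene action, multi-generation pedigrees and repeated
    low-incidence health records, so every stage can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    IRanges,
    S4Vectors,
    vcfR,
    methods,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    rtracklayer,
    fgsea,
    jsonlite
Config/testthat/edition: 3
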