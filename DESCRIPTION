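Package: spermnet
Title: Systems-Biology Integration of Multi-Trait GWAS and Sperm RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for dissecting the molecular basis of
    semen-quality traits by integrating genotype and sperm RNA-seq data:
    genotype quality control, mixed-linear-model genome-wide association with
    a genomic relationship matrix, GREML heritability, expression filtering
    and trait-abundance correlation screens, expression GWAS with a
    phenotype-anchored double filter, associated weight matrix (AWM)
    construction around a key phenotype, PCIT partial-correlation network
    inference for SNP co-association and RNA co-abundance networks, network
    intersection and augmentation, and RNA/SNP phenotype-prediction panels.
    Includes a synthetic-data generator that emulates the study design
    (LD-blocked genotypes, 25 correlated semen traits, planted QTL, eQTL and
    expression-trait correlations) so that every stage is testable without
    access to the original animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
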