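Package: demosel
Title: Two-Population Divergence Modelling and Selective-Sweep Scans for
    Whole-Genome SNP Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the population-genomic analysis of multi-population
    SNP data from whole-genome resequencing: site/genotype/sample quality
    control and allele polarization, windowed diversity and differentiation
    statistics (nucleotide diversity, Tajima's D, Hudson's FST with
    block-jackknife, runs of homozygosity, identity-by-descent tracts, site
    frequency spectra with hypergeometric projection), principal component
    analysis and a permutation test of panmixia on the joint site frequency
    spectrum, diffusion-based fitting of eight two-population divergence
    models (strict isolation, continuous migration, ancient migration and
    secondary contact, each with or without exponential size change) with
    AIC model choice and parametric-bootstrap confidence intervals,
    haplotype-based selection scans (Garud H statistics, EHH and XP-EHH with
    candidate-region calling), and demography-aware five-class selective
    sweep classification from simulated training data. A built-in coalescent
    and forward-in-time simulator generates synthetic genotypes, haplotypes
    and sweep regions so every stage can be exercised and validated without
    access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml,
    xgboost
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Coverage, Sequencing, Software
RoxygenNote: 7.3.3
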