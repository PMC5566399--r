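Package: azrate
Title: Mutation and Gene-Conversion Rate Estimation from Autozygous Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-generational estimation of the coding de novo mutation rate
    and the non-crossover gene-conversion rate from heterozygous genotype calls
    observed inside long autozygous segments of individuals with consanguineous
    parents. Provides pedigree recombination simulation over a genetic map,
    supervised inference of the number of separating meioses from autozygous
    segment-length distributions, joint estimation of genotype false-positive
    and false-negative rates from duplicate-sample replication curves and
    spike-in recall simulation, minor-allele-frequency threshold regression
    separating mutation (intercept) from gene conversion (slope), trinucleotide
    mutational-spectrum classification and population comparison, and a fully
    labelled synthetic-cohort generator for end-to-end validation against
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
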