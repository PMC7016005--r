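Package: enuscan
Title: Forward-Genetics Mapping of Dominant ENU-Induced Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for mapping dominant causal alleles from
    N-ethyl-N-nitrosourea (ENU) mutagenesis screens in the mouse. Implements
    candidate-variant filtering from affected/unaffected exome variant calls
    (read support, heterozygous allelic-fraction band, functional annotation
    class), pedigree co-segregation exclusion mapping over +/-/? genotype
    panels, backcross disassociation checks, penetrance and expressivity
    statistics, and Chou-Fasman alpha-helix propensity profiling for ranking
    the structural impact of candidate missense mutations. A synthetic
    ENU-screen simulator (Poisson mutation load, Mendelian transmission,
    configurable penetrance, binomial read sampling, missing-at-random
    genotyping) exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
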