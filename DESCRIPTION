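Package: dnmrate
Title: De Novo Mutation Discovery and Rate Estimation in Sequenced Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies de novo single-nucleotide and short indel mutations in
    father-mother-child trios from multi-sample VCF genotypes via Mendelian
    violations with conservative site and individual quality filters, and
    partitions candidates into germline and putative somatic classes by allele
    balance. Estimates the per-nucleotide per-generation mutation rate with a
    probabilistic denominator: depth-stratified genotype callability is
    calibrated from informative polymorphic sites and summed over the genome,
    corrected for the expected site-filter loss. Provides exact (Garwood)
    Poisson confidence intervals, a paternal-age regression, a
    homopolymer/tandem-repeat indel context classifier, a Sanger validation
    tally, and a seeded synthetic trio-cohort simulator with known truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    vcfR,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
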