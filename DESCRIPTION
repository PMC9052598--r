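Package: herdstat
Title: Population Genetics of Livestock Breeds: Diversity, Inbreeding and
    Selection Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the population-genetic characterisation of small
    livestock populations from pedigree, microsatellite and SNP data.
    Computes pedigree inbreeding coefficients, per-generation inbreeding
    rates and effective population size; per-locus and per-population
    diversity statistics (heterozygosities, effective allele numbers,
    polymorphism information content, null and private alleles, nucleotide
    diversity); multiallelic Weir-Cockerham F-statistics and Nei genetic
    distances; Rosenberg informativeness for assignment; Mantel tests and
    isolation-by-distance correlograms; runs of homozygosity (ROH), genomic
    inbreeding (F_ROH) and ROH islands; linkage-disequilibrium based
    historical effective population size trajectories; and within-population
    EHH/iHS selection scans. Includes forward-in-time simulators of
    pedigrees, drifted breeds and recombining haplotypes with known ground
    truth, plus readers and writers for PLINK PED/MAP, VCF and Genepop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
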