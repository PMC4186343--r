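Package: hlagdiv
Title: HLA-G Haplotype Diversity from Low-Coverage Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying worldwide HLA-G haplotype diversity from
    low-coverage sequencing data. Implements the HLA-G gene model with
    CDS-anchored coordinates and variant effect annotation, depth-based
    genotype refinement rules for allele-depth (AD) records, EM haplotype
    phasing with partition-ligation and missing-allele imputation, haplotype
    nomenclature assignment against bundled reference tables (promoter
    lineages, coding alleles, 3'UTR haplotypes and extended haplotypes), and
    population-genetics statistics: gene/haplotype/nucleotide diversity,
    private haplotypes, Guo-Thompson exact tests of Hardy-Weinberg
    equilibrium, pairwise FST with permutation p-values, exact tests of
    population differentiation, Reynolds distance, hierarchical AMOVA and
    classical multidimensional scaling. A synthetic-cohort generator emulates
    1000Genomes-like low-coverage allele-depth observations of diplotypes
    drawn from the bundled frequency tables so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, vcfR, seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
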