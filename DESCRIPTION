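Package: founderhap
Title: Founder Haplotype Reconstruction and Rare Biallelic Genotype Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs local ancestral (founder) haplotypes around a rare
    disease allele from small-cohort genotype data. Implements the multistep
    rare-variant filter that yields biallelic candidate genotypes per affected
    individual (homozygous, compound heterozygous in trans, or heterozygous
    opposite a multigene deletion, i.e. hemizygous), pedigree-based phasing of
    informative SNVs in a window around the target gene, hemizygosity anchoring
    over a whole-gene deletion, cross-family shared-core detection with
    per-family recombination breakpoint sides, and direct variant interrogation
    for singletons that cannot be phased. Ships a synthetic cohort generator
    with a machine-readable truth ledger for validating the pipeline, plus
    cohort genotype and phenotype tabulation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
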