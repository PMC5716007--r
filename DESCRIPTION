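Package: exomeFreq
Title: Cohort Allele-Frequency Shift Detection from Exome VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects SNP alleles whose frequency in a small phenotype cohort
    (tens to hundreds of exomes) differs significantly from a reference
    population catalogue. Aggregates per-individual exome VCFs over a
    catalogue of common SNPs, counts alleles with sex-aware ploidy
    (hemizygous X and Y handling with pseudoautosomal regions), verifies
    sample sex from X-chromosome heterozygosity, applies a per-base read
    depth cutoff, computes cohort rare-allele frequencies with upper and
    lower bounds under missing data, and tests each SNP against the
    catalogue frequency with a two-tailed chi-squared test without Yates'
    continuity correction, with Bonferroni and Benjamini-Hochberg
    correction. Includes a protein-altering consequence filter, a power
    simulation comparing the cohort-versus-catalogue design to a
    case-control association design, a per-exon/per-gene coverage census,
    and a synthetic fixture generator producing VCFs, catalogues, depth
    tables and annotations with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
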