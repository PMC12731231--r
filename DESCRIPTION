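Package: HLAensemble
Title: Ensemble Two-Field HLA Genotyping with HLA-Targeted Read Filtering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rapid, high-confidence HLA genotyping from short-read
    sequencing data. Builds combined genomic+cDNA HLA reference sets
    (All-HLA or restricted to the nine classical loci), filters paired-end
    FASTQ reads to the HLA region by shared k-mer matching with single-end
    mate rescue, ingests and normalizes two-field allele calls from four
    HLA-typing tools (OptiType, Polysolver, ATHLATES, seq2HLA) across
    normal-exome, tumor-exome and tumor RNA-seq sources, and integrates
    them into unanimous, consensus or ambiguous genotype calls. Includes
    concordance, call-diversity and quality-retention statistics, plus a
    fully labeled synthetic-data generator (reference, diploid cohort,
    paired reads, tool call tables) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Genetics, Sequencing, Alignment, ImmunoOncology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
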