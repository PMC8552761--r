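Package: haplodiff
Title: Haplotype-Pair Comparative Genomics and Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two haplotype-resolved haploid genome assemblies of a
    dikaryotic fungus end to end: classifies the variants that separate them
    (SNPs, indels and structural variants under the 50-bp size rule), overlays
    variants on gene models to call conserved and variable genes and
    haplotype-specific genes, resolves one-to-one allelic pairs, duplication
    groups and tandem clusters for a gene family from protein alignments,
    calls differentially expressed genes with fixed fold-change and p-value
    thresholds and intersects them across condition designs, quantifies
    allele-specific expression from read depth at allele-distinguishing SNP
    loci with allele-dominance calls, and runs degenerate-primer in-silico PCR
    with clone-to-copy assignment. A bundled synthetic diploid-genome
    generator plants all of these structures with machine-readable ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    DESeq2,
    limma,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
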