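Package: lincRNAkit
Title: Discovery and Epigenomic Profiling of Long Intergenic Noncoding RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for defining long intergenic noncoding RNAs (lincRNAs)
    from assembled transcript models and for characterising their expression
    and epigenomic signatures. Implements the multi-step lincRNA filter
    cascade (exon coverage, splice-junction support, transcript structure,
    intergenic position, coding potential, housekeeping-RNA exclusion),
    Jensen-Shannon tissue-specificity scoring of expression matrices,
    transcription-start-site-centred metaprofiles of bisulfite methylation,
    transcription-factor binding intensity, GC content and CpG
    observed/expected ratio, and overlap of differentially methylated
    regions with gene loci, including a naive differential-methylation
    caller. A seeded synthetic-data generator produces miniature genomes,
    annotations, expression matrices, methylation call sets and binding
    tracks with known ground truth so that the whole analysis can be
    exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, Epigenetics, DNAMethylation, GeneRegulation,
    Sequencing, Software
RoxygenNote: 7.3.3
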