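Package: nucleodyn
Title: Differential Nucleosome Occupancy, Repositioning and Chromatin
    Contacts from MNase-seq Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of nucleosome dynamics between two
    MNase-seq time points. Implements a windowed, normalized
    log-likelihood-ratio occupancy statistic whose null distribution is
    estimated empirically from transcriptionally inert genomic regions;
    multi-scale depletion/enrichment domain calling; nucleosome dyad
    calling from fragment midpoints with classification of repositioning
    events (>10 bp dyad shifts); length-normalized metagene occupancy
    profiles over expression-classed genes; transcription-factor peak
    embedding and Fisher association tests; and viewpoint contact
    domainograms (2-200 kbp sliding windows) with permutation-based FDR
    control. A seeded synthetic-data generator producing phased
    nucleosome arrays, planted occupancy changes and dyad shifts, gene
    classes, TF peaks and viewpoint contact profiles supports end-to-end
    validation and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    DESeq2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
biocViews: Epigenetics, NucleosomePositioning, Sequencing, Coverage,
    FunctionalGenomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
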