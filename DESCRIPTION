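Package: methBind
Title: Discovery and Characterization of Methyl-CpG-Dependent
    Transcription Factor Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to discover and characterize transcription factors that
    preferentially bind methylated CpG (mCpG) DNA motifs. Implements
    protein-microarray competition-assay analysis (local window-median
    normalization, mirrored-shadow background noise estimation, Z-score hit
    calling with a duplicate-spot rule), integration of methylated and
    unmethylated protein-DNA interaction screens, mCpG-centered 6-mer
    clustering into consensus motifs, ChIP-seq x whole-genome methylome
    central-CpG k-mer enrichment with hypergeometric tests, 1:1 Langmuir
    kinetic fitting of label-free sensorgrams (k_on, k_off, K_D), and
    ChIP-bisulfite methylation comparison with binomial tail tests. Ships
    seeded synthetic-data generators emulating each input so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Transcription, MotifDiscovery,
    ChIPSeq, Microarray
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
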