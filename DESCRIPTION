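Package: cpgtraffic
Title: CpG Traffic Lights: Single-Cytosine Methylation-Expression Correlation
    and Selection Against Methylation-Sensitive CpGs in TF Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links single-CpG methylation profiles across cell-type classes to
    the expression profiles of nearby transcription start sites (TSSs) and
    quantifies selection against methylation-sensitive CpGs ("traffic lights",
    cytosines whose methylation correlates significantly negatively with TSS
    expression) inside transcription factor binding sites. Binding sites are
    predicted with position weight matrices (PWMs) and remote dependency
    models (RDMs) calibrated to an exact random-word P-value; CpG-containing
    motif positions are stratified into core and flanking classes by discrete
    information content. Includes a synthetic methylome-transcriptome
    generator with planted correlations and planted binding-site depletion so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
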