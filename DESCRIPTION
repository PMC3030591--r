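Package: solidtags
Title: SOLiD Color-Space Tag Mapping and Two-Library Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of SOLiD color-space transcriptome tag
    libraries. Provides di-base ("color-space") encoding and decoding, an
    exon-junction reference database, a complete seeded alignment cascade with
    iterative 3' trimming (35/30/25 colors), rRNA and quality filtering, RPKM
    quantification with exon/intron/antisense tag assignment, an exact
    conditional binomial test for two-library differential expression under the
    random-sampling model, and chromosome coverage and category reports. A
    synthetic-data generator emits annotated genomes and stranded tag libraries
    with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stringi,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
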