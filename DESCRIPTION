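Package: msrpipe
Title: Sex-Linked Region Detection, Methylation and Regulatory Networks for
    Telomere-to-Telomere Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sex determination on complete (telomere-to-
    telomere) plant genome assemblies. Annotates telomeric heptamer arrays and
    centromeric tandem-repeat monomers; detects and delimits a male-specific
    region from sexed resequencing data using windowed Hudson FST, nucleotide
    diversity, read-depth contrast and penalised changepoint segmentation;
    estimates gene copy number from depth; summarises CG/CHG/CHH cytosine
    methylation at site, gene, region and metagene resolution from per-cytosine
    read-support calls; and builds sex-resolved gene regulatory networks via
    Pearson correlation, mutual-rank scoring, promoter motif scanning and
    Fisher enrichment. A deterministic simulator generates every input with
    planted, recorded ground truth so the whole pipeline is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
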