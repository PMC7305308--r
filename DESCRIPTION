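Package: cdrseq
Title: Alignment-Free Assembly of Immunoglobulin CDR3 Clonotypes from RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs B-cell receptor CDR3 repertoires from bulk RNA-Seq
    reads without alignment to a reference genome. Candidate reads (unmapped or
    soft-clipped at the immunoglobulin loci, or raw FASTQ) are scanned in six
    frames for putative CDR3 spans delimited by the conserved cysteine of V
    segments and the conserved phenylalanine/tryptophan of J segments; spans are
    validated by bounded edit-distance matching of read context against germline
    anchor-split substrings, partial-CDR3 reads are merged on exact nucleotide
    overlap, and PCR/sequencing errors are corrected by CAST graph clustering
    with weighted consensus calling. Includes a ground-truth V(D)J transcript
    and read simulator, precision/recall evaluation, and repertoire diversity
    statistics (CPM, Shannon alpha-diversity, Sorensen-Dice beta-diversity,
    public/private sharing, cell-type signature scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
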