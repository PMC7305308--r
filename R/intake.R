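# Candidate-read intake: produce the read set admitted to assembly, from FASTQ
# or from a coordinate-sorted BAM (reads overlapping the Ig loci, including
# soft-clipped alignments, plus all unmapped reads), then apply quality and
# complexity filters.

#' Read candidate reads from a FASTQ file
#'
#' @param path FASTQ file (optionally gzipped).
#' @return A `data.frame` with columns `read_id`, `nt_seq`, `qual` (character,
#'   `NA` when absent), `origin`, `mate`.
#' @export
read_candidates_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(set)$qualities
  data.frame(
    read_id = names(set),
    nt_seq = as.character(set),
    qual = if (is.null(q)) NA_character_ else as.character(q),
    origin = "direct_fastq",
    mate = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Extract candidate receptor reads from an alignment file
#'
#' Emits (a) reads whose alignments overlap the supplied immunoglobulin locus
#' intervals — soft-clipped alignments included, with the full original read
#' sequence as stored in the BAM — and (b) all unmapped reads. Duplicate
#' emissions of the same read/mate are removed.
#'
#' @param path Indexed, coordinate-sorted BAM file.
#' @param ig_regions Ig locus intervals: a `GRanges`, or the path to a BED file.
#' @return Candidate read `data.frame` (see [read_candidates_fastq()]), with
#'   `origin` set to `"ig_mapped_clipped"` or `"unmapped"`.
#' @export
extract_candidates_bam <- function(path, ig_regions) {
  if (!file.exists(path)) stop("BAM not found: ", path)
  if (!file.exists(paste0(path, ".bai")) && !file.exists(sub("\\.bam$", ".bai", path)))
    stop("BAM index (.bai) not found for ", path)
  if (is.character(ig_regions)) ig_regions <- read_bed(ig_regions)

  what <- c("qname", "flag", "seq", "qual")
  mapped <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    which = ig_regions, what = what,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  ))
  unmapped <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = what,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)
  ))

  collect <- function(chunks, origin) {
    parts <- lapply(chunks, function(ch) {
      if (length(ch$qname) == 0L) return(NULL)
      data.frame(
        read_id = ch$qname,
        nt_seq = as.character(ch$seq),
        qual = as.character(ch$qual),
        origin = origin,
        mate = ifelse(bitwAnd(ch$flag, 64L) > 0L, 1L,
               ifelse(bitwAnd(ch$flag, 128L) > 0L, 2L, NA_integer_)),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, parts[!vapply(parts, is.null, logical(1L))])
  }
  out <- rbind(collect(mapped, "ig_mapped_clipped"), collect(unmapped, "unmapped"))
  if (is.null(out) || nrow(out) == 0L) {
    warning("no candidate reads extracted; repertoire will be empty")
    return(data.frame(read_id = character(), nt_seq = character(), qual = character(),
                      origin = character(), mate = integer(), stringsAsFactors = FALSE))
  }
  out <- out[!duplicated(paste(out$read_id, out$mate)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Minimal BED reader (chrom, start, end; 0-based half-open) -> GRanges.
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  GenomicRanges::GRanges(bed[[1L]], IRanges::IRanges(bed[[2L]] + 1L, bed[[3L]]))
}

# Dinucleotide Shannon entropy (bits) per read; the low-complexity screen.
dinucleotide_entropy <- function(seqs) {
  set <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::dinucleotideFrequency(set)
  tot <- rowSums(counts)
  tot[tot == 0L] <- 1L
  p <- counts / tot
  ifelse(rowSums(counts) == 0L, 0, -rowSums(ifelse(p > 0, p * log2(p), 0)))
}

# Mean Phred quality per read from an ASCII (offset 33) quality string.
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Filter low-quality and low-complexity candidate reads
#'
#' Drops reads with mean base quality below `min_qual` (only when qualities are
#' present), reads whose dinucleotide Shannon entropy falls below `min_entropy`
#' bits (a cheap DUST-like low-complexity screen), and — optionally — reads
#' sharing an exact 31-mer with a user-supplied rRNA FASTA.
#'
#' @param reads Candidate read `data.frame`.
#' @param min_qual Minimum mean Phred quality (default 20).
#' @param min_entropy Minimum dinucleotide entropy in bits (default 1).
#' @param rrna_fasta Optional rRNA FASTA path; `NULL` (default) disables the
#'   rRNA screen.
#' @return The surviving subset of `reads`.
#' @export
quality_filter <- function(reads, min_qual = 20, min_entropy = 1, rrna_fasta = NULL) {
  if (nrow(reads) == 0L) return(reads)
  keep <- rep(TRUE, nrow(reads))
  if (!all(is.na(reads$qual))) {
    mq <- mean_phred(reads$qual)
    keep <- keep & (is.na(mq) | mq >= min_qual)
  }
  keep <- keep & dinucleotide_entropy(reads$nt_seq) >= min_entropy
  if (!is.null(rrna_fasta)) {
    ref <- Biostrings::readDNAStringSet(rrna_fasta)
    kmers <- unique(unlist(lapply(as.character(ref), function(s) {
      n <- nchar(s)
      if (n < 31L) return(character())
      substring(s, 1:(n - 30L), 31:n)
    })))
    idx <- which(keep & nchar(reads$nt_seq) >= 31L)
    if (length(idx) && length(kmers)) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
      hits <- Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(reads$nt_seq[idx]))
      keep[idx[colSums(hits) > 0L]] <- FALSE
    }
  }
  reads[keep, , drop = FALSE]
}
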