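# Ground-truth simulator: synthetic germline segment sets, V(D)J-recombined
# transcripts with non-templated junction insertions and exonucleolytic
# trimming, substitution-error paired-end reads with a truth manifest, and
# decoy RNA-Seq mixtures.

AA20 <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character())

# Reverse-translate an amino-acid string, sampling uniformly among synonymous
# codons (seeded by the caller's RNG state).
reverse_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(aa, "")[[1]], function(a) {
    sample(names(gc)[gc == a], 1L)
  }, character(1L)), collapse = "")
}

random_nt <- function(n, gc_content = 0.5) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a synthetic germline segment set
#'
#' Generates a miniature germline for testing and simulation: V segments of
#' `v_len_aa` residues with a planted upstream cysteine and the conserved
#' anchor cysteine three residues from the end, J segments with the conserved
#' phenylalanine/tryptophan at position 2 (0-based), and random-nucleotide D
#' segments (IGH only). Nucleotide sequences are uniform random synonymous
#' codons, so the set is entirely synthetic — it mimics the anchor geometry of
#' real IMGT segments, not their sequence content.
#'
#' @param chains Chains to generate.
#' @param n_v,n_d,n_j Segments per class and chain.
#' @param v_len_aa,j_len_aa V/J lengths in amino acids.
#' @param d_len_range D segment nucleotide length range (IGH).
#' @param seed Optional RNG seed.
#' @return Germline `data.frame` in the [read_germline()] layout.
#' @export
simulate_germline <- function(chains = "IGH", n_v = 8L, n_d = 6L, n_j = 4L,
                              v_len_aa = 96L, j_len_aa = 16L,
                              d_len_range = c(12L, 21L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (chn in chains) {
    end_res <- anchor_residue("J", chn)
    for (i in seq_len(n_v)) {
      aa <- sample(setdiff(AA20, "C"), v_len_aa, replace = TRUE)
      aa[22L] <- "C"              # upstream framework cysteine
      aa[v_len_aa - 2L] <- "C"    # conserved anchor: last C, 2 residues follow
      aa <- paste(aa, collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%sV%d-S", chn, i), chain = chn, class = "V",
        nt_seq = reverse_translate(aa), stringsAsFactors = FALSE
      )
    }
    if (chn == "IGH") {
      for (i in seq_len(n_d)) {
        len <- sample(d_len_range[1L]:d_len_range[2L], 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("IGHD%d-S", i), chain = chn, class = "D",
          nt_seq = random_nt(len), stringsAsFactors = FALSE
        )
      }
    }
    for (i in seq_len(n_j)) {
      aa <- sample(setdiff(AA20, c("F", "W")), j_len_aa, replace = TRUE)
      aa[3L] <- end_res           # conserved anchor: first F/W at 0-based pos 2
      aa <- paste(aa, collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%sJ%d-S", chn, i), chain = chn, class = "J",
        nt_seq = reverse_translate(aa), stringsAsFactors = FALSE
      )
    }
  }
  germ <- do.call(rbind, rows)
  # run through the loader logic to attach translations and anchor splits
  germ$aa_seq <- NA_character_
  germ$anchor_pos <- NA_integer_
  germ$pre_anchor <- NA_character_
  germ$post_anchor <- NA_character_
  vj <- germ$class %in% c("V", "J")
  for (i in which(vj)) {
    aa <- translate_nt(germ$nt_seq[i])
    pos <- locate_anchor(aa, germ$class[i], germ$chain[i])
    sp <- anchor_split(aa, pos)
    germ$aa_seq[i] <- aa
    germ$anchor_pos[i] <- pos
    germ$pre_anchor[i] <- sp$pre
    germ$post_anchor[i] <- sp$post
  }
  germ
}

# Truncated-at-zero rounded Gaussian draw.
trunc_norm_int <- function(n, mean, sd) pmax(0L, as.integer(round(stats::rnorm(n, mean, sd))))

#' Simulate ground-truth V(D)J-recombined transcripts
#'
#' Uniformly samples V, (D,) and J segments, inserts non-templated junction
#' sequences of truncated-Gaussian length, applies exonucleolytic trimming to
#' the joining segment ends (V 3', both D ends, J 5'), and rejection-samples
#' until `n` in-frame transcripts are obtained (the junction must keep the J
#' anchor in the V reading frame and the CDR3 span must be stop-free).
#' Relative abundances follow a power law over the transcript rank.
#'
#' @param germline Germline `data.frame` with V/(D/)J segments for `chain`.
#' @param n Number of in-frame transcripts.
#' @param chain Chain to recombine (default IGH).
#' @param ins_mean,ins_sd Junction insertion length distribution
#'   (nucleotides; truncated rounded Gaussian, defaults 15 and 4).
#' @param trim_mean,trim_sd Exonucleolytic trimming per segment end
#'   (|Gaussian|, defaults 4 and 3; capped so anchors survive).
#' @param exponent Power-law exponent for abundances (default 1, Zipf;
#'   0 gives uniform abundances).
#' @param seed Optional RNG seed.
#' @return `data.frame` with one row per transcript: segment ids, junction
#'   sequences, `full_nt`, 0-based CDR3 nucleotide span (`cdr3_start`,
#'   `cdr3_end`), `true_cdr3_aa`, `true_cdr3_nt`, the junction-insert
#'   interval (`junction_start`, `junction_end`, 0-based half-open) and
#'   `abundance`.
#' @export
simulate_transcripts <- function(germline, n = 200L, chain = "IGH",
                                 ins_mean = 15, ins_sd = 4,
                                 trim_mean = 4, trim_sd = 3,
                                 exponent = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- germline[germline$chain == chain & germline$class == "V" &
                  !is.na(germline$anchor_pos), , drop = FALSE]
  j <- germline[germline$chain == chain & germline$class == "J" &
                  !is.na(germline$anchor_pos), , drop = FALSE]
  d <- germline[germline$chain == chain & germline$class == "D", , drop = FALSE]
  has_d <- nrow(d) > 0L
  if (nrow(v) == 0L || nrow(j) == 0L) stop("need V and J segments for ", chain)

  draws <- 0L
  out <- vector("list", n)
  accepted <- 0L
  while (accepted < n) {
    draws <- draws + 1L
    if (draws > max(10000L, 100L * n)) {
      stop("rejection rate too high while sampling in-frame transcripts; ",
           "check germline/configuration")
    }
    vi <- sample.int(nrow(v), 1L)
    ji <- sample.int(nrow(j), 1L)
    di <- if (has_d) sample.int(nrow(d), 1L) else NA_integer_

    n1 <- trunc_norm_int(1L, ins_mean, ins_sd)
    n2 <- if (has_d) trunc_norm_int(1L, ins_mean, ins_sd) else 0L
    tv <- min(abs(trunc_norm_int(1L, trim_mean, trim_sd)), 6L)
    tj <- min(abs(trunc_norm_int(1L, trim_mean, trim_sd)), 6L)

    v_nt <- v$nt_seq[vi]
    v_used <- substr(v_nt, 1L, nchar(v_nt) - tv)
    j_nt <- j$nt_seq[ji]
    j_used <- substr(j_nt, tj + 1L, nchar(j_nt))
    d_used <- ""
    if (has_d) {
      d_nt <- d$nt_seq[di]
      cap <- max(0L, (nchar(d_nt) - 3L) %/% 2L)
      td1 <- min(abs(trunc_norm_int(1L, trim_mean, trim_sd)), cap)
      td2 <- min(abs(trunc_norm_int(1L, trim_mean, trim_sd)), cap)
      d_used <- substr(d_nt, td1 + 1L, nchar(d_nt) - td2)
    }
    ins1 <- random_nt(n1)
    ins2 <- if (has_d) random_nt(n2) else ""

    full <- paste0(v_used, ins1, d_used, ins2, j_used)
    c_start <- 3L * v$anchor_pos[vi]                       # C codon, 0-based
    j_off <- nchar(v_used) + n1 + nchar(d_used) + n2       # J start in transcript
    f_start <- j_off + 3L * j$anchor_pos[ji] - tj          # F/W codon, 0-based
    if (f_start <= c_start || (f_start - c_start) %% 3L != 0L) next
    cdr3_nt <- substr(full, c_start + 1L, f_start + 3L)
    cdr3_aa <- translate_nt(cdr3_nt)
    if (grepl("*", cdr3_aa, fixed = TRUE)) next            # out-of-frame protein
    end_res <- anchor_residue("J", chain)
    if (substr(cdr3_aa, 1L, 1L) != "C" ||
        substr(cdr3_aa, nchar(cdr3_aa), nchar(cdr3_aa)) != end_res) next

    accepted <- accepted + 1L
    out[[accepted]] <- data.frame(
      transcript_id = sprintf("tx%04d", accepted),
      v_id = v$id[vi], d_id = if (has_d) d$id[di] else NA_character_,
      j_id = j$id[ji], n1_nt = ins1, n2_nt = ins2,
      full_nt = full, cdr3_start = c_start, cdr3_end = f_start + 2L,
      true_cdr3_aa = cdr3_aa, true_cdr3_nt = cdr3_nt,
      junction_start = nchar(v_used), junction_end = j_off,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  w <- seq_len(n)^(-exponent)
  res$abundance <- w / sum(w)
  res
}

# Vectorised substitution errors at a per-base rate; substituted bases are
# always different from the original.
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

revcomp_chr <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Simulate paired-end reads from ground-truth transcripts
#'
#' Per transcript, the number of read mates is `round(coverage * length /
#' read_length)` — coverage is the expected per-base depth contributed by all
#' mates — emitted as fragment pairs with uniform fragment placement and
#' substitution errors at `error_rate` per base. The truth manifest records,
#' per mate, the source transcript, its true CDR3, and whether the mate
#' overlaps the non-templated junction region.
#'
#' @param transcripts Output of [simulate_transcripts()].
#' @param read_length Read length in nucleotides (e.g. 50, 75, 100).
#' @param coverage Expected per-base depth per transcript.
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param weight_by_abundance Scale each transcript's coverage by
#'   `abundance * n_transcripts` instead of covering every transcript at
#'   `coverage` (default `FALSE`, matching a per-transcript coverage design).
#' @param seed Optional RNG seed.
#' @return List with `reads` (`read_id`, `nt_seq`, `qual`, `origin`, `mate`)
#'   and `manifest` (`read_id`, `transcript_id`, `mate`, `start`, `end`
#'   1-based transcript coordinates, `true_cdr3_aa`, `contains_junction`).
#' @export
simulate_reads <- function(transcripts, read_length = 75L, coverage = 8,
                           error_rate = 0.001, weight_by_abundance = FALSE,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  l <- as.integer(read_length)
  n_tx <- nrow(transcripts)
  reads <- list(); manifest <- list()
  for (t in seq_len(n_tx)) {
    tx <- transcripts[t, ]
    len <- nchar(tx$full_nt)
    if (l > len) stop("read length exceeds transcript length for ", tx$transcript_id)
    cov_t <- if (weight_by_abundance) coverage * tx$abundance * n_tx else coverage
    n_mates <- as.integer(round(cov_t * len / l))
    n_pairs <- as.integer(ceiling(n_mates / 2))
    if (n_pairs == 0L) next
    frag <- pmin(len, pmax(l, as.integer(round(stats::rnorm(n_pairs, 1.8 * l, 0.12 * l)))))
    start <- as.integer(floor(stats::runif(n_pairs) * (len - frag + 1L))) + 1L
    r1 <- substring(tx$full_nt, start, start + l - 1L)
    r2 <- revcomp_chr(substring(tx$full_nt, start + frag - l, start + frag - 1L))
    ids <- sprintf("%s_p%03d", tx$transcript_id, seq_len(n_pairs))
    reads[[t]] <- data.frame(
      read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
      nt_seq = c(r1, r2), qual = NA_character_, origin = "direct_fastq",
      mate = rep(1:2, each = n_pairs), stringsAsFactors = FALSE
    )
    s1 <- start; e1 <- start + l - 1L
    s2 <- start + frag - l; e2 <- start + frag - 1L
    overlaps <- function(s, e) s <= tx$junction_end & e >= tx$junction_start + 1L
    manifest[[t]] <- data.frame(
      read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
      transcript_id = tx$transcript_id, mate = rep(1:2, each = n_pairs),
      start = c(s1, s2), end = c(e1, e2),
      true_cdr3_aa = tx$true_cdr3_aa,
      contains_junction = c(overlaps(s1, e1), overlaps(s2, e2)),
      stringsAsFactors = FALSE
    )
  }
  reads <- do.call(rbind, reads)
  manifest <- do.call(rbind, manifest)
  reads$nt_seq <- add_substitution_errors(reads$nt_seq, error_rate)
  rownames(reads) <- rownames(manifest) <- NULL
  list(reads = reads, manifest = manifest)
}

#' Generate a decoy transcript pool
#'
#' Random-composition transcripts standing in for a background transcriptome:
#' human-like GC content (42%) and lengths uniform in `len_range`. A real
#' transcriptome FASTA can be supplied to [make_mixture()] instead for
#' fidelity.
#'
#' @param n Number of decoy transcripts.
#' @param len_range Length range in nucleotides.
#' @param gc GC content.
#' @param seed Optional RNG seed.
#' @return Character vector of sequences (named `decoytx1..n`).
#' @export
simulate_decoy_pool <- function(n = 200L, len_range = c(500L, 3000L),
                                gc = 0.42, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  out <- vapply(lens, random_nt, character(1L), gc_content = gc)
  names(out) <- paste0("decoytx", seq_len(n))
  out
}

#' Mix receptor-derived reads with transcriptomic decoy reads
#'
#' Draws `ratio` decoy reads per receptor read from a decoy source (a
#' character vector of transcript sequences, a FASTA path, or the built-in
#' random pool when `NULL`), applies the same substitution error model, and
#' shuffles the combined set.
#'
#' @param receptor_reads Read `data.frame` from [simulate_reads()].
#' @param ratio Decoy reads per receptor read (default 100; real tissue
#'   RNA-Seq shows Ig-to-transcriptome read ratios around 1:3600).
#' @param decoy_source `NULL` (built-in pool), a named character vector of
#'   transcript sequences, or a FASTA path.
#' @param read_length Decoy read length (default: receptor read length).
#' @param error_rate Per-base substitution error rate for decoy reads.
#' @param seed Optional RNG seed.
#' @return List with `reads` (shuffled combined table) and `receptor_ids`.
#' @export
make_mixture <- function(receptor_reads, ratio = 100, decoy_source = NULL,
                         read_length = NULL, error_rate = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_rec <- nrow(receptor_reads)
  n_decoy <- as.integer(round(ratio * n_rec))
  if (is.null(read_length)) read_length <- max(nchar(receptor_reads$nt_seq))
  if (n_decoy > 0L) {
    pool <- if (is.null(decoy_source)) {
      simulate_decoy_pool()
    } else if (is.character(decoy_source) && length(decoy_source) == 1L &&
               file.exists(decoy_source)) {
      set <- Biostrings::readDNAStringSet(decoy_source)
      stats::setNames(as.character(set), names(set))
    } else {
      decoy_source
    }
    pool <- pool[nchar(pool) >= read_length]
    if (length(pool) == 0L) stop("decoy pool has no transcript >= read length")
    lens <- nchar(pool)
    tx <- sample.int(length(pool), n_decoy, replace = TRUE, prob = lens)
    start <- floor(stats::runif(n_decoy) * (lens[tx] - read_length + 1L)) + 1L
    seqs <- substring(pool[tx], start, start + read_length - 1L)
    seqs <- add_substitution_errors(seqs, error_rate)
    decoys <- data.frame(
      read_id = sprintf("decoy%07d", seq_len(n_decoy)), nt_seq = seqs,
      qual = NA_character_, origin = "direct_fastq", mate = NA_integer_,
      stringsAsFactors = FALSE
    )
    combined <- rbind(receptor_reads[, names(decoys)], decoys)
  } else {
    combined <- receptor_reads
  }
  combined <- combined[sample.int(nrow(combined)), , drop = FALSE]
  rownames(combined) <- NULL
  list(reads = combined, receptor_ids = receptor_reads$read_id)
}

#' Write a read table as FASTQ
#'
#' @param reads Read `data.frame` (`read_id`, `nt_seq`, optional `qual`).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
  qual <- ifelse(is.na(qual),
                 vapply(nchar(reads$nt_seq), function(n) strrep("I", n), character(1L)),
                 qual)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$nt_seq, "\n+\n", qual), con)
  invisible(path)
}
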