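# Shared fixtures and the independent brute-force stage-1 oracle.

fixture_germline_dir <- function() {
  system.file("extdata", "synthetic_germline", package = "cdrseq")
}

# Cached bundled germline (all three chains).
fixture_germline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_germline_dir(fixture_germline_dir(), quiet = TRUE)
    cache
  }
})

# Hand-built minimal germline rows for matcher unit tests.
toy_germline <- function() {
  v_aa <- "QLVESGGGLVQPGGSLRLSCAASYYYQSCAR"   # last C at 0-based 28
  j_aa <- "DYWGQGTLVTVSS"                     # first W at 0-based 2
  rev_tr <- function(aa) {
    gc <- Biostrings::GENETIC_CODE
    paste(vapply(strsplit(aa, "")[[1]], function(a) names(gc)[gc == a][1L],
                 character(1L)), collapse = "")
  }
  mk <- function(id, chain, class, aa) {
    nt <- rev_tr(aa)
    pos <- locate_anchor(aa, class, chain)
    sp <- anchor_split(aa, pos)
    data.frame(id = id, chain = chain, class = class, nt_seq = nt, aa_seq = aa,
               anchor_pos = pos, pre_anchor = sp$pre, post_anchor = sp$post,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("IGHV-toy1", "IGH", "V", v_aa),
    mk("IGHV-toy2", "IGH", "V", "QLVESGGGLVQPGGSLRLSCAASYYYQACAR"),
    mk("IGHJ-toy1", "IGH", "J", j_aa),
    mk("IGHJ-toy2", "IGH", "J", "DYWGQGALVTVSS")
  )
}

# Brute-force stage-1 oracle: every (frame, span, V, J) combination with full
# dynamic-programming edit distance via the reference R matchers. Independent
# of the compiled engine.
oracle_stage1 <- function(reads, germline, chain, min_core = 4L, max_core = 30L,
                          min_context = 5L, max_dist = 1L) {
  v <- germline[germline$chain == chain & germline$class == "V" &
                  !is.na(germline$anchor_pos), , drop = FALSE]
  j <- germline[germline$chain == chain & germline$class == "J" &
                  !is.na(germline$anchor_pos), , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(reads))) {
    frames <- six_frame_translate(reads$nt_seq[r])
    best <- NULL
    for (f in seq_along(frames)) {
      aa <- frames[f]
      spans <- scan_putative_cdr3(aa, chain, min_len = min_core, max_len = max_core)
      for (sidx in seq_len(nrow(spans))) {
        x <- spans$x[sidx]; y <- spans$y[sidx]
        prefix <- substr(aa, 1L, x)
        suffix <- substr(aa, y + 2L, nchar(aa))
        if (nchar(prefix) < min_context || nchar(suffix) < min_context) next
        vd <- vapply(v$pre_anchor, function(ctx) {
          k <- min(nchar(prefix), nchar(ctx))
          drop(utils::adist(substr(prefix, nchar(prefix) - k + 1L, nchar(prefix)),
                            substr(ctx, nchar(ctx) - k + 1L, nchar(ctx))))
        }, numeric(1L), USE.NAMES = FALSE)
        jd <- vapply(j$post_anchor, function(ctx) {
          k <- min(nchar(suffix), nchar(ctx))
          drop(utils::adist(substr(suffix, 1L, k), substr(ctx, 1L, k)))
        }, numeric(1L), USE.NAMES = FALSE)
        v_ok <- vd <= max_dist
        j_ok <- jd <= max_dist
        if (!any(v_ok) || !any(j_ok)) next
        v_hits <- which(v_ok & vd == min(vd[v_ok]))
        j_hits <- which(j_ok & jd == min(jd[j_ok]))
        ctx_v <- max(pmin(nchar(prefix), nchar(v$pre_anchor[v_hits])))
        ctx_j <- max(pmin(nchar(suffix), nchar(j$post_anchor[j_hits])))
        cand <- list(frame = f - 1L, x = x, y = y, ctx = ctx_v + ctx_j,
                     core_aa = substr(aa, x + 1L, y + 1L),
                     v_hits = sort(v$id[v_hits]), j_hits = sort(j$id[j_hits]))
        better <- is.null(best) || cand$ctx > best$ctx ||
          (cand$ctx == best$ctx && cand$core_aa < best$core_aa) ||
          (cand$ctx == best$ctx && cand$core_aa == best$core_aa &&
             (cand$frame < best$frame ||
                (cand$frame == best$frame && cand$x < best$x)))
        if (better) best <- cand
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = reads$read_id[r], core_aa = best$core_aa, ctx = best$ctx,
        v_hits = paste(best$v_hits, collapse = ","),
        j_hits = paste(best$j_hits, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read_id = character(), core_aa = character(),
                      ctx = integer(), v_hits = character(),
                      j_hits = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$read_id), , drop = FALSE]
}

# Read table constructor.
make_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs))) {
  data.frame(read_id = ids, nt_seq = seqs, qual = NA_character_,
             origin = "direct_fastq", mate = NA_integer_,
             stringsAsFactors = FALSE)
}
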