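# Stage-1/stage-2 CDR3 assembly: six-frame translation, putative-span
# enumeration, bounded edit-distance anchoring against germline V/J context,
# and exact-overlap merging of partial-CDR3 reads.

# Batched six-frame translation: returns a list of 6 character vectors
# (forward frames 0..2, then reverse-complement frames 0..2), one element per
# input read. Trailing partial codons are dropped; ambiguous codons -> 'X',
# stops -> '*'.
frame_translations <- function(seqs) {
  fwd <- Biostrings::DNAStringSet(seqs)
  sets <- list(fwd, Biostrings::reverseComplement(fwd))
  out <- vector("list", 6L)
  for (s in 1:2) {
    set <- sets[[s]]
    w <- Biostrings::width(set)
    for (f in 0:2) {
      len3 <- pmax(0L, ((w - f) %/% 3L) * 3L)
      start <- ifelse(len3 == 0L, 1L, f + 1L)
      end <- ifelse(len3 == 0L, 0L, f + len3)
      sub <- Biostrings::subseq(set, start = start, end = end)
      out[[(s - 1L) * 3L + f + 1L]] <-
        as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
    }
  }
  out
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames 1-3 are the forward strand at offsets 0-2; frames 4-6 are the
#' reverse complement at offsets 0-2. Ambiguous codons translate to `X`,
#' stop codons to `*`.
#'
#' @param nt_seq A single nucleotide string.
#' @return Character vector of 6 amino-acid strings.
#' @examples
#' six_frame_translate("TGTGCT")[1]  # "CA"
#' @export
six_frame_translate <- function(nt_seq) {
  stopifnot(length(nt_seq) == 1L, nchar(nt_seq) >= 3L)
  vapply(frame_translations(nt_seq), `[`, character(1L), 1L)
}

#' Enumerate putative CDR3 spans in a translated read
#'
#' Lists every (cysteine, terminal F/W) index pair whose span length lies in
#' `[min_len, max_len]` amino acids and contains no stop codon (unless
#' `keep_out_of_frame`). Indices are 0-based and inclusive; the span runs from
#' the anchoring `C` to the terminal `F` (light chains) or `W` (IGH).
#'
#' @param aa Translated read (one frame).
#' @param chain One of `IG_CHAINS`; selects the terminal residue.
#' @param min_len,max_len Span length bounds in amino acids (default 4-30).
#' @param keep_out_of_frame Allow stop codons inside the span.
#' @return `data.frame` with columns `x`, `y` (0-based span endpoints).
#' @export
scan_putative_cdr3 <- function(aa, chain, min_len = 4L, max_len = 30L,
                               keep_out_of_frame = FALSE) {
  end_res <- anchor_residue("J", chain)
  chars <- strsplit(aa, "")[[1L]]
  xs <- which(chars == "C") - 1L
  ys <- which(chars == end_res) - 1L
  out <- expand.grid(x = xs, y = ys)
  out <- out[out$y - out$x + 1L >= min_len & out$y - out$x + 1L <= max_len, , drop = FALSE]
  if (!keep_out_of_frame && nrow(out) > 0L) {
    stop_free <- mapply(function(x, y) {
      !any(chars[(x + 1L):(y + 1L)] == "*")
    }, out$x, out$y)
    out <- out[stop_free, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$x, out$y), , drop = FALSE]
}

# Bounded window edit distance used by the reference matchers: last/first k
# residues of each side, full Levenshtein via adist (equal-length windows make
# distance <= 1 equivalent to <= 1 mismatch).
window_distance <- function(read_ctx, germ_ctx, side = c("V", "J")) {
  side <- match.arg(side)
  k <- min(nchar(read_ctx), nchar(germ_ctx))
  if (k == 0L) return(Inf)
  if (side == "V") {
    a <- substr(read_ctx, nchar(read_ctx) - k + 1L, nchar(read_ctx))
    b <- substr(germ_ctx, nchar(germ_ctx) - k + 1L, nchar(germ_ctx))
  } else {
    a <- substr(read_ctx, 1L, k)
    b <- substr(germ_ctx, 1L, k)
  }
  drop(utils::adist(a, b))
}

#' Match a read prefix against germline V pre-anchor context
#'
#' A V gene matches when the read prefix (everything before the putative
#' anchoring cysteine) is longer than `min_context - 1` amino acids and the
#' Levenshtein distance between the equal-length window — the last
#' `min(len(prefix), len(V_x))` residues of each — is at most `max_dist`.
#' All equally-best genes are returned.
#'
#' @param prefix_aa Read prefix (amino acids before the anchor C).
#' @param germline Germline `data.frame`.
#' @param chain Chain to match within.
#' @param min_context Minimum prefix length (default 5, i.e. strictly more
#'   than 4 residues of context).
#' @param max_dist Maximum edit distance within the window (default 1).
#' @return Character vector of matching V segment ids (possibly empty).
#' @export
match_v <- function(prefix_aa, germline, chain, min_context = 5L, max_dist = 1L) {
  if (nchar(prefix_aa) < min_context) return(character())
  v <- germline[germline$chain == chain & germline$class == "V" &
                  !is.na(germline$anchor_pos), , drop = FALSE]
  if (nrow(v) == 0L) return(character())
  d <- vapply(v$pre_anchor, window_distance, numeric(1L),
              read_ctx = prefix_aa, side = "V", USE.NAMES = FALSE)
  ok <- d <= max_dist
  if (!any(ok)) return(character())
  v$id[ok & d == min(d[ok])]
}

#' Match a read suffix against germline J post-anchor context
#'
#' Symmetric to [match_v()]: the read suffix (everything after the terminal
#' F/W) is compared against the equal-length *prefix* of the J post-anchor
#' string.
#'
#' @inheritParams match_v
#' @param suffix_aa Read suffix (amino acids after the terminal residue).
#' @return Character vector of matching J segment ids (possibly empty).
#' @export
match_j <- function(suffix_aa, germline, chain, min_context = 5L, max_dist = 1L) {
  if (nchar(suffix_aa) < min_context) return(character())
  j <- germline[germline$chain == chain & germline$class == "J" &
                  !is.na(germline$anchor_pos), , drop = FALSE]
  if (nrow(j) == 0L) return(character())
  d <- vapply(j$post_anchor, window_distance, numeric(1L),
              read_ctx = suffix_aa, side = "J", USE.NAMES = FALSE)
  ok <- d <= max_dist
  if (!any(ok)) return(character())
  j$id[ok & d == min(d[ok])]
}

# Map a (frame, aa position) pair back to nucleotide coordinates on the
# frame-oriented read (reverse frames refer to the reverse complement).
orient_reads <- function(seqs, frame) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  ifelse(frame >= 3L, rc, seqs)
}

empty_candidates <- function() {
  data.frame(read_id = character(), chain = character(), frame = integer(),
             x = integer(), y = integer(), ctx = integer(), core_aa = character(),
             core_nt = character(), v_hits = character(), j_hits = character(),
             stage = integer(), stringsAsFactors = FALSE)
}

#' Stage 1: assemble full CDR3 candidates from single reads
#'
#' Each read is translated in six frames and scanned for putative CDR3 spans;
#' a span is kept when its flanking read context matches at least one V and
#' one J gene of the same chain. At most one candidate is reported per read
#' (largest total matched context; ties broken by lexicographically smallest
#' core, then frame, then span start). Reads with one-sided evidence only are
#' returned as partials for [stage2_merge()].
#'
#' @param reads Candidate read `data.frame` (needs `read_id`, `nt_seq`).
#' @param germline Germline `data.frame`.
#' @param chains Chains to assemble (default: chains present in `germline`).
#' @param min_core,max_core CDR3 length bounds in amino acids.
#' @param min_context Minimum flanking context (amino acids, default 5).
#' @param max_dist Maximum window edit distance (default 1).
#' @param keep_out_of_frame Report spans containing stop codons.
#' @return A list with elements `candidates`, `v_partial`, `j_partial`.
#' @export
stage1_assemble <- function(reads, germline, chains = NULL, min_core = 4L,
                            max_core = 30L, min_context = 5L, max_dist = 1L,
                            keep_out_of_frame = FALSE) {
  idx <- germline_index(germline, chains)
  if (nrow(reads) == 0L) {
    return(list(candidates = empty_candidates(),
                v_partial = NULL, j_partial = NULL))
  }
  frames <- frame_translations(reads$nt_seq)

  cand <- list(); vpart <- list(); jpart <- list()
  for (chn in names(idx)) {
    ix <- idx[[chn]]
    res <- cpp_stage1_chain(frames, ix$v_ids, ix$vx, ix$j_ids, ix$jy,
                            ix$end_residue, as.integer(min_core),
                            as.integer(max_core), as.integer(min_context),
                            as.integer(max_dist), keep_out_of_frame)
    f <- res$full
    if (length(f$read)) {
      cand[[chn]] <- data.frame(
        row = f$read, chain = chn, frame = f$frame, x = f$x, y = f$y,
        ctx = f$ctx, core_aa = f$core_aa, v_hits = f$v_hits,
        j_hits = f$j_hits, stringsAsFactors = FALSE
      )
    }
    vp <- res$v_partial
    if (length(vp$read)) {
      vpart[[chn]] <- data.frame(row = vp$read, chain = chn, frame = vp$frame,
                                 x = vp$x, ctx = vp$ctx, v_hits = vp$v_hits,
                                 stringsAsFactors = FALSE)
    }
    jp <- res$j_partial
    if (length(jp$read)) {
      jpart[[chn]] <- data.frame(row = jp$read, chain = chn, frame = jp$frame,
                                 y = jp$y, ctx = jp$ctx, j_hits = jp$j_hits,
                                 stringsAsFactors = FALSE)
    }
  }

  cand <- if (length(cand)) do.call(rbind, cand) else NULL
  if (!is.null(cand)) {
    # across chains: keep the best-context candidate per read (chain order
    # breaks ties deterministically because idx preserves IG_CHAINS order)
    cand <- cand[order(cand$row, -cand$ctx), , drop = FALSE]
    cand <- cand[!duplicated(cand$row), , drop = FALSE]
    fr <- cand$frame %% 3L
    oriented <- orient_reads(reads$nt_seq[cand$row], cand$frame)
    cand$core_nt <- substr(oriented, fr + 3L * cand$x + 1L, fr + 3L * (cand$y + 1L))
    cand$read_id <- reads$read_id[cand$row]
    cand$stage <- 1L
  }

  full_rows <- if (is.null(cand)) integer() else cand$row
  finish_partial <- function(parts) {
    if (length(parts) == 0L) return(NULL)
    p <- do.call(rbind, parts)
    p <- p[!p$row %in% full_rows, , drop = FALSE]
    if (nrow(p) == 0L) return(NULL)
    # one partial per read: best context, chain order breaking ties
    p <- p[order(p$row, -p$ctx), , drop = FALSE]
    p <- p[!duplicated(p$row), , drop = FALSE]
    p$read_id <- reads$read_id[p$row]
    p$oriented_nt <- orient_reads(reads$nt_seq[p$row], p$frame)
    p
  }
  vp <- finish_partial(vpart)
  jp <- finish_partial(jpart)
  # a read id may surface on both sides via different chains; keep one side
  if (!is.null(vp) && !is.null(jp)) {
    both <- intersect(vp$row, jp$row)
    if (length(both)) jp <- jp[!jp$row %in% both, , drop = FALSE]
  }
  if (!is.null(vp) && nrow(vp)) {
    vp$c_nt_start <- vp$frame %% 3L + 3L * vp$x  # 0-based start of the C codon
  }
  if (!is.null(jp) && nrow(jp)) {
    jp$f_nt_end <- jp$frame %% 3L + 3L * jp$y + 2L  # 0-based end of the F/W codon
  }

  cols <- c("read_id", "chain", "frame", "x", "y", "ctx", "core_aa", "core_nt",
            "v_hits", "j_hits")
  candidates <- if (is.null(cand)) empty_candidates() else {
    out <- cand[, c(cols, "stage")]
    rownames(out) <- NULL
    out
  }
  list(candidates = candidates, v_partial = vp, j_partial = jp)
}

#' Stage 2: merge partial-CDR3 reads on exact nucleotide overlap
#'
#' V-side partial reads are indexed by their 15-mers; each J-side read whose
#' prefix exactly matches a V-side read's suffix over at least `min_overlap`
#' nucleotides is concatenated with it, the junction is re-translated and the
#' full C..F/W core re-extracted. Pairing is greedy, longest overlap first
#' (ties by read id), and each partial read is used at most once.
#'
#' @param v_partial,j_partial Partial tables from [stage1_assemble()].
#' @param min_overlap Minimum exact overlap in nucleotides (default 15).
#' @param min_core,max_core CDR3 length bounds in amino acids.
#' @param keep_out_of_frame Allow stop codons inside the merged core.
#' @return Candidate `data.frame` in the [stage1_assemble()] layout
#'   (`stage = 2`).
#' @export
stage2_merge <- function(v_partial, j_partial, min_overlap = 15L,
                         min_core = 4L, max_core = 30L,
                         keep_out_of_frame = FALSE) {
  if (is.null(v_partial) || is.null(j_partial) ||
      nrow(v_partial) == 0L || nrow(j_partial) == 0L) {
    return(empty_candidates())
  }
  pairs <- list()
  for (chn in intersect(unique(v_partial$chain), unique(j_partial$chain))) {
    vp <- v_partial[v_partial$chain == chn, , drop = FALSE]
    jp <- j_partial[j_partial$chain == chn, , drop = FALSE]
    # index every min_overlap-mer of the V-side reads whose suffix it starts
    key <- list(); vi <- list(); pp <- list()
    for (i in seq_len(nrow(vp))) {
      s <- vp$oriented_nt[i]
      n <- nchar(s)
      if (n < min_overlap) next
      starts <- 1:(n - min_overlap + 1L)
      key[[i]] <- substring(s, starts, starts + min_overlap - 1L)
      vi[[i]] <- rep(i, length(starts))
      pp[[i]] <- starts
    }
    if (length(key) == 0L) next
    key <- unlist(key); vi <- unlist(vi); pp <- unlist(pp)
    for (jidx in seq_len(nrow(jp))) {
      js <- jp$oriented_nt[jidx]
      nj <- nchar(js)
      if (nj < min_overlap) next
      jkey <- substr(js, 1L, min_overlap)
      hits <- which(key == jkey)
      for (h in hits) {
        i <- vi[h]; p <- pp[h]
        nv <- nchar(vp$oriented_nt[i])
        k <- nv - p + 1L
        if (k < min_overlap || k > nj) next
        if (substr(vp$oriented_nt[i], p, nv) != substr(js, 1L, k)) next
        pairs[[length(pairs) + 1L]] <- data.frame(
          chain = chn, vrow = i + 0L, jrow = jidx, k = k,
          v_id = vp$read_id[i], j_id = jp$read_id[jidx],
          stringsAsFactors = FALSE
        )
      }
    }
    pairs[[length(pairs) + 1L]] <- NULL
  }
  pairs <- Filter(Negate(is.null), pairs)
  if (length(pairs) == 0L) return(empty_candidates())
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(-pairs$k, pairs$v_id, pairs$j_id), , drop = FALSE]

  used_v <- character(); used_j <- character()
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    if (pr$v_id %in% used_v || pr$j_id %in% used_j) next
    vp <- v_partial[v_partial$chain == pr$chain, , drop = FALSE][pr$vrow, ]
    jp <- j_partial[j_partial$chain == pr$chain, , drop = FALSE][pr$jrow, ]
    merged <- paste0(vp$oriented_nt, substr(jp$oriented_nt, pr$k + 1L, nchar(jp$oriented_nt)))
    c_start <- vp$c_nt_start
    f_end <- (nchar(vp$oriented_nt) - pr$k) + jp$f_nt_end
    if (f_end <= c_start || (f_end - 2L - c_start) %% 3L != 0L) next
    core_nt <- substr(merged, c_start + 1L, f_end + 1L)
    core_aa <- translate_nt(core_nt)
    n_aa <- nchar(core_aa)
    end_ok <- substr(core_aa, n_aa, n_aa) == anchor_residue("J", pr$chain)
    if (n_aa < min_core || n_aa > max_core ||
        substr(core_aa, 1L, 1L) != "C" || !end_ok) next
    if (!keep_out_of_frame && grepl("*", core_aa, fixed = TRUE)) next
    used_v <- c(used_v, pr$v_id); used_j <- c(used_j, pr$j_id)
    out[[length(out) + 1L]] <- data.frame(
      read_id = paste0(pr$v_id, "+", pr$j_id), chain = pr$chain,
      frame = vp$frame, x = as.integer((c_start - vp$frame %% 3L) / 3L),
      y = NA_integer_, ctx = vp$ctx + jp$ctx, core_aa = core_aa,
      core_nt = core_nt, v_hits = vp$v_hits, j_hits = jp$j_hits,
      stage = 2L, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(empty_candidates())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble CDR3 candidates from a candidate read set
#'
#' Runs stage 1 on every read and, when enabled, stage 2 on the reads left
#' with one-sided germline evidence. Stage 2 defaults to "auto": enabled only
#' when the median read length is at most 50 bp, where single reads rarely
#' contain a complete CDR3 with sufficient context.
#'
#' @inheritParams stage1_assemble
#' @param stage2 `TRUE`, `FALSE`, or `NULL` (auto by read length).
#' @param min_overlap Stage-2 minimum exact nucleotide overlap.
#' @return Candidate `data.frame` (stage-1 and stage-2 rows combined), with
#'   the partial tables attached as attribute `"partials"`.
#' @export
assemble_cdr3 <- function(reads, germline, chains = NULL, stage2 = NULL,
                          min_overlap = 15L, min_core = 4L, max_core = 30L,
                          min_context = 5L, max_dist = 1L,
                          keep_out_of_frame = FALSE) {
  s1 <- stage1_assemble(reads, germline, chains = chains, min_core = min_core,
                        max_core = max_core, min_context = min_context,
                        max_dist = max_dist, keep_out_of_frame = keep_out_of_frame)
  if (is.null(stage2)) {
    stage2 <- nrow(reads) > 0L && stats::median(nchar(reads$nt_seq)) <= 50L
  }
  out <- s1$candidates
  if (isTRUE(stage2)) {
    s2 <- stage2_merge(s1$v_partial, s1$j_partial, min_overlap = min_overlap,
                       min_core = min_core, max_core = max_core,
                       keep_out_of_frame = keep_out_of_frame)
    out <- rbind(out, s2)
  }
  attr(out, "partials") <- list(v = s1$v_partial, j = s1$j_partial)
  out
}
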