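# Clonotype calling: aggregate per-read CDR3 candidates into weighted nodes,
# correct errors with CAST, emit consensus clonotypes with V(D)J assignments,
# and the end-to-end `profile_repertoire()` pipeline.

# Collapse identical (chain, CDR3) candidates into weighted nodes. The
# representative nucleotide core is the most frequent one (ties lexicographic).
aggregate_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(data.frame(chain = character(), aa_seq = character(), count = integer(),
                      v_hits = character(), j_hits = character(),
                      rep_nt = character(), stringsAsFactors = FALSE))
  }
  key <- paste(candidates$chain, candidates$core_aa, sep = "\r")
  groups <- split(seq_len(nrow(candidates)), key)
  rows <- lapply(groups, function(ix) {
    sub <- candidates[ix, , drop = FALSE]
    nt_tab <- sort(table(sub$core_nt), decreasing = TRUE)
    nt_best <- names(nt_tab)[nt_tab == nt_tab[1L]]
    data.frame(
      chain = sub$chain[1L], aa_seq = sub$core_aa[1L], count = length(ix),
      v_hits = paste(sort(unique(unlist(split_hits(sub$v_hits)))), collapse = ","),
      j_hits = paste(sort(unique(unlist(split_hits(sub$j_hits)))), collapse = ","),
      rep_nt = sort(nt_best)[1L], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chain, out$aa_seq), , drop = FALSE]
}

#' Call clonotypes from assembled CDR3 candidates
#'
#' Candidates sharing a chain and amino-acid core collapse into weighted
#' nodes; each chain's nodes are clustered with CAST (unless `cast = FALSE`)
#' and every partition is reported as one clonotype carrying its weighted
#' consensus sequence, total read support, within-chain frequency, V/J
#' assignments and — for IGH, when D segments are supplied — the best-matching
#' D gene.
#'
#' @param candidates Candidate `data.frame` from [assemble_cdr3()].
#' @param germline Optional germline `data.frame` (needed for D mapping).
#' @param cast Apply CAST error correction (default `TRUE`).
#' @param tau CAST affinity threshold (default 0.25).
#' @param min_d_match Minimum D-gene shared substring (nt, default 5).
#' @return Clonotype `data.frame`: `chain`, `cdr3_aa`, `cdr3_nt`, `count`,
#'   `frequency`, `v_genes`, `d_gene`, `j_genes`.
#' @export
call_clonotypes <- function(candidates, germline = NULL, cast = TRUE,
                            tau = 0.25, min_d_match = 5L) {
  nodes <- aggregate_candidates(candidates)
  out <- list()
  for (chn in unique(nodes$chain)) {
    nd <- nodes[nodes$chain == chn, , drop = FALSE]
    clusters <- if (cast) cast_cluster(nd, tau = tau) else as.list(seq_len(nrow(nd)))
    for (cl in clusters) {
      members <- nd[cl, , drop = FALSE]
      cons <- weighted_consensus(members)
      rep_row <- members[order(-members$count, members$aa_seq), , drop = FALSE][1L, ]
      out[[length(out) + 1L]] <- data.frame(
        chain = chn, cdr3_aa = cons$consensus_aa, cdr3_nt = rep_row$rep_nt,
        count = sum(members$count), frequency = NA_real_,
        v_genes = paste(cons$v_genes, collapse = ","),
        d_gene = NA_character_,
        j_genes = paste(cons$j_genes, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chain = character(), cdr3_aa = character(),
                      cdr3_nt = character(), count = integer(),
                      frequency = numeric(), v_genes = character(),
                      d_gene = character(), j_genes = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  for (chn in unique(res$chain)) {
    sel <- res$chain == chn
    res$frequency[sel] <- res$count[sel] / sum(res$count[sel])
  }
  if (!is.null(germline)) {
    d <- germline[germline$chain == "IGH" & germline$class == "D", , drop = FALSE]
    if (nrow(d) > 0L) {
      igh <- which(res$chain == "IGH")
      res$d_gene[igh] <- vapply(res$cdr3_nt[igh], map_d_gene, character(1L),
                                d_ids = d$id, d_nt = d$nt_seq,
                                min_len = min_d_match, USE.NAMES = FALSE)
    }
  }
  res <- sort_clonotypes(res)
  rownames(res) <- NULL
  res
}

#' Profile an immunoglobulin repertoire from RNA-Seq reads
#'
#' End-to-end pipeline: candidate-read intake (FASTQ, BAM, or an in-memory
#' read table), quality/complexity filtering, two-stage CDR3 assembly, CAST
#' error correction and clonotype reporting.
#'
#' @param input A FASTQ path, a BAM path (with `ig_regions`), or a candidate
#'   read `data.frame` with `read_id` and `nt_seq` columns.
#' @param germline Germline `data.frame` (see [read_germline_dir()]).
#' @param chains Chains to assemble (default: all present in `germline`).
#' @param ig_regions Ig locus intervals (BED path or `GRanges`); required for
#'   BAM input.
#' @param stage2 `TRUE`/`FALSE`/`NULL` (auto by read length; see
#'   [assemble_cdr3()]).
#' @param cast Apply CAST error correction.
#' @param tau CAST affinity threshold.
#' @param min_qual,min_entropy,rrna_fasta Intake filters (see
#'   [quality_filter()]).
#' @param keep_out_of_frame Report CDR3 spans containing stop codons.
#' @return An object of class `repertoire`: a list with `clonotypes`,
#'   `candidates`, `n_input`, `n_candidates` and `params`.
#' @export
profile_repertoire <- function(input, germline, chains = NULL,
                               ig_regions = NULL, stage2 = NULL, cast = TRUE,
                               tau = 0.25, min_qual = 20, min_entropy = 1,
                               rrna_fasta = NULL, keep_out_of_frame = FALSE) {
  reads <- if (is.data.frame(input)) {
    input
  } else if (grepl("\\.bam$", input, ignore.case = TRUE)) {
    if (is.null(ig_regions)) stop("BAM input requires ig_regions (BED or GRanges)")
    extract_candidates_bam(input, ig_regions)
  } else {
    read_candidates_fastq(input)
  }
  n_input <- nrow(reads)
  if (is.null(reads$qual)) reads$qual <- NA_character_
  reads <- quality_filter(reads, min_qual = min_qual, min_entropy = min_entropy,
                          rrna_fasta = rrna_fasta)
  cand <- assemble_cdr3(reads, germline, chains = chains, stage2 = stage2,
                        keep_out_of_frame = keep_out_of_frame)
  clono <- call_clonotypes(cand, germline = germline, cast = cast, tau = tau)
  structure(list(
    clonotypes = clono,
    candidates = cand,
    candidate_read_ids = reads$read_id,
    n_input = n_input,
    n_candidates = nrow(reads),
    params = list(stage2 = stage2, cast = cast, tau = tau, min_qual = min_qual,
                  min_entropy = min_entropy,
                  keep_out_of_frame = keep_out_of_frame)
  ), class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat("CDR3 repertoire profile\n")
  cat("  input reads:      ", x$n_input, "\n")
  cat("  candidate reads:  ", x$n_candidates, "\n")
  cat("  clonotypes:       ", nrow(x$clonotypes), "\n")
  tab <- table(x$clonotypes$chain)
  for (chn in names(tab)) cat("    ", chn, ": ", tab[[chn]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.repertoire <- function(object, ...) {
  cl <- object$clonotypes
  chains <- unique(cl$chain)
  rows <- lapply(chains, function(chn) {
    sub <- cl[cl$chain == chn, ]
    data.frame(
      chain = chn, clonotypes = nrow(sub), reads = sum(sub$count),
      shannon_bits = shannon_alpha(sub$frequency),
      top_cdr3 = sub$cdr3_aa[which.max(sub$count)],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.repertoire", "data.frame")
  out
}

#' @export
print.summary.repertoire <- function(x, ...) {
  cat("Per-chain repertoire summary\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Plot a repertoire profile
#'
#' Two base-graphics panels: the frequencies of the most abundant clonotypes
#' and the CDR3 amino-acid length distribution.
#'
#' @param x A `repertoire` object.
#' @param top Number of top clonotypes to show (default 15).
#' @param ... Unused.
#' @export
plot.repertoire <- function(x, top = 15L, ...) {
  cl <- x$clonotypes
  if (nrow(cl) == 0L) {
    warning("empty repertoire; nothing to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  sub <- cl[order(-cl$count), , drop = FALSE][seq_len(min(top, nrow(cl))), ]
  graphics::barplot(sub$frequency, names.arg = sub$cdr3_aa, las = 2,
                    cex.names = 0.6, ylab = "frequency",
                    main = "Top clonotypes")
  graphics::hist(nchar(cl$cdr3_aa), breaks = seq(3.5, 30.5, by = 1),
                 xlab = "CDR3 length (aa)", main = "CDR3 length", col = "grey")
  invisible(x)
}
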