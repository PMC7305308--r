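# Evaluation against simulation truth: exact-match precision/recall/F-score
# on clonotype sets, extraction recall of junction-spanning reads, and the
# read-length x coverage sweep.

#' Score assembled clonotypes against simulation truth
#'
#' Clonotype-level scoring by exact amino-acid match: TP is the number of
#' distinct assembled CDR3 sequences present in the truth set, FN the true
#' sequences not assembled, FP the assembled sequences not in the truth.
#' Recall = TP/(TP+FN), Precision = TP/(TP+FP), F = 2PR/(P+R) (0 when both
#' are 0; precision of an empty assembly is reported as 0).
#'
#' @param assembled Character vector of assembled CDR3 amino-acid sequences
#'   (duplicates collapse).
#' @param truth Character vector of true CDR3 sequences (non-empty).
#' @return One-row `data.frame`: `tp`, `fn`, `fp`, `recall`, `precision`,
#'   `f_score`.
#' @export
score_assembly <- function(assembled, truth) {
  stopifnot(length(truth) > 0L)
  a <- unique(assembled); t <- unique(truth)
  tp <- length(intersect(a, t))
  fn <- length(setdiff(t, a))
  fp <- length(setdiff(a, t))
  recall <- tp / (tp + fn)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  data.frame(tp = tp, fn = fn, fp = fp, recall = recall, precision = precision,
             f_score = f)
}

#' Recall of junction-spanning reads into the candidate read set
#'
#' The fraction of manifest-flagged junction-spanning receptor reads present
#' in the candidate read set produced by intake preprocessing.
#'
#' @param candidate_ids Read ids admitted to assembly.
#' @param manifest Truth manifest from [simulate_reads()].
#' @return Fraction in `[0, 1]`.
#' @export
read_extraction_recall <- function(candidate_ids, manifest) {
  flagged <- manifest$read_id[manifest$contains_junction]
  if (length(flagged) == 0L) return(NA_real_)
  mean(flagged %in% candidate_ids)
}

#' Precision/recall sweep over read length and coverage
#'
#' For every (read length, coverage, seed) cell: simulate transcripts and
#' reads, run the full assembly + CAST pipeline, and score the resulting
#' clonotype set against the simulated truth by exact match.
#'
#' @param germline Germline `data.frame` (e.g. [simulate_germline()]).
#' @param read_lengths,coverages Grid axes.
#' @param seeds One RNG seed per replicate.
#' @param n_transcripts Transcripts per cell.
#' @param chain Chain to simulate and assemble.
#' @param error_rate Per-base substitution error rate.
#' @param cast,tau CAST settings passed to [call_clonotypes()].
#' @param ... Further arguments to [simulate_transcripts()].
#' @return `data.frame` with one row per grid cell and seed: the grid
#'   coordinates plus `tp`, `fn`, `fp`, `recall`, `precision`, `f_score`.
#' @export
sweep_grid <- function(germline, read_lengths = c(50L, 75L, 100L),
                       coverages = c(8, 16, 32), seeds = 1:3,
                       n_transcripts = 200L, chain = "IGH",
                       error_rate = 0.001, cast = TRUE, tau = 0.25, ...) {
  rows <- list()
  for (seed in seeds) {
    tx <- simulate_transcripts(germline, n = n_transcripts, chain = chain,
                               seed = seed, ...)
    truth <- unique(tx$true_cdr3_aa)
    for (l in read_lengths) {
      for (cv in coverages) {
        sim <- simulate_reads(tx, read_length = l, coverage = cv,
                              error_rate = error_rate,
                              seed = seed + 7907L * l + 104729L * as.integer(cv))
        cand <- assemble_cdr3(sim$reads, germline, chains = chain)
        clono <- call_clonotypes(cand, germline = germline, cast = cast, tau = tau)
        sc <- score_assembly(clono$cdr3_aa[clono$chain == chain], truth)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(read_length = l, coverage = cv, seed = seed), sc
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
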