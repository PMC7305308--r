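# CAST (cluster-affinity search technique) error correction: assembled CDR3
# amino-acid sequences form a complete graph whose edge weights are the
# inverse Levenshtein distance; partitions are grown from max-degree seeds and
# refined by mean-affinity add/remove passes, then collapsed to a
# count-weighted consensus clonotype.

#' Affinity between two distinct CDR3 sequences
#'
#' The inverse of the Levenshtein edit distance. Identical sequences are never
#' compared: identical reads aggregate into a single weighted node first.
#'
#' @param a,b Distinct amino-acid strings.
#' @return Affinity in (0, 1].
#' @examples
#' cdr3_affinity("CARDW", "CARGW")    # 1
#' cdr3_affinity("kitten", "sitting") # 1/3
#' @export
cdr3_affinity <- function(a, b) {
  stopifnot(a != b)
  1 / drop(utils::adist(a, b))
}

#' Cluster CDR3 nodes with the CAST algorithm
#'
#' Nodes are unique CDR3 amino-acid sequences weighted by their supporting
#' read counts. Until all nodes are assigned: a partition is opened with the
#' unassigned node of maximal count-weighted affinity sum (the "max-degree"
#' node of the complete affinity graph); then, alternately, every unassigned
#' node whose mean affinity to the partition is at least `tau` is added, and
#' every member whose mean affinity to the rest of the partition falls below
#' `tau` is removed, until neither set changes. A 100-pass cap per partition
#' guards against oscillation (closing the partition as-is with a warning).
#'
#' @param nodes `data.frame` with columns `aa_seq` (unique) and `count`.
#' @param tau Affinity threshold (default 0.25, i.e. edit distance 4).
#' @param max_iter Add/remove pass cap per partition.
#' @return List of integer vectors, each the row indices of one partition;
#'   partitions are disjoint and cover all nodes.
#' @export
cast_cluster <- function(nodes, tau = 0.25, max_iter = 100L) {
  n <- nrow(nodes)
  stopifnot(n > 0L, !anyDuplicated(nodes$aa_seq))
  if (n == 1L) return(list(1L))
  A <- 1 / utils::adist(nodes$aa_seq, nodes$aa_seq)
  diag(A) <- 0
  counts <- as.numeric(nodes$count)

  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) > 0L) {
    if (length(remaining) == 1L) {
      clusters[[length(clusters) + 1L]] <- remaining
      break
    }
    deg <- as.vector(A[remaining, remaining, drop = FALSE] %*% counts[remaining])
    ord <- order(-deg, -counts[remaining], nodes$aa_seq[remaining])
    P <- remaining[ord[1L]]
    U <- setdiff(remaining, P)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      changed <- FALSE
      if (length(U) > 0L) {
        mean_aff <- rowMeans(A[U, P, drop = FALSE])
        add <- U[mean_aff >= tau]
        if (length(add) > 0L) {
          P <- c(P, add)
          U <- setdiff(U, add)
          changed <- TRUE
        }
      }
      if (length(P) > 1L) {
        mean_rest <- rowSums(A[P, P, drop = FALSE]) / (length(P) - 1L)
        drop_v <- P[mean_rest < tau]
        if (length(drop_v) == length(P)) {
          # keep the best-connected member so the partition cannot empty
          drop_v <- setdiff(drop_v, P[which.max(mean_rest)])
        }
        if (length(drop_v) > 0L) {
          P <- setdiff(P, drop_v)
          U <- c(U, drop_v)
          changed <- TRUE
        }
      }
      if (!changed) break
      if (iter >= max_iter) {
        warning("CAST add/remove did not stabilise after ", max_iter,
                " passes; closing partition as-is")
        break
      }
    }
    clusters[[length(clusters) + 1L]] <- sort(P)
    remaining <- setdiff(remaining, P)
  }
  clusters
}

# Split comma-joined gene hit strings into a per-row list.
split_hits <- function(x) strsplit(ifelse(is.na(x) | x == "", "", x), ",", fixed = TRUE)

#' Count-weighted consensus of a CAST partition
#'
#' Members are restricted to the length class with the largest total count
#' (ties to the shorter length); the consensus takes the count-weighted
#' majority residue at each position (ties alphabetical). V/J assignments are
#' the union of member hits filtered to the genes with maximal total
#' supporting weight.
#'
#' @param members `data.frame` with `aa_seq`, `count` and optionally
#'   `v_hits`, `j_hits` (comma-joined id strings).
#' @return List with `consensus_aa`, `v_genes`, `j_genes`.
#' @export
weighted_consensus <- function(members) {
  stopifnot(nrow(members) > 0L)
  lens <- nchar(members$aa_seq)
  by_len <- tapply(members$count, lens, sum)
  best_len <- as.integer(names(by_len)[order(-by_len, as.integer(names(by_len)))][1L])
  cls <- members[lens == best_len, , drop = FALSE]

  consensus <- vapply(seq_len(best_len), function(p) {
    res <- substr(cls$aa_seq, p, p)
    w <- tapply(cls$count, res, sum)
    names(w)[order(-w, names(w))][1L]
  }, character(1L))

  majority_genes <- function(col) {
    if (is.null(members[[col]])) return(character())
    hits <- split_hits(members[[col]])
    tab <- tapply(rep(members$count, lengths(hits)), unlist(hits), sum)
    if (is.null(tab) || length(tab) == 0L) return(character())
    sort(names(tab)[tab == max(tab)])
  }
  list(
    consensus_aa = paste(consensus, collapse = ""),
    v_genes = majority_genes("v_hits"),
    j_genes = majority_genes("j_hits")
  )
}
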