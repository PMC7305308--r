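# D-gene mapping for IGH clonotypes and the clonotype report writer.

# Longest exact common substring length between two nucleotide strings,
# scanning from the longest possible shared length downwards.
longest_shared_substring <- function(a, b, floor_len = 1L) {
  na <- nchar(a); nb <- nchar(b)
  kmax <- min(na, nb)
  if (kmax < floor_len) return(0L)
  for (k in kmax:floor_len) {
    starts <- 1:(na - k + 1L)
    subs <- substring(a, starts, starts + k - 1L)
    if (any(vapply(subs, grepl, logical(1L), x = b, fixed = TRUE))) return(k)
  }
  0L
}

#' Map a D gene onto an assembled IGH CDR3
#'
#' Returns the D segment sharing the longest exact nucleotide substring with
#' the CDR3 interior (the anchor codons are excluded). Matches shorter than
#' `min_len` nucleotides are considered noise and yield no assignment; ties go
#' to the alphabetically first gene id.
#'
#' @param cdr3_nt Representative nucleotide core of the clonotype.
#' @param d_ids,d_nt D segment ids and nucleotide sequences.
#' @param min_len Minimum shared substring length (default 5 nt).
#' @return A D gene id, or `NA_character_`.
#' @export
map_d_gene <- function(cdr3_nt, d_ids, d_nt, min_len = 5L) {
  if (length(d_ids) == 0L || is.na(cdr3_nt) || nchar(cdr3_nt) < 7L) {
    return(NA_character_)
  }
  interior <- substr(cdr3_nt, 4L, nchar(cdr3_nt) - 3L)
  best <- vapply(d_nt, longest_shared_substring, integer(1L),
                 b = interior, floor_len = min_len, USE.NAMES = FALSE)
  if (max(best) < min_len) return(NA_character_)
  sort(d_ids[best == max(best)])[1L]
}

# Deterministic clonotype ordering: chain, descending count, CDR3.
sort_clonotypes <- function(clonotypes) {
  clonotypes[order(clonotypes$chain, -clonotypes$count, clonotypes$cdr3_aa), ,
             drop = FALSE]
}

#' Write the clonotype report
#'
#' Tab-separated, deterministically sorted by (chain, descending count,
#' CDR3). With `airr = TRUE` the columns carry AIRR-rearrangement-style
#' aliases (`locus`, `junction_aa`, `junction`, `duplicate_count`, `v_call`,
#' `d_call`, `j_call`).
#'
#' @param clonotypes Clonotype `data.frame` (see [call_clonotypes()]).
#' @param path Output file.
#' @param airr Use AIRR column aliases.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(clonotypes, path, airr = FALSE) {
  cols <- c("chain", "cdr3_aa", "cdr3_nt", "count", "frequency",
            "v_genes", "d_gene", "j_genes")
  out <- sort_clonotypes(clonotypes)[, cols, drop = FALSE]
  if (airr) {
    names(out) <- c("locus", "junction_aa", "junction", "duplicate_count",
                    "frequency", "v_call", "d_call", "j_call")
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write clonotype table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a clonotype report written by [write_clonotype_table()]
#'
#' @param path TSV file.
#' @return Clonotype `data.frame`.
#' @export
read_clonotype_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA")
}
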