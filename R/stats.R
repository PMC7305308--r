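# Repertoire summary statistics: depth-adjusted clonotype richness (CPM),
# Shannon alpha-diversity, Sorensen-Dice beta-diversity, public/private
# sharing classification and the cell-type signature score.

#' Clonotypes per million raw reads (CPM)
#'
#' Distinct-clonotype richness adjusted for sequencing depth: the number of
#' distinct clonotypes per one million raw RNA-Seq reads.
#'
#' @param distinct_count Number of distinct clonotypes in the sample.
#' @param total_raw_reads Library size (raw RNA-Seq reads).
#' @return CPM value.
#' @examples
#' clonotype_cpm(500, 5e7)  # 10
#' @export
clonotype_cpm <- function(distinct_count, total_raw_reads) {
  stopifnot(total_raw_reads > 0)
  distinct_count * 1e6 / total_raw_reads
}

#' Shannon alpha-diversity (bits)
#'
#' Shannon entropy of the clonotype frequency distribution, in bits
#' (log base 2). Zero frequencies contribute nothing.
#'
#' @param frequencies Clonotype frequencies summing to 1.
#' @return Entropy in bits, in `[0, log2(n)]`.
#' @examples
#' shannon_alpha(rep(0.25, 4))  # 2
#' @export
shannon_alpha <- function(frequencies) {
  stopifnot(abs(sum(frequencies) - 1) < 1e-6, all(frequencies >= 0))
  f <- frequencies[frequencies > 0]
  -sum(f * log2(f))
}

#' Sorensen-Dice similarity between two clonotype sets
#'
#' Compositional (beta-diversity) overlap: `2|A n B| / (|A| + |B|)`. Samples
#' with fewer than `min_clonotypes` reported clonotypes are excluded from
#' pairwise analyses (returns `NA`).
#'
#' @param set_a,set_b Character vectors of clonotype CDR3 sequences.
#' @param min_clonotypes Minimum set size for a valid comparison (default 10).
#' @return Similarity in `[0, 1]`, or `NA` if either set is too small.
#' @examples
#' sorensen_dice(letters[1:3], letters[2:4], min_clonotypes = 1)  # 2/3
#' @export
sorensen_dice <- function(set_a, set_b, min_clonotypes = 10L) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) < min_clonotypes || length(b) < min_clonotypes) return(NA_real_)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise Sorensen-Dice matrix across samples
#'
#' @param sets Named list of clonotype sets.
#' @param min_clonotypes Minimum set size (see [sorensen_dice()]).
#' @return Symmetric matrix of similarities (`NA` where a sample fails the
#'   size filter); diagonal is 1 for valid samples.
#' @export
sorensen_dice_matrix <- function(sets, min_clonotypes = 10L) {
  n <- length(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- if (i == j && length(unique(sets[[i]])) >= min_clonotypes) 1
                 else sorensen_dice(sets[[i]], sets[[j]], min_clonotypes)
    }
  }
  m
}

#' Classify clonotype sharing across individuals and tissues
#'
#' A clonotype is *public* when observed in at least two individuals (else
#' *private*) and *multi-tissue* when observed in at least two tissues (else
#' *tissue-specific*).
#'
#' @param incidence `data.frame` with columns `clonotype`, `individual`,
#'   `tissue` (one row per observation; duplicates allowed).
#' @return List with `labels` (per-clonotype `data.frame`: `clonotype`,
#'   `n_individuals`, `n_tissues`, `sharing`, `tissue_span`) and `crosstab`
#'   (2x2 contingency table of the two labels).
#' @export
classify_sharing <- function(incidence) {
  stopifnot(all(c("clonotype", "individual", "tissue") %in% names(incidence)))
  n_ind <- tapply(incidence$individual, incidence$clonotype,
                  function(x) length(unique(x)))
  n_tis <- tapply(incidence$tissue, incidence$clonotype,
                  function(x) length(unique(x)))
  labels <- data.frame(
    clonotype = names(n_ind),
    n_individuals = as.integer(n_ind),
    n_tissues = as.integer(n_tis[names(n_ind)]),
    stringsAsFactors = FALSE
  )
  labels$sharing <- ifelse(labels$n_individuals >= 2L, "public", "private")
  labels$tissue_span <- ifelse(labels$n_tissues >= 2L, "multi_tissue",
                               "tissue_specific")
  crosstab <- table(
    sharing = factor(labels$sharing, c("private", "public")),
    tissue_span = factor(labels$tissue_span, c("tissue_specific", "multi_tissue"))
  )
  list(labels = labels, crosstab = crosstab)
}

#' Cell-type signature score
#'
#' The mean of the log2-transformed expression values over a user-supplied
#' signature gene list (e.g. a CD19+ B-cell signature). Signature genes
#' missing from the expression vector are excluded with a warning.
#'
#' @param expression Named numeric vector of positive expression values.
#' @param signature_genes Character vector of gene names.
#' @return Mean log2 expression of the signature genes.
#' @examples
#' signature_score(c(g1 = 2, g2 = 4), c("g1", "g2"))  # 1.5
#' @export
signature_score <- function(expression, signature_genes) {
  present <- signature_genes[signature_genes %in% names(expression)]
  missing <- setdiff(signature_genes, present)
  if (length(missing) > 0L) {
    warning("signature genes missing from expression data: ",
            paste(missing, collapse = ", "))
  }
  if (length(present) == 0L) stop("no signature genes present in expression data")
  vals <- expression[present]
  stopifnot(all(vals > 0))
  mean(log2(vals))
}

#' Per-sample repertoire profile statistics
#'
#' Convenience wrapper computing distinct-clonotype count, CPM and Shannon
#' alpha-diversity for one chain of a clonotype table.
#'
#' @param clonotypes Clonotype `data.frame`.
#' @param total_raw_reads Library size.
#' @param chain Chain to summarise (default: all rows).
#' @return One-row `data.frame`: `chain`, `distinct`, `cpm`, `alpha_bits`.
#' @export
repertoire_stats <- function(clonotypes, total_raw_reads, chain = NULL) {
  sub <- if (is.null(chain)) clonotypes else
    clonotypes[clonotypes$chain == chain, , drop = FALSE]
  freq <- sub$count / sum(sub$count)
  data.frame(
    chain = if (is.null(chain)) "all" else chain,
    distinct = nrow(sub),
    cpm = clonotype_cpm(nrow(sub), total_raw_reads),
    alpha_bits = if (nrow(sub) > 0L) shannon_alpha(freq) else 0,
    stringsAsFactors = FALSE
  )
}
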