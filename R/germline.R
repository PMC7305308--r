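#' @useDynLib cdrseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Supported immunoglobulin chains
#'
#' The three human immunoglobulin loci handled by the assembler: heavy (IGH),
#' kappa light (IGK) and lambda light (IGL).
#' @export
IG_CHAINS <- c("IGH", "IGK", "IGL")

# Conserved residue delimiting the CDR3 on each side: the last cysteine of the
# V segment, and the first phenylalanine (light chains) or tryptophan (IGH) of
# the J segment.
anchor_residue <- function(segment_class, chain) {
  if (segment_class == "V") return("C")
  if (chain == "IGH") "W" else "F"
}

#' Locate the conserved CDR3 anchor residue of a germline segment
#'
#' For V segments the anchor is the *last* cysteine of the amino-acid sequence;
#' for J segments it is the *first* phenylalanine (IGK/IGL) or tryptophan
#' (IGH). Positions are 0-based.
#'
#' @param aa_seq Amino-acid sequence of the segment.
#' @param segment_class `"V"` or `"J"`.
#' @param chain One of `IG_CHAINS`.
#' @return 0-based anchor position, or `NA_integer_` if the residue is absent.
#' @examples
#' locate_anchor("ACDC", "V", "IGH")    # 3: last C
#' locate_anchor("DYWGQG", "J", "IGH")  # 2: first W
#' locate_anchor("FGFG", "J", "IGK")    # 0: first F
#' @export
locate_anchor <- function(aa_seq, segment_class, chain) {
  res <- anchor_residue(segment_class, chain)
  hits <- gregexpr(res, aa_seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(NA_integer_)
  pos <- if (segment_class == "V") hits[length(hits)] else hits[1L]
  as.integer(pos - 1L)
}

#' Split a germline amino-acid sequence at its anchor residue
#'
#' Returns the pre-anchor and post-anchor substrings, with the anchor residue
#' excluded from both. For a V segment the pre-anchor string is the read-prefix
#' matching context; for a J segment the post-anchor string is the read-suffix
#' matching context.
#'
#' @param aa_seq Amino-acid sequence.
#' @param anchor_pos 0-based anchor position (see [locate_anchor()]).
#' @return A list with elements `pre` and `post`.
#' @examples
#' anchor_split("YYCAR", 2L)   # pre "YY", post "AR"
#' @export
anchor_split <- function(aa_seq, anchor_pos) {
  stopifnot(!is.na(anchor_pos), anchor_pos >= 0L, anchor_pos < nchar(aa_seq))
  list(
    pre  = substr(aa_seq, 1L, anchor_pos),
    post = substr(aa_seq, anchor_pos + 2L, nchar(aa_seq))
  )
}

# Translate a nucleotide string in frame 0, truncating trailing partial codons.
# Ambiguous codons become 'X', stops '*'.
translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    if.fuzzy.codon = "X"
  ))
}

# Infer chain / segment class from a (possibly IMGT pipe-delimited) FASTA
# header. IMGT headers carry the gene name in the second pipe field, e.g.
# "X92343|IGHV1-2*02|Homo sapiens|...". Plain headers are used whole.
parse_germline_header <- function(header) {
  fields <- strsplit(header, "|", fixed = TRUE)[[1L]]
  name <- if (length(fields) >= 2L && grepl("^IG", fields[2L])) fields[2L] else fields[1L]
  name <- trimws(name)
  chain <- substr(name, 1L, 3L)
  if (!chain %in% IG_CHAINS) chain <- NA_character_
  cls <- substr(name, 4L, 4L)
  if (!cls %in% c("V", "D", "J")) cls <- NA_character_
  list(id = name, chain = chain, class = cls)
}

#' Read germline V/D/J segments from a FASTA file
#'
#' Accepts plain or IMGT-dialect FASTA (pipe-delimited headers, `.` alignment
#' gaps). Gap characters are stripped, records containing non-ACGT bases are
#' rejected with a warning, V/J records are translated in frame 0 and indexed
#' by their conserved anchor residue. V/J segments lacking the anchor, or with
#' a stop codon at or before the anchor (pseudogenes), are excluded with a
#' warning.
#'
#' @param path FASTA file.
#' @param segment_class Optional explicit class (`"V"`, `"D"`, `"J"`) when the
#'   headers do not carry one.
#' @param chain Optional explicit chain when the headers do not carry one.
#' @param chain_filter Optional subset of `IG_CHAINS` to keep.
#' @param quiet Suppress per-record warnings.
#' @return A `data.frame` with one row per usable segment: `id`, `chain`,
#'   `class`, `nt_seq`, `aa_seq`, `anchor_pos` (0-based), `pre_anchor`,
#'   `post_anchor`. D segments have `NA` amino-acid columns.
#' @export
read_germline <- function(path, segment_class = NULL, chain = NULL,
                          chain_filter = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("germline FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  rows <- vector("list", length(set))
  for (i in seq_along(set)) {
    hdr <- parse_germline_header(names(set)[i])
    cls <- if (!is.null(segment_class)) segment_class else hdr$class
    chn <- if (!is.null(chain)) chain else hdr$chain
    nt <- gsub(".", "", toupper(as.character(set[[i]])), fixed = TRUE)
    if (is.na(cls) || is.na(chn)) {
      if (!quiet) warning("cannot infer chain/class for record '", hdr$id, "'; skipped")
      next
    }
    if (grepl("[^ACGT]", nt)) {
      if (!quiet) warning("ambiguous bases in record '", hdr$id, "'; skipped")
      next
    }
    row <- data.frame(
      id = hdr$id, chain = chn, class = cls, nt_seq = nt,
      aa_seq = NA_character_, anchor_pos = NA_integer_,
      pre_anchor = NA_character_, post_anchor = NA_character_,
      stringsAsFactors = FALSE
    )
    if (cls %in% c("V", "J")) {
      aa <- translate_nt(nt)
      pos <- locate_anchor(aa, cls, chn)
      if (is.na(pos)) {
        if (!quiet) warning("no conserved anchor in '", hdr$id, "'; excluded from index")
        next
      }
      # a stop codon before the anchor cannot support a CDR3 (pseudogene)
      if (grepl("*", substr(aa, 1L, pos + 1L), fixed = TRUE)) {
        if (!quiet) warning("stop codon before anchor in '", hdr$id, "'; excluded")
        next
      }
      sp <- anchor_split(aa, pos)
      row$aa_seq <- aa
      row$anchor_pos <- pos
      row$pre_anchor <- sp$pre
      row$post_anchor <- sp$post
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out) || nrow(out) == 0L) stop("no usable germline records in ", path)
  if (!is.null(chain_filter)) out <- out[out$chain %in% chain_filter, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a directory of per-chain germline FASTA files
#'
#' Files are expected to follow the `<chain><class>.fasta` convention
#' (e.g. `IGHV.fasta`, `IGHD.fasta`, `IGHJ.fasta`). Missing files are skipped.
#'
#' @param dir Directory containing the FASTA files.
#' @param chains Chains to load (default all of `IG_CHAINS`).
#' @param quiet Suppress per-record warnings.
#' @return A combined germline `data.frame` (see [read_germline()]).
#' @export
read_germline_dir <- function(dir, chains = IG_CHAINS, quiet = FALSE) {
  if (!dir.exists(dir)) stop("germline directory not found: ", dir)
  parts <- list()
  for (chn in chains) {
    for (cls in c("V", "D", "J")) {
      f <- file.path(dir, paste0(chn, cls, ".fasta"))
      if (!file.exists(f)) next
      parts[[paste0(chn, cls)]] <-
        read_germline(f, segment_class = cls, chain = chn, quiet = quiet)
    }
  }
  if (length(parts) == 0L) stop("no <chain><class>.fasta files found in ", dir)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write germline segments to per-chain FASTA files
#'
#' Inverse of [read_germline_dir()]; used to materialise simulated germline
#' fixtures on disk.
#'
#' @param germline Germline `data.frame`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_germline_dir <- function(germline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (chn in unique(germline$chain)) {
    for (cls in unique(germline$class[germline$chain == chn])) {
      sub <- germline[germline$chain == chn & germline$class == cls, ]
      set <- Biostrings::DNAStringSet(sub$nt_seq)
      names(set) <- sub$id
      Biostrings::writeXStringSet(set, file.path(dir, paste0(chn, cls, ".fasta")))
    }
  }
  invisible(dir)
}

# Validate a germline table and split into per-chain V/J context lists used by
# the stage-1 engine.
germline_index <- function(germline, chains = NULL) {
  stopifnot(is.data.frame(germline), all(c("id", "chain", "class", "nt_seq") %in% names(germline)))
  if (is.null(chains)) chains <- intersect(IG_CHAINS, unique(germline$chain))
  idx <- list()
  for (chn in chains) {
    v <- germline[germline$chain == chn & germline$class == "V" & !is.na(germline$anchor_pos), ]
    j <- germline[germline$chain == chn & germline$class == "J" & !is.na(germline$anchor_pos), ]
    d <- germline[germline$chain == chn & germline$class == "D", ]
    if (nrow(v) == 0L || nrow(j) == 0L) next
    idx[[chn]] <- list(
      v_ids = v$id, vx = v$pre_anchor,
      j_ids = j$id, jy = j$post_anchor,
      d_ids = d$id, d_nt = d$nt_seq,
      end_residue = anchor_residue("J", chn)
    )
  }
  if (length(idx) == 0L) stop("germline index is empty for requested chains")
  idx
}
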