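test_that("six-frame translation follows the standard code on both strands", {
  fr <- six_frame_translate("TGTGCT")
  expect_identical(fr[1], "CA")
  expect_identical(six_frame_translate("AGCACA")[4], "CA")  # revcomp of TGTGCT
  expect_identical(six_frame_translate("TGA")[1], "*")
  expect_identical(six_frame_translate("TGTNCTGCT")[1], "CXA")  # fuzzy codon
  # frame offsets drop leading bases
  expect_identical(six_frame_translate("ATGTGCT")[2], "CA")
})

test_that("putative span scan enumerates anchored pairs within length bounds", {
  s <- scan_putative_cdr3("GGCARDYWGG", "IGH")
  expect_identical(nrow(s), 1L)
  expect_identical(c(s$x, s$y), c(2L, 7L))

  s <- scan_putative_cdr3("CACW", "IGH")          # (2,3) span is shorter than 4
  expect_identical(nrow(s), 1L)
  expect_identical(c(s$x, s$y), c(0L, 3L))

  expect_identical(nrow(scan_putative_cdr3("GGCAR*DYWGG", "IGH")), 0L)
  expect_identical(nrow(scan_putative_cdr3("GGCAR*DYWGG", "IGH",
                                           keep_out_of_frame = TRUE)), 1L)
  # light chains end at F, heavy at W
  expect_identical(nrow(scan_putative_cdr3("GCARDYFG", "IGH")), 0L)
  expect_identical(nrow(scan_putative_cdr3("GCARDYFG", "IGK")), 1L)
})

test_that("V/J context matching applies the >4 length rule and distance bound", {
  g <- toy_germline()
  # toy1 pre-anchor ends "...YYYQS"
  expect_identical(match_v("YYYQS", g, "IGH"), "IGHV-toy1")
  expect_setequal(match_v("AASYYYQS", g, "IGH"), "IGHV-toy1")
  # "YYYQA" is distance 0 from toy2 and 1 from toy1: only the best is kept
  expect_identical(match_v("YYYQA", g, "IGH"), "IGHV-toy2")
  # "YYYQG" is distance 1 from both: all equally-best genes reported
  expect_setequal(match_v("YYYQG", g, "IGH"), c("IGHV-toy1", "IGHV-toy2"))
  expect_identical(match_v("YYAA", g, "IGH"), character())        # length 4: rejected
  expect_identical(match_v("QQQQQQ", g, "IGH"), character())      # distance > 1

  # J side: toy1 post-anchor starts "GQGTL"
  expect_identical(match_j("GQGTL", g, "IGH"), "IGHJ-toy1")
  expect_identical(match_j("GQGTA", g, "IGH"), "IGHJ-toy1")  # distance 1
  expect_identical(match_j("GQG", g, "IGH"), character())         # length rule
  # all equally-best genes are reported
  expect_setequal(match_j("GQGXL", g, "IGH"), c("IGHJ-toy1", "IGHJ-toy2"))
})

test_that("stage 1 recovers a constructed junction read with V/J assignment", {
  g <- fixture_germline()
  tx <- simulate_transcripts(g, n = 6, chain = "IGH", seed = 21)
  for (i in seq_len(nrow(tx))) {
    # window: full CDR3 plus 18 nt of context on each side
    s <- tx$cdr3_start[i] - 18L
    e <- tx$cdr3_end[i] + 18L
    read <- make_reads(substr(tx$full_nt[i], s + 1L, e + 1L))
    res <- stage1_assemble(read, g, chains = "IGH")
    expect_identical(nrow(res$candidates), 1L)
    expect_identical(res$candidates$core_aa, tx$true_cdr3_aa[i])
    expect_true(tx$v_id[i] %in% strsplit(res$candidates$v_hits, ",")[[1]])
    expect_true(tx$j_id[i] %in% strsplit(res$candidates$j_hits, ",")[[1]])
    expect_identical(res$candidates$core_nt, tx$true_cdr3_nt[i])

    # one substitution in the V context window leaves the call unchanged
    mut <- read
    pos <- 5L
    old <- substr(mut$nt_seq, pos, pos)
    substr(mut$nt_seq, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    res2 <- stage1_assemble(mut, g, chains = "IGH")
    # the mutation may change at most the matched gene list, never the core
    expect_identical(res2$candidates$core_aa, tx$true_cdr3_aa[i])
  }
})

test_that("random non-receptor reads produce no candidates", {
  g <- fixture_germline()
  set.seed(99)
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 75, replace = TRUE), collapse = "")
  }, character(1))
  res <- stage1_assemble(make_reads(seqs), g, chains = "IGH")
  oracle <- oracle_stage1(make_reads(seqs), g, "IGH")
  expect_identical(nrow(res$candidates), nrow(oracle))
  expect_identical(nrow(res$candidates), 0L)
})

test_that("stage-1 engine equals the brute-force DP oracle on small instances", {
  small_g <- simulate_germline(chains = "IGH", n_v = 3, n_d = 2, n_j = 2, seed = 31)
  tx <- simulate_transcripts(small_g, n = 10, chain = "IGH", seed = 32)
  set.seed(34)
  # windows guaranteed to contain the CDR3, with varying flank widths, plus
  # error-bearing copies and pure noise
  wins <- unlist(lapply(seq_len(nrow(tx)), function(i) {
    vapply(1:3, function(k) {
      lf <- sample(15:30, 1); rf <- sample(15:30, 1)
      substr(tx$full_nt[i], max(1L, tx$cdr3_start[i] - lf + 1L),
             min(nchar(tx$full_nt[i]), tx$cdr3_end[i] + rf + 1L))
    }, character(1))
  }))
  mutated <- vapply(wins[seq(1, length(wins), by = 3)], function(s) {
    p <- sample.int(nchar(s), 1)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(s, p, p)), 1)
    s
  }, character(1), USE.NAMES = FALSE)
  noise <- vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 75, replace = TRUE), collapse = "")
  }, character(1))
  reads <- make_reads(c(wins, mutated, noise))
  res <- stage1_assemble(reads, small_g, chains = "IGH")

  got <- res$candidates[order(res$candidates$read_id),
                        c("read_id", "core_aa", "ctx", "v_hits", "j_hits")]
  got$v_hits <- vapply(strsplit(got$v_hits, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  got$j_hits <- vapply(strsplit(got$j_hits, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  rownames(got) <- NULL
  want <- oracle_stage1(reads, small_g, "IGH")
  rownames(want) <- NULL
  expect_gt(nrow(want), 0L)
  expect_identical(got, want)
})

test_that("stage 2 merges partial reads on exact overlap of at least 15 nt", {
  g <- fixture_germline()
  tx <- simulate_transcripts(g, n = 4, chain = "IGH", seed = 41)
  for (i in seq_len(nrow(tx))) {
    # split the CDR3 across two short reads overlapping by exactly 20 nt:
    # the V-side read carries the anchor C plus 20 nt of V context, the J-side
    # read the terminal residue plus 21 nt of J context (0-based coordinates)
    mid <- as.integer((tx$cdr3_start[i] + tx$cdr3_end[i]) / 2)
    v_read <- substr(tx$full_nt[i], tx$cdr3_start[i] - 20L + 1L, mid + 9L + 1L)
    j_read <- substr(tx$full_nt[i], mid - 10L + 1L, tx$cdr3_end[i] + 21L + 1L)
    reads <- make_reads(c(v_read, j_read), ids = c("vside", "jside"))
    res <- stage1_assemble(reads, g, chains = "IGH")
    merged <- stage2_merge(res$v_partial, res$j_partial)
    expect_identical(nrow(merged), 1L)
    expect_identical(merged$core_aa, tx$true_cdr3_aa[i])
    expect_identical(merged$stage, 2L)

    # overlap of 14 nt only: below threshold, no merge
    j_short <- substr(tx$full_nt[i], mid - 4L + 1L, tx$cdr3_end[i] + 21L + 1L)
    res2 <- stage1_assemble(make_reads(c(v_read, j_short), ids = c("v", "j")), g,
                            chains = "IGH")
    expect_identical(nrow(stage2_merge(res2$v_partial, res2$j_partial)), 0L)
  }
  # zero J-side reads -> empty result
  expect_identical(nrow(stage2_merge(data.frame(), NULL)), 0L)
})

test_that("stage 2 never removes stage-1 candidates and assembly gates by read length", {
  g <- fixture_germline()
  tx <- simulate_transcripts(g, n = 30, chain = "IGH", seed = 51)
  sim <- simulate_reads(tx, read_length = 50, coverage = 8, seed = 52)
  with_s2 <- assemble_cdr3(sim$reads, g, chains = "IGH", stage2 = TRUE)
  without <- assemble_cdr3(sim$reads, g, chains = "IGH", stage2 = FALSE)
  expect_true(all(without$read_id %in% with_s2$read_id))
  expect_true(nrow(with_s2) >= nrow(without))
  # auto mode enables stage 2 at 50 bp
  auto <- assemble_cdr3(sim$reads, g, chains = "IGH")
  expect_identical(nrow(auto), nrow(with_s2))
})

test_that("noiseless junction-spanning reads with context are always recovered", {
  g <- fixture_germline()
  for (chain in c("IGH", "IGL")) {
    tx <- simulate_transcripts(g, n = 25, chain = chain, seed = 61)
    reads <- make_reads(
      substr(tx$full_nt, tx$cdr3_start - 14L, tx$cdr3_end + 16L),
      ids = tx$transcript_id
    )
    cand <- assemble_cdr3(reads, g, chains = chain, stage2 = FALSE)
    sc <- score_assembly(cand$core_aa, unique(tx$true_cdr3_aa))
    expect_identical(sc$recall, 1)
    expect_identical(sc$precision, 1)
    # every reported core starts with C and ends with the chain's residue
    last <- substr(cand$core_aa, nchar(cand$core_aa), nchar(cand$core_aa))
    expect_true(all(substr(cand$core_aa, 1, 1) == "C"))
    expect_true(all(last == ifelse(chain == "IGH", "W", "F")))
  }
})
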