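test_that("transcript simulation is deterministic and structurally valid", {
  g <- fixture_germline()
  tx1 <- simulate_transcripts(g, n = 10, chain = "IGH", seed = 12)
  tx2 <- simulate_transcripts(g, n = 10, chain = "IGH", seed = 12)
  expect_identical(tx1, tx2)

  expect_true(all(substr(tx1$true_cdr3_aa, 1, 1) == "C"))
  expect_true(all(substr(tx1$true_cdr3_aa, nchar(tx1$true_cdr3_aa),
                         nchar(tx1$true_cdr3_aa)) == "W"))
  expect_false(any(grepl("*", tx1$true_cdr3_aa, fixed = TRUE)))  # in frame
  # the recorded CDR3 span matches the sequence content
  expect_identical(substr(tx1$full_nt, tx1$cdr3_start + 1L, tx1$cdr3_end + 1L),
                   tx1$true_cdr3_nt)
  # abundances: normalised Zipf by default
  expect_equal(sum(tx1$abundance), 1, tolerance = 1e-12)
  expect_true(all(diff(tx1$abundance) < 0))
  tx_flat <- simulate_transcripts(g, n = 10, chain = "IGH", exponent = 0, seed = 12)
  expect_true(all(abs(tx_flat$abundance - 0.1) < 1e-12))
})

test_that("every simulated transcript passes the independent CDR3 oracle", {
  g <- fixture_germline()
  tx <- simulate_transcripts(g, n = 8, chain = "IGH", seed = 13)
  got <- oracle_stage1(
    make_reads(tx$full_nt, ids = tx$transcript_id), g, "IGH")
  expect_identical(nrow(got), nrow(tx))
  expect_identical(got$core_aa[match(tx$transcript_id, got$read_id)],
                   tx$true_cdr3_aa)
})

test_that("read counts follow the per-transcript coverage arithmetic", {
  g <- fixture_germline()
  tx <- simulate_transcripts(g, n = 1, chain = "IGH", seed = 14)
  tx$full_nt <- substr(tx$full_nt, 1, 300)   # force a 300 nt transcript
  sim <- simulate_reads(tx, read_length = 75, coverage = 8, error_rate = 0, seed = 15)
  # round(8 * 300 / 75) = 32 mates = 16 fragments
  expect_identical(nrow(sim$reads), 32L)
  expect_identical(nrow(sim$manifest), 32L)
  expect_true(all(nchar(sim$reads$nt_seq) == 75L))
})

test_that("read simulation is seed-reproducible and error-model robust", {
  g <- fixture_germline()
  tx <- simulate_transcripts(g, n = 5, chain = "IGH", seed = 16)
  s1 <- simulate_reads(tx, read_length = 50, coverage = 4, seed = 17)
  s2 <- simulate_reads(tx, read_length = 50, coverage = 4, seed = 17)
  expect_identical(s1, s2)
  # degenerate error rate still yields legal reads
  s3 <- simulate_reads(tx, read_length = 50, coverage = 2, error_rate = 0.5, seed = 18)
  expect_true(all(grepl("^[ACGT]+$", s3$reads$nt_seq)))
  expect_true(all(nchar(s3$reads$nt_seq) == 50L))
})

test_that("manifest junction flags agree with an interval-overlap recount", {
  g <- fixture_germline()
  tx <- simulate_transcripts(g, n = 10, chain = "IGH", seed = 19)
  sim <- simulate_reads(tx, read_length = 75, coverage = 4, error_rate = 0, seed = 20)
  # the recorded junction interval is exactly the non-templated region:
  # everything before it is a prefix of the V gene, everything after a suffix
  # of the J gene
  for (i in seq_len(nrow(tx))) {
    v_nt <- g$nt_seq[g$id == tx$v_id[i]]
    j_nt <- g$nt_seq[g$id == tx$j_id[i]]
    pre <- substr(tx$full_nt[i], 1L, tx$junction_start[i])
    post <- substr(tx$full_nt[i], tx$junction_end[i] + 1L, nchar(tx$full_nt[i]))
    expect_identical(pre, substr(v_nt, 1L, nchar(pre)))
    expect_identical(post, substr(j_nt, nchar(j_nt) - nchar(post) + 1L, nchar(j_nt)))
  }
  m <- sim$manifest
  jx <- tx[match(m$transcript_id, tx$transcript_id), ]
  recount <- m$start <= jx$junction_end & m$end >= jx$junction_start + 1L
  expect_identical(m$contains_junction, recount)
  expect_gt(sum(recount), 0L)
})

test_that("mixtures interleave decoys at the requested ratio", {
  g <- fixture_germline()
  tx <- simulate_transcripts(g, n = 3, chain = "IGH", seed = 22)
  sim <- simulate_reads(tx, read_length = 50, coverage = 1, seed = 23)
  rec <- sim$reads[1:10, ]
  mix <- make_mixture(rec, ratio = 10, seed = 24)
  expect_identical(nrow(mix$reads), 110L)
  expect_setequal(mix$receptor_ids, rec$read_id)
  expect_true(all(rec$read_id %in% mix$reads$read_id))
  # ratio 0 is a pass-through (shuffled)
  mix0 <- make_mixture(rec, ratio = 0, seed = 25)
  expect_setequal(mix0$reads$read_id, rec$read_id)
  # determinism
  mix2 <- make_mixture(rec, ratio = 10, seed = 24)
  expect_identical(mix$reads, mix2$reads)
})

test_that("FASTQ round trip preserves ids and sequences", {
  g <- fixture_germline()
  tx <- simulate_transcripts(g, n = 3, chain = "IGK", seed = 26)
  sim <- simulate_reads(tx, read_length = 50, coverage = 2, seed = 27)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, f)
  back <- read_candidates_fastq(f)
  expect_identical(back$read_id, sim$reads$read_id)
  expect_identical(back$nt_seq, sim$reads$nt_seq)
  expect_true(all(nchar(back$qual) == 50L))
})
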