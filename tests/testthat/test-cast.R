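nodes_df <- function(aa, count) {
  data.frame(aa_seq = aa, count = count, v_hits = "", j_hits = "",
             rep_nt = "", stringsAsFactors = FALSE)
}

test_that("affinity is the inverse Levenshtein distance", {
  expect_identical(cdr3_affinity("CARDW", "CARGW"), 1)
  expect_identical(cdr3_affinity("CARDW", "CAW"), 0.5)
  expect_equal(cdr3_affinity("kitten", "sitting"), 1 / 3)
  expect_error(cdr3_affinity("CARDW", "CARDW"))
})

test_that("CAST groups close sequences and separates distant ones", {
  cl <- cast_cluster(nodes_df(c("CARDW", "CARGW"), c(10L, 1L)), tau = 0.25)
  expect_identical(length(cl), 1L)

  # distance 4 = affinity 0.25: the boundary is inclusive, one cluster;
  # raising tau past the boundary splits them
  nd <- nodes_df(c("CAAAAW", "CTTTTW"), c(5L, 5L))
  expect_identical(length(cast_cluster(nd, tau = 0.25)), 1L)
  expect_identical(length(cast_cluster(nd, tau = 0.30)), 2L)
  expect_identical(length(cast_cluster(nd[2:1, ], tau = 0.30)), 2L)  # order-free

  # tau above 1 makes every node a singleton (affinity is at most 1)
  nd <- nodes_df(c("CARDW", "CARGW", "CARDF"), c(3L, 2L, 1L))
  expect_identical(length(cast_cluster(nd, tau = 1.01)), 3L)
  # tau near zero yields a single cluster
  expect_identical(length(cast_cluster(nd, tau = 1e-6)), 1L)
})

test_that("CAST partitions are disjoint, covering, and count-conserving", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    aa <- unique(vapply(seq_len(n), function(i) {
      paste0("C", paste(sample(LETTERS[LETTERS %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]],
                               sample(6:14, 1), replace = TRUE), collapse = ""), "W")
    }, character(1)))
    nd <- nodes_df(aa, sample(1:50, length(aa), replace = TRUE))
    cl <- cast_cluster(nd, tau = 0.25)
    members <- unlist(cl)
    expect_identical(sort(members), seq_len(nrow(nd)))     # disjoint + covering
    expect_identical(sum(vapply(cl, function(ix) sum(nd$count[ix]), numeric(1))),
                     as.numeric(sum(nd$count)))            # conservation
  }
})

test_that("weighted consensus takes the count-weighted majority", {
  expect_identical(
    weighted_consensus(nodes_df(c("CARDW", "CARGW"), c(3L, 1L)))$consensus_aa,
    "CARDW")
  # exact count tie at the variable position: alphabetical residue wins
  expect_identical(
    weighted_consensus(nodes_df(c("CARDW", "CARGW"), c(2L, 2L)))$consensus_aa,
    "CARDW")
  expect_identical(
    weighted_consensus(nodes_df("CQQW", 1L))$consensus_aa, "CQQW")
  # the dominant length class is chosen first (ties to the shorter length)
  expect_identical(
    weighted_consensus(nodes_df(c("CAAAW", "CAAGGW"), c(2L, 3L)))$consensus_aa,
    "CAAGGW")
  expect_identical(
    weighted_consensus(nodes_df(c("CAAAW", "CAAGGW"), c(3L, 3L)))$consensus_aa,
    "CAAAW")
  # gene assignments: union filtered to maximal total weight
  nd <- nodes_df(c("CARDW", "CARGW"), c(3L, 1L))
  nd$v_hits <- c("V1,V2", "V2")
  nd$j_hits <- c("J1", "J2")
  cons <- weighted_consensus(nd)
  expect_identical(cons$v_genes, "V2")        # weight 4 vs 3
  expect_identical(cons$j_genes, "J1")        # weight 3 vs 1
})

test_that("CAST recovers planted clonotypes from Levenshtein-1 satellites", {
  set.seed(123)
  alpha <- strsplit("ADEGHIKLMNPQRSTVY", "")[[1]]
  parents <- unique(vapply(1:20, function(i) {
    paste0("C", paste(sample(alpha, 12, replace = TRUE), collapse = ""), "W")
  }, character(1)))
  # planted parents must be mutually distant for the recovery claim to apply
  expect_true(min(utils::adist(parents)[upper.tri(diag(length(parents)))]) > 4)
  rows <- list()
  for (p in parents) {
    cnt <- sample(30:60, 1)
    rows[[length(rows) + 1L]] <- nodes_df(p, cnt)
    for (s in seq_len(sample(1:2, 1))) {       # satellites at distance 1
      pos <- sample(2:13, 1)
      sat <- p
      substr(sat, pos, pos) <- sample(setdiff(alpha, substr(p, pos, pos)), 1)
      rows[[length(rows) + 1L]] <- nodes_df(sat, max(1L, as.integer(cnt * 0.08)))
    }
  }
  nd <- do.call(rbind, rows)
  nd <- nd[!duplicated(nd$aa_seq), ]
  cl <- cast_cluster(nd, tau = 0.25)
  recovered <- vapply(cl, function(ix) weighted_consensus(nd[ix, ])$consensus_aa,
                      character(1))
  expect_setequal(recovered, parents)
  expect_identical(sum(vapply(cl, function(ix) sum(nd$count[ix]), numeric(1))),
                   as.numeric(sum(nd$count)))
})
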