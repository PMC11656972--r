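test_that("match_truth counts TP and both FP classes by overlap", {
  loci <- data.frame(contig = "t", start = seq(0L, 24L) * 10000L,
                     end = seq(0L, 24L) * 10000L + 5000L)
  gaps <- data.frame(contig = "t", start = loci$start, end = loci$end)
  res <- fake_result(gaps, cluster_members = list(1:25))
  m <- match_truth(res, fake_truth(loci, "ACGT"))
  expect_equal(m, list(TP = 25L, FP_r = 0L, FP_nr = 0L))

  # an extra cluster in a region without truth is FP_r
  gaps2 <- rbind(gaps, data.frame(contig = "t",
                                  start = 400000L + c(0L, 2000L, 4000L),
                                  end = 401000L + c(0L, 2000L, 4000L)))
  res2 <- fake_result(gaps2, cluster_members = list(1:25, 26:28))
  m2 <- match_truth(res2, fake_truth(loci, "ACGT"))
  expect_equal(m2$FP_r, 1L)
  expect_equal(m2$TP, 25L)

  # a non-repetitive record off-truth is FP_nr; on-truth is not
  res3 <- fake_result(gaps2[1:26, ], cluster_members = list(1:25),
                      non_rep = 26L)
  expect_equal(match_truth(res3, fake_truth(loci, "A"))$FP_nr, 1L)
  res4 <- fake_result(gaps, cluster_members = list(1:24), non_rep = 25L)
  expect_equal(match_truth(res4, fake_truth(loci, "A"))$FP_nr, 0L)

  # partial coverage: a locus covered < 50% by gaps is not a TP
  half <- data.frame(contig = "t", start = loci$start,
                     end = loci$start + 2400L)
  res5 <- fake_result(half, cluster_members = list(1:25))
  expect_equal(match_truth(res5, fake_truth(loci, "A"))$TP, 0L)
  # fragmented detection still counts once when the union reaches 50%
  frag <- rbind(data.frame(contig = "t", start = loci$start[1],
                           end = loci$start[1] + 1500L),
                data.frame(contig = "t", start = loci$start[1] + 2000L,
                           end = loci$start[1] + 3500L))
  res6 <- fake_result(frag, cluster_members = list(1:2))
  expect_equal(match_truth(res6, fake_truth(loci[1, ], "A"))$TP, 1L)

  # empty run output
  empty <- fake_result(data.frame(contig = character(), start = integer(),
                                  end = integer()))
  expect_equal(match_truth(empty, fake_truth(loci, "A")),
               list(TP = 0L, FP_r = 0L, FP_nr = 0L))
})

test_that("percent_identity agrees with an independent aligner oracle", {
  set.seed(401)
  s <- rand_dna(2000)
  expect_equal(percent_identity(s, s), 100)

  # consensus missing 2 terminal bases still hits 100 (local semantics)
  expect_equal(percent_identity(substr(s, 2, 1999), s), 100)

  # unrelated random sequences: no qualifying alignment
  expect_equal(percent_identity(rand_dna(2000), rand_dna(2000)), 0)

  # cross-check against Biostrings local alignment on mutated pairs
  for (rate in c(0.01, 0.05)) {
    a <- rand_dna(800)
    b <- mutate_seq(a, rate)
    ours <- percent_identity(a, b)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 1, gapExtension = 1)
    oracle <- Biostrings::pid(ref, type = "PID2")
    expect_lt(abs(ours - oracle), 1.5)
  }
})

test_that("metrics_row reproduces the validation table semantics", {
  loci <- data.frame(contig = "t", start = c(0L, 50000L), end = c(5000L, 55000L))
  gaps <- data.frame(contig = "t", start = loci$start, end = loci$end)
  set.seed(402)
  insert <- rand_dna(5000)
  res <- fake_result(gaps, cluster_members = list(1:2), consensus = insert)
  row <- metrics_row(res, fake_truth(loci, insert))
  expect_equal(row$TP, 2L)
  expect_equal(row$consensus_length, 5000L)
  expect_equal(row$similarity_pct, 100)

  # no detected cluster -> all-zero row
  empty <- fake_result(data.frame(contig = character(), start = integer(),
                                  end = integer()))
  row0 <- metrics_row(empty, fake_truth(loci, insert))
  expect_equal(unlist(row0), c(TP = 0, FP_nr = 0, FP_r = 0,
                               consensus_length = 0, similarity_pct = 0))
})

test_that("TP is higher at 5x than at 1x random coverage (small replicate)", {
  # statistical monotonicity on matched seeds, small desk-scale genomes
  wins <- 0L
  for (seed in 1:3) {
    tp <- vapply(c(1, 5), function(cov) {
      sc <- simulate_scenario("random", cov, seed = seed, template_bp = 3e5,
                              n_copies = 4, insert_bp = 2000)
      res <- run_pipeline(sc$assembly, reads = sc$reads,
                          out_dir = tempfile())
      match_truth(res, sc$truth)$TP
    }, integer(1))
    if (tp[2] >= tp[1]) wins <- wins + 1L
  }
  expect_equal(wins, 3L)
})
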