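test_that("build_index enumerates k-mers, skips N, enforces minimum k", {
  # 14-bp contig, k=11 -> 4 k-mer start positions
  cs <- contig_set(c(c1 = "ACGTACGGTTACCA"))
  idx <- build_index(cs, k = 11)
  st <- index_stats(idx)
  expect_equal(st$n_positions, 4)

  expect_error(build_index(cs, k = 10), "k must be >= 11")

  # all-N contig -> empty index
  nn <- contig_set(c(n = paste(rep("N", 30), collapse = "")))
  expect_equal(index_stats(build_index(nn, 11))$n_positions, 0)

  # a k-mer shared by two contigs maps to 2 positions
  shared <- "ACGTACGTACG"
  cs2 <- contig_set(c(a = paste0(shared, "TTTTT"), b = paste0("GGGGG", shared)))
  idx2 <- build_index(cs2, 11)
  hits <- gapdelta:::index_lookup(idx2, shared)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits[, 1], c(1L, 2L))
})

test_that("a read identical to a unique window maps perfectly", {
  set.seed(21)
  ref <- rand_dna(2000)
  cs <- contig_set(c(ref = ref))
  idx <- build_index(cs)
  read <- c(q = substr(ref, 501, 600))
  pl <- map_read(read, idx)
  expect_true(pl$mapped)
  expect_equal(pl$contig, "ref")
  expect_equal(pl$ref_start, 500L)
  expect_equal(pl$ref_end, 600L)
  expect_equal(pl$edits, 0L)
  expect_equal(pl$cigar, "100M")
})

test_that("junction reads are soft-clipped at the insertion boundary", {
  set.seed(22)
  template <- rand_dna(4000)
  insert <- guard_insert(rand_dna(1000), template, 2000)
  # insertion at template position 2000
  # mapping reference lacks the insert: a read whose first 60 bp match the
  # reference up to the insertion point and whose last 40 bp come from the
  # novel insert aligns only its reference side; the insert side is clipped
  ref <- contig_set(c(t = template))
  idx0 <- build_index(ref)
  read <- c(j = paste0(substr(template, 1941, 2000), substr(insert, 1, 40)))
  pl <- map_read(read, idx0)
  expect_true(pl$mapped)
  expect_equal(pl$ref_end, 2000L) # no aligned base inside the insert
  expect_equal(pl$cigar, "60M40S")

  # against the insertion-carrying target, a read wholly from the template
  # spanning the insertion point aligns its majority side only and depth
  # stops exactly at the junction
  target <- paste0(substr(template, 1, 2000), insert,
                   substr(template, 2001, 4000))
  cs <- contig_set(c(t = target))
  idx <- build_index(cs)
  read2 <- c(j2 = substr(template, 1941, 2040)) # 60 bp left, 40 bp right
  pl2 <- map_read(read2, idx)
  expect_true(pl2$mapped)
  expect_equal(pl2$ref_end, 2000L) # depth stops exactly at the junction
  expect_equal(pl2$query_end - pl2$query_start, 60L)
})

test_that("clip rescue maps the minority side as a supplementary placement", {
  set.seed(25)
  template <- rand_dna(4000)
  insert <- guard_insert(rand_dna(1000), template, 2000)
  target <- paste0(substr(template, 1, 2000), insert,
                   substr(template, 2001, 4000))
  cs <- contig_set(c(t = target))
  idx <- build_index(cs)
  read <- setNames(substr(template, 1941, 2040), "j")
  pl <- map_reads(read, idx)
  expect_equal(nrow(pl), 2L)
  expect_true(any(pl$supplementary))
  sup <- pl[pl$supplementary, ]
  # the clipped 40 bp resume right after the 1000-bp insert
  expect_equal(sup$ref_start, 3000L)
  expect_equal(sup$ref_end, 3040L)
})

test_that("random reads with no seed hits stay unmapped", {
  set.seed(23)
  cs <- contig_set(c(ref = rand_dna(5000)))
  idx <- build_index(cs)
  reads <- setNames(vapply(rep(100, 20), rand_dna, character(1)),
                    paste0("rnd", 1:20))
  pl <- map_reads(reads, idx)
  expect_false(any(pl$mapped))
})

test_that("uniform tiling reads of the reference give depth 1 everywhere", {
  set.seed(24)
  cs <- contig_set(c(ref = rand_dna(3000)))
  reads <- reads_uniform(cs, coverage = 1, read_length = 100)
  dr <- depth_from_reads(reads, cs)
  d <- dr$depth$depth$ref
  expect_true(all(d[1:2900] == 1L))
  expect_true(all(d >= 0L))
  expect_equal(unname(dr$counters["mapped"]), 30)
})

test_that("a novel insertion produces a zero-depth run of exactly its length", {
  set.seed(26)
  tpl_seq <- rand_dna(60000)
  at <- 30000L
  insert <- guard_insert(rand_dna(5000), tpl_seq, at)
  template <- contig_set(c(t = tpl_seq))
  modified <- contig_set(c(t = paste0(substr(tpl_seq, 1, at), insert,
                                      substr(tpl_seq, at + 1, 60000))))
  reads <- reads_uniform(template, coverage = 5, read_length = 100)
  dr <- depth_from_reads(reads, modified)
  d <- dr$depth$depth$t
  runs <- rle(d == 0L)
  zero_lens <- runs$lengths[runs$values]
  expect_true(5000L %in% zero_lens)
  expect_equal(sum(d[(at + 1):(at + 5000)]), 0L)
})

test_that("mapper placements and emitted SAM give identical depth", {
  set.seed(27)
  cs <- contig_set(c(a = rand_dna(4000), b = rand_dna(2500)))
  reads <- reads_random(cs, coverage = 3, read_length = 80)
  dr <- depth_from_reads(reads, cs)
  sam <- tempfile(fileext = ".sam")
  write_sam(dr$placements, reads, cs, sam)
  d2 <- depth_from_sam(sam, cs)
  expect_identical(lapply(dr$depth$depth, as.integer),
                   lapply(d2$depth, as.integer))
  expect_equal(dr$depth$genome_mean, d2$genome_mean)
})

test_that("mapping is deterministic and input-order invariant", {
  set.seed(28)
  # two identical repeat copies: tied reads must go to a deterministic copy
  copy <- rand_dna(600)
  cs <- contig_set(c(r = paste0(rand_dna(2000), copy, rand_dna(2000), copy,
                                rand_dna(2000))))
  idx <- build_index(cs)
  reads <- setNames(substring(copy, seq(1, 451, 50), seq(100, 550, 50)),
                    paste0("tied", 1:10))
  pl1 <- map_reads(reads, idx)
  pl2 <- map_reads(rev(reads), idx)
  pl2 <- pl2[match(pl1$read_id, pl2$read_id), ]
  expect_equal(pl1$ref_start, pl2$ref_start)
  expect_true(all(pl1$n_ties[!pl1$supplementary] == 2L))
  # hash spreading uses both loci across the read set
  expect_equal(length(unique(pl1$ref_start %/% 2000)), 2L)
})
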