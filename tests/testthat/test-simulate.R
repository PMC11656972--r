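test_that("random_sequence is reproducible, balanced and validated", {
  expect_identical(random_sequence(4, seed = 5), random_sequence(4, seed = 5))
  s <- random_sequence(5000, seed = 6)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 5000
  expect_true(abs(gc - 0.5) < 0.05)
  expect_error(random_sequence(0), ">= 1")
})

test_that("insert_copies keeps exact length bookkeeping and is invertible", {
  tpl <- contig_set(c(t = random_sequence(1e6, seed = 7)))
  one <- insert_copies(tpl, "ACGTACGTAC", n = 1, seed = 8)
  expect_equal(nchar(one$modified[["t"]]), 1000010L)
  expect_equal(one$truth$loci$end - one$truth$loci$start, 10L)

  ins <- insert_copies(tpl, random_sequence(5000, seed = 9), n = 25, seed = 10)
  expect_equal(nchar(ins$modified[["t"]]), 1e6 + 125000)
  expect_equal(nrow(ins$truth$loci), 25L)
  # spacing: >= 25 kb between template points, >= 10 kb from ends
  tpl_pts <- ins$truth$loci$start - (seq_len(25) - 1) * 5000
  expect_true(all(diff(tpl_pts) >= 25000))
  expect_true(tpl_pts[1] >= 10000 && tpl_pts[25] <= 1e6 - 10000)

  # splice inverse: removing the truth loci reproduces the template
  mod <- ins$modified[["t"]]
  loci <- ins$truth$loci
  keep <- substring(mod, c(1, loci$end + 1),
                    c(loci$start, nchar(mod)))
  expect_identical(paste(keep, collapse = ""), tpl[["t"]])
  # and every locus carries the insert sequence
  expect_true(all(substring(mod, loci$start + 1, loci$end) ==
                    ins$truth$insert))

  expect_error(insert_copies(tpl, "ACGT", n = 100), "too short")
})

test_that("reads_uniform tiles with the exact stride", {
  cs <- contig_set(c(t = random_sequence(1000, seed = 11)))
  r <- reads_uniform(cs, coverage = 1, read_length = 100)
  expect_equal(length(r), 10L)
  expect_equal(names(r), sprintf("u_t_%d", seq(0, 900, 100)))
  expect_true(all(r == substring(cs[["t"]], seq(0, 900, 100) + 1,
                                 seq(0, 900, 100) + 100)))
  # coverage 5: each interior position covered exactly 5x
  cs2 <- contig_set(c(t = random_sequence(2000, seed = 12)))
  r5 <- reads_uniform(cs2, coverage = 5, read_length = 100)
  d <- depth_from_reads(r5, cs2)$depth$depth$t
  expect_true(all(d[100:1800] == 5L))
})

test_that("reads_random has the expected count, mean depth and determinism", {
  cs <- contig_set(c(t = random_sequence(2e5, seed = 13)))
  r1 <- reads_random(cs, coverage = 10, read_length = 100, seed = 14)
  expect_equal(length(r1), 20000L)
  r2 <- reads_random(cs, coverage = 10, read_length = 100, seed = 14)
  expect_identical(r1, r2)
  # mean per-position depth close to the target coverage
  d <- depth_from_reads(r1, cs)$depth
  expect_true(abs(d$genome_mean - 10) / 10 < 0.05)
  # at coverage 1 some positions are uncovered
  rlow <- reads_random(cs, coverage = 1, read_length = 100, seed = 15)
  dlow <- depth_from_reads(rlow, cs)$depth$depth$t
  expect_gt(sum(dlow == 0L), 0L)
})

test_that("reads_ancient reproduces fractions, fragment sizes and damage", {
  cs <- contig_set(c(t = random_sequence(5e5, seed = 16)))
  r <- reads_ancient(cs, coverage = 1, seed = 17)
  cls <- sub("_[0-9]+$", "", names(r))
  tab <- table(cls) / length(r)
  expect_true(abs(tab[["anc_endo"]] - 0.82) < 0.02)
  expect_true(abs(tab[["anc_bact"]] - 0.10) < 0.02)
  expect_true(abs(tab[["anc_mod"]] - 0.08) < 0.02)
  expect_true(abs(mean(nchar(r)) - 50) < 2)
  expect_true(all(nchar(r) >= 25 & nchar(r) <= 150))

  # deamination off: endogenous reads are exact template substrings
  p0 <- ancient_params(deamination_p0 = 0)
  r0 <- reads_ancient(cs, coverage = 0.2, params = p0, seed = 18)
  endo <- r0[startsWith(names(r0), "anc_endo")]
  hit <- vapply(endo[1:50], function(x) grepl(x, cs[["t"]], fixed = TRUE),
                logical(1))
  expect_true(all(hit))

  # deamination on: C->T / G->A excess at terminal positions
  r1 <- reads_ancient(cs, coverage = 0.5, seed = 19)
  endo1 <- r1[startsWith(names(r1), "anc_endo")]
  first <- substr(endo1, 1, 1)
  # template is ~25% C; with p0 = 0.3 terminal damage, observed C frequency
  # at the 5' end drops well below 20%
  expect_lt(mean(first == "C"), 0.20)
  expect_gt(mean(first == "T"), 0.30)

  expect_error(ancient_params(frac_bacterial = 0.6, frac_modern = 0.5),
               "at most 1")
})

test_that("generators are pure functions of their seed", {
  s1 <- simulate_scenario("random", 2, seed = 20, template_bp = 5e4,
                          n_copies = 1, insert_bp = 1200)
  s2 <- simulate_scenario("random", 2, seed = 20, template_bp = 5e4,
                          n_copies = 1, insert_bp = 1200)
  expect_identical(s1$assembly, s2$assembly)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$loci, s2$truth$loci)
})
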