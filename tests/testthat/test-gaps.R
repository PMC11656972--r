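test_that("detect_gaps returns maximal low-depth runs", {
  d <- toy_depth(c(3, 3, 0, 0, 0, 3))
  expect_equal(detect_gaps(d, 0),
               data.frame(contig = "c", start = 2L, end = 5L))
  expect_equal(nrow(detect_gaps(toy_depth(c(1, 2, 3)), 0)), 0L)
  g <- detect_gaps(toy_depth(c(0, 0, 1, 0)), 0)
  expect_equal(g$start, c(0L, 3L))
  expect_equal(g$end, c(2L, 4L))
  # threshold semantics: depth <= threshold is uncovered
  g2 <- detect_gaps(toy_depth(c(2, 1, 1, 2)), 1)
  expect_equal(g2$start, 1L)
  expect_equal(g2$end, 3L)
})

test_that("detect_gaps agrees with a brute-force per-position oracle", {
  brute <- function(d, thr) {
    in_gap <- d <= thr
    gaps <- list()
    i <- 1
    while (i <= length(d)) {
      if (in_gap[i]) {
        j <- i
        while (j < length(d) && in_gap[j + 1]) j <- j + 1
        # 1-based inclusive run [i, j] -> 0-based half-open [i-1, j)
        gaps[[length(gaps) + 1]] <- c(i - 1, j)
        i <- j + 1
      } else i <- i + 1
    }
    if (length(gaps) == 0)
      return(data.frame(contig = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    m <- do.call(rbind, gaps)
    data.frame(contig = "c", start = as.integer(m[, 1]),
               end = as.integer(m[, 2]), stringsAsFactors = FALSE)
  }
  set.seed(101)
  for (rep in 1:1000) {
    d <- sample(0:3, sample(1:50, 1), replace = TRUE)
    thr <- sample(0:2, 1)
    expect_identical(detect_gaps(toy_depth(d), thr), brute(d, thr))
  }
  # conservation: every low position lies in exactly one detected gap
  set.seed(102)
  d <- sample(0:2, 500, replace = TRUE)
  g <- detect_gaps(toy_depth(d), 0)
  covered <- logical(500)
  for (i in seq_len(nrow(g))) covered[(g$start[i] + 1):g$end[i]] <- TRUE
  expect_identical(covered, d == 0)
})

test_that("merge_gaps merges by separation, is idempotent and monotone", {
  g <- data.frame(contig = "c", start = c(2L, 6L), end = c(5L, 9L))
  m1 <- merge_gaps(g, 1)
  expect_equal(m1, data.frame(contig = "c", start = 2L, end = 9L))
  expect_equal(merge_gaps(g, 0), g)
  touching <- data.frame(contig = "c", start = c(0L, 3L), end = c(3L, 6L))
  expect_equal(merge_gaps(touching, 0),
               data.frame(contig = "c", start = 0L, end = 6L))
  expect_error(merge_gaps(data.frame(contig = "c", start = c(5L, 0L),
                                     end = c(8L, 3L)), 1), "sorted")
  # idempotence and d-monotonicity (refinement) on random interval sets
  set.seed(103)
  for (rep in 1:50) {
    pos <- 0L
    rows <- lapply(1:10, function(j) {
      s <- pos + sample(0:15, 1)
      e <- s + sample(1:20, 1)
      pos <<- e
      c(s, e)
    })
    m <- do.call(rbind, rows)
    g <- data.frame(contig = "c", start = as.integer(m[, 1]),
                    end = as.integer(m[, 2]))
    d1 <- sample(0:10, 1); d2 <- d1 + sample(1:10, 1)
    m1 <- merge_gaps(g, d1)
    expect_identical(merge_gaps(m1, d1), m1)
    m2 <- merge_gaps(g, d2)
    expect_true(nrow(m2) <= nrow(m1))
    # refinement: every d1-gap lies within a single d2-gap
    for (i in seq_len(nrow(m1)))
      expect_true(any(m2$start <= m1$start[i] & m2$end >= m1$end[i]))
  }
})

test_that("filter_by_length is inclusive at the 1000-bp default", {
  g <- data.frame(contig = "c", start = c(0L, 2000L), end = c(999L, 3000L))
  expect_equal(filter_by_length(g, 1000),
               data.frame(contig = "c", start = 2000L, end = 3000L))
  exact <- data.frame(contig = "c", start = 0L, end = 1000L)
  expect_equal(nrow(filter_by_length(exact, 1000)), 1L)
  expect_equal(nrow(filter_by_length(g[0, ], 1000)), 0L)
})

test_that("gap_bias matches the 2f/(g+f)-1 formula at anchor points", {
  # f = g: constant depth everywhere -> bias 0
  d <- toy_depth(rep(10L, 40000))
  g1 <- data.frame(contig = "c", start = 15000L, end = 16000L)
  expect_equal(gap_bias(g1, d), 0, ignore_attr = TRUE)

  # f = 0 with positive genome mean -> -1
  dep <- c(rep(10L, 20000), rep(0L, 21000), rep(10L, 19000))
  d2 <- toy_depth(dep)
  g2 <- data.frame(contig = "c", start = 30000L, end = 31000L)
  expect_equal(gap_bias(g2, d2), -1, ignore_attr = TRUE)

  # f = 3g -> 0.5 (f = 30, g = 10 via explicit construction)
  dep3 <- integer(4000)
  dep3[1001:1500] <- 30L; dep3[2501:3000] <- 30L # flanks
  dep3[c(1:1000, 3001:4000)] <- 5L               # far regions
  d3 <- toy_depth(dep3)
  expect_equal(d3$genome_mean, 10)
  g3 <- data.frame(contig = "c", start = 1500L, end = 2500L)
  b3 <- gap_bias(g3, d3, flank = 500)
  expect_equal(b3, 0.5, ignore_attr = TRUE)
  expect_equal(attr(b3, "flank_mean"), 30)

  # undefined when both f and g are zero
  expect_error(gap_bias(g1, toy_depth(integer(40000))), "undefined")
})

test_that("gap_bias is bounded, monotone in f, and zero iff f = g", {
  # direct property sweep via constructed flank depths
  set.seed(104)
  for (rep in 1:200) {
    flank_depth <- sample(0:50, 1)
    far_depth <- sample(0:50, 1)
    dep <- integer(600)
    dep[c(81:200, 301:420)] <- flank_depth
    dep[c(1:80, 421:600)] <- far_depth
    d <- toy_depth(dep)
    if (d$genome_mean == 0 && flank_depth == 0) next
    b <- as.numeric(gap_bias(data.frame(contig = "c", start = 200L,
                                        end = 300L), d, flank = 120))
    expect_true(b >= -1 && b <= 1)
    f <- attr(gap_bias(data.frame(contig = "c", start = 200L, end = 300L),
                       d, flank = 120), "flank_mean")
    if (abs(f - d$genome_mean) < 1e-12) expect_equal(b, 0)
    if (f > d$genome_mean) expect_gt(b, 0)
    if (f < d$genome_mean) expect_lt(b, 0)
  }
})

test_that("extract_sequences slices the assembly with exact coordinates", {
  cs <- contig_set(c(c = "AACGTTT"))
  g <- data.frame(contig = "c", start = 2L, end = 5L)
  out <- extract_sequences(g, cs)
  expect_equal(out$sequence, "CGT")
  expect_equal(out$name, "c:2-5")
  # full-contig gap
  full <- extract_sequences(data.frame(contig = "c", start = 0L, end = 7L), cs)
  expect_equal(full$sequence, "AACGTTT")
  # out of bounds
  expect_error(extract_sequences(data.frame(contig = "c", start = 2L,
                                            end = 9L), cs), "out of bounds")
})
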