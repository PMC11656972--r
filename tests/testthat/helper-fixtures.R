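# Shared fixtures: all test data is generated in code.

# small deterministic contig set
toy_contigs <- function() {
  contig_set(c(c1 = "AACGTTTACGGATTACAGGCATG", c2 = "GGGCCCAAATTT"))
}

write_tmp_fasta <- function(records, wrap = 60) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(records, path, wrap = wrap)
  path
}

# write raw SAM lines (header + records) to a temp file
write_tmp_sam <- function(lines) {
  path <- tempfile(fileext = ".sam")
  writeLines(lines, path)
  path
}

# depth track over a single contig from a plain integer vector
toy_depth <- function(d, name = "c") {
  depth_track(setNames(list(as.integer(d)), name))
}

# random DNA string without touching the global seed contract of callers
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# force the first/last 3 insert bases to mismatch the template continuation
# at an insertion point, so local alignments cannot coincidentally extend
# across the junction (the boundary property is only exact on such fixtures)
guard_insert <- function(insert, template, at) {
  nxt <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  v <- strsplit(insert, "")[[1]]
  tpl <- strsplit(template, "")[[1]]
  L <- length(v)
  for (i in 1:3) {
    if (v[i] == tpl[at + i]) v[i] <- nxt(v[i])          # left junction
    if (v[L - i + 1] == tpl[at - i + 1]) v[L - i + 1] <- nxt(v[L - i + 1])
  }
  paste(v, collapse = "")
}

# a minimal RunResult-like list for matching/report tests
fake_result <- function(gaps, cluster_members = list(), non_rep = integer(),
                        consensus = NULL) {
  clusters <- lapply(seq_along(cluster_members), function(i) {
    m <- cluster_members[[i]]
    list(id = i, members = m, copy_number = length(m),
         mean_length = mean(gaps$end[m] - gaps$start[m]),
         median_bias = 0,
         consensus = consensus)
  })
  list(clusters = clusters, non_repetitive = non_rep, gaps = gaps)
}

fake_truth <- function(loci, insert) {
  structure(list(insert = insert, loci = loci, template = NULL),
            class = "TruthSet")
}

# mutate a sequence with substitutions at a given rate (for identity tests)
mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
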