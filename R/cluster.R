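# Single-linkage clustering of gap sequences by pairwise local-alignment
# similarity; groups below the minimum size are routed to the non-repetitive
# output.

#' All-vs-all similarity search over gap sequences
#'
#' For every unordered pair of sequences the best banded local alignment is
#' computed on both strands (seeded by a shared k-mer; pairs sharing no
#' 15-mer are pruned without alignment, which cannot drop a pair that would
#' reach the identity/coverage thresholds). An edge is emitted when percent
#' identity is at least `min_identity` and the aligned span covers at least
#' `min_cov` of the shorter sequence.
#'
#' @param seqs Character vector of gap sequences.
#' @param min_identity Minimum percent identity (default 80).
#' @param min_cov Minimum aligned fraction of the shorter sequence
#'   (default 0.5).
#' @param prefilter_k Shared-k-mer prefilter length (default 15).
#' @return Data frame with columns query, subject (1-based indices,
#'   query < subject), identity, aln_len, coverage, strand -- a tabular-hit
#'   layout mirroring BLAST outfmt 6.
#' @export
pairwise_hits <- function(seqs, min_identity = 80, min_cov = 0.5,
                          prefilter_k = 15) {
  n <- length(seqs)
  stopifnot(n >= 1)
  hits <- list()
  if (n >= 2) {
    share <- cpp_kmer_share(seqs, as.integer(prefilter_k))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (share[i, j] <= 0) {
          # also try the reverse complement before pruning
          rc <- revcomp(seqs[j])
          if (cpp_kmer_share(c(seqs[i], rc), as.integer(prefilter_k))[1, 2] <= 0)
            next
        }
        a <- cpp_local_align(seqs[i], seqs[j], as.integer(prefilter_k),
                             TRUE, 600L)
        if (!a$found) next
        span_short <- if (nchar(seqs[i]) <= nchar(seqs[j]))
          a$a_end - a$a_start else a$b_end - a$b_start
        coverage <- span_short / min(nchar(seqs[i]), nchar(seqs[j]))
        if (a$identity >= min_identity && coverage >= min_cov)
          hits[[length(hits) + 1]] <-
            data.frame(query = i, subject = j, identity = a$identity,
                       aln_len = a$aln_len, coverage = coverage,
                       strand = a$strand)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(query = integer(), subject = integer(),
                      identity = numeric(), aln_len = integer(),
                      coverage = numeric(), strand = integer()))
  do.call(rbind, hits)
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

#' Connected components of the similarity graph
#'
#' Single-linkage clusters are the connected components; isolated vertices
#' are singleton groups. Groups are ordered by their smallest member index.
#'
#' @param edges Edge data frame from [pairwise_hits()] (columns query,
#'   subject).
#' @param n_seqs Total number of sequences.
#' @return List of sorted integer vectors (1-based indices).
#' @export
connected_components <- function(edges, n_seqs) {
  g <- igraph::make_empty_graph(n = n_seqs, directed = FALSE)
  if (nrow(edges) > 0) {
    stopifnot(all(edges$query <= n_seqs), all(edges$subject <= n_seqs))
    g <- igraph::add_edges(g, rbind(edges$query, edges$subject))
  }
  comp <- igraph::components(g)$membership
  groups <- split(seq_len(n_seqs), comp)
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, integer(1)))]
}

#' Partition groups into repetitive clusters and non-repetitive records
#'
#' Groups with at least `min_members` sequences become clusters (the
#' repetitive candidates); all remaining gap sequences are reported as
#' non-repetitive. Cluster bias is the median of the member biases.
#'
#' @param groups List of index groups from [connected_components()].
#' @param gaps Gap data frame with columns sequence and bias (see
#'   [extract_sequences()] and [gap_bias()]).
#' @param min_members Minimum cluster size (default 3).
#' @return List with `clusters` (each a list with members, copy_number,
#'   mean_length, median_bias) and `non_repetitive` (row indices into
#'   `gaps`).
#' @export
partition_repetitive <- function(groups, gaps, min_members = 3) {
  clusters <- list()
  non_rep <- integer()
  for (grp in groups) {
    if (length(grp) >= min_members) {
      lens <- gaps$end[grp] - gaps$start[grp]
      clusters[[length(clusters) + 1]] <- list(
        id = length(clusters) + 1L,
        members = grp,
        copy_number = length(grp),
        mean_length = mean(lens),
        median_bias = stats::median(gaps$bias[grp]))
    } else {
      non_rep <- c(non_rep, grp)
    }
  }
  list(clusters = clusters, non_repetitive = sort(non_rep))
}
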