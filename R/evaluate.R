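# Validation harness: score a pipeline run against the simulated truth,
# reproducing the TP / FP_nr / FP_r / consensus length / similarity metrics.

# total overlap (bp) of interval [s, e) with a set of intervals on the same
# contig, counting each position at most once (intervals are merged first)
union_overlap <- function(s, e, starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts)
  starts <- pmax(starts[o], s)
  ends <- pmin(ends[o], e)
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) return(0L)
  tot <- 0L; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i])
    else { tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i] }
  }
  tot + (ce - cs)
}

#' Match a pipeline run against the simulated truth
#'
#' A truth locus counts as detected (TP) when at least `min_overlap` of its
#' length is covered by reported gaps (cluster members or non-repetitive
#' records). A repetitive cluster is a false positive (FP_r) when none of
#' its member gaps overlaps any truth locus; a non-repetitive record is a
#' false positive (FP_nr) when it overlaps no truth locus.
#'
#' @param result A [run_pipeline()] result.
#' @param truth A `TruthSet` from [insert_copies()].
#' @param min_overlap Minimum covered fraction of a truth locus
#'   (default 0.5).
#' @return List with TP, FP_r, FP_nr.
#' @export
match_truth <- function(result, truth, min_overlap = 0.5) {
  gaps <- result$gaps
  loci <- truth$loci
  # does any of the given gap rows overlap any truth locus by >= 1 bp?
  overlaps_locus <- function(idxs) {
    for (idx in idxs) {
      if (any(gaps$contig[idx] == loci$contig & gaps$start[idx] < loci$end &
                gaps$end[idx] > loci$start))
        return(TRUE)
    }
    FALSE
  }
  tp <- 0L
  for (i in seq_len(nrow(loci))) {
    on_ctg <- gaps$contig == loci$contig[i]
    cov <- union_overlap(loci$start[i], loci$end[i],
                         gaps$start[on_ctg], gaps$end[on_ctg])
    if (cov >= min_overlap * (loci$end[i] - loci$start[i])) tp <- tp + 1L
  }
  fp_r <- sum(vapply(result$clusters, function(cl)
    !overlaps_locus(cl$members), logical(1)))
  fp_nr <- sum(vapply(result$non_repetitive, function(idx)
    !overlaps_locus(idx), logical(1)))
  list(TP = tp, FP_r = as.integer(fp_r), FP_nr = as.integer(fp_nr))
}

#' Percent identity between two sequences
#'
#' Best seeded local alignment identity (matches / alignment columns x 100)
#' over both strands. Pairs sharing no seed k-mer, or whose best alignment
#' spans fewer than 30 columns, have no qualifying alignment and report 0.
#'
#' @param a,b Non-empty nucleotide sequences.
#' @param seed_k Seed length for the local alignment (default 13).
#' @return Percent identity in [0, 100].
#' @export
percent_identity <- function(a, b, seed_k = 13) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  hit <- cpp_local_align(a, b, as.integer(seed_k), TRUE, 600L)
  if (!hit$found || hit$aln_len < 30) return(0)
  hit$identity
}

#' Validation metrics row for a pipeline run
#'
#' Consensus length and similarity are taken from the cluster with the most
#' truth-overlapping members; a run without any truth-matching cluster
#' reports zeros.
#'
#' @inheritParams match_truth
#' @return Data frame with columns TP, FP_nr, FP_r, consensus_length,
#'   similarity_pct.
#' @export
metrics_row <- function(result, truth, min_overlap = 0.5) {
  m <- match_truth(result, truth, min_overlap)
  gaps <- result$gaps
  loci <- truth$loci
  n_matching <- vapply(result$clusters, function(cl) {
    sum(vapply(cl$members, function(idx) {
      any(gaps$contig[idx] == loci$contig & gaps$start[idx] < loci$end &
            gaps$end[idx] > loci$start)
    }, logical(1)))
  }, integer(1))
  if (length(n_matching) > 0 && max(n_matching) > 0) {
    best <- result$clusters[[which.max(n_matching)]]
    cons_len <- nchar(best$consensus)
    sim <- percent_identity(best$consensus, truth$insert)
  } else {
    cons_len <- 0L
    sim <- 0
  }
  data.frame(TP = m$TP, FP_nr = m$FP_nr, FP_r = m$FP_r,
             consensus_length = cons_len, similarity_pct = sim)
}
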