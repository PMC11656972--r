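# Progressive multiple sequence alignment of cluster members and
# majority-rule consensus construction.

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree from pairwise shared-8-mer distances (average-linkage
#' hierarchical clustering) and aligns profiles progressively along it with
#' banded affine-gap dynamic programming (match +1, mismatch -1, gap open -2,
#' gap extend -0.5). Deterministic for fixed input.
#'
#' @param seqs Character vector of sequences (a single sequence is returned
#'   as a one-row alignment).
#' @param guide_k k-mer length for the guide-tree distance (default 8).
#' @return Character vector of equal-length gapped rows over
#'   {A,C,G,T,N,-}, one per input sequence, in input order.
#' @export
progressive_msa <- function(seqs, guide_k = 8) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (n == 0) stop("no sequences to align")
  if (n == 1) return(seqs)
  if (n == 2) {
    merge <- matrix(c(-1L, -2L), nrow = 1)
    return(cpp_progressive_msa(seqs, merge))
  }
  share <- cpp_kmer_share(seqs, as.integer(guide_k))
  hc <- stats::hclust(stats::as.dist(1 - share), method = "average")
  cpp_progressive_msa(seqs, hc$merge)
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column, symbols including '-' are counted; columns where '-' holds a
#' strict majority are omitted. Otherwise the most frequent base is emitted,
#' ties broken in the fixed order A < C < G < T; N never outvotes a base.
#'
#' @param msa Character vector of equal-length gapped rows (from
#'   [progressive_msa()]).
#' @return Consensus sequence (character scalar).
#' @export
majority_consensus <- function(msa) {
  stopifnot(length(msa) >= 1)
  if (length(unique(nchar(msa))) != 1)
    stop("alignment rows must have equal length")
  cpp_majority_consensus(as.character(msa))
}

#' Summary of a gap cluster
#'
#' @param cluster A cluster from [partition_repetitive()] with a `consensus`
#'   element attached.
#' @return Named list: copy_number, mean_length, median_bias,
#'   consensus_length.
#' @export
cluster_summary <- function(cluster) {
  list(copy_number = cluster$copy_number,
       mean_length = cluster$mean_length,
       median_bias = cluster$median_bias,
       consensus_length = if (is.null(cluster$consensus)) 0L
                          else nchar(cluster$consensus))
}

#' Refine a cluster consensus using flanking sequence
#'
#' Re-extracts each member insertion together with `flank` bp of flanking
#' assembly sequence and re-runs the MSA/consensus machinery. Useful when
#' degraded older copies of a repeat attract reads that truncate the primary
#' coverage gaps and hence the initial consensus.
#'
#' @param cluster A cluster from [partition_repetitive()].
#' @param gaps The gap data frame the cluster indexes into.
#' @param contigs The assembly [contig_set()].
#' @param flank Flank size in bp (default 3000).
#' @return The refined consensus sequence (character scalar).
#' @export
refine_consensus <- function(cluster, gaps, contigs, flank = 3000) {
  lens <- contig_lengths(contigs)
  g <- gaps[cluster$members, , drop = FALSE]
  g$start <- pmax(0L, g$start - as.integer(flank))
  g$end <- pmin(unname(lens[g$contig]), g$end + as.integer(flank))
  seqs <- substr(contigs[g$contig], g$start + 1, g$end)
  majority_consensus(progressive_msa(seqs))
}
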