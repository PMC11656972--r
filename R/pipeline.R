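# Orchestration: map -> depth -> detect -> merge -> filter -> bias ->
# extract -> cluster -> MSA -> consensus -> report, with the fixed output
# file contract (GD-candidates.fasta, GD-non-repetitive.fasta, GD.bed,
# GD-summary.tsv) and preserved intermediates.

#' Run the full coverage-gap detection pipeline
#'
#' Aligns the reads of sample A to the assembly of sample P (or takes
#' precomputed alignments/depth), calls zero-coverage gaps, merges and
#' length-filters them, scores each with the flanking-coverage bias,
#' clusters similar gap sequences and writes a majority-rule consensus per
#' cluster. Exactly one of `reads`, `sam`, `depth` must be given.
#'
#' @param assembly The assembly of sample P: a [contig_set()] or FASTA path.
#' @param reads Reads of sample A: named character vector or FASTQ path(s).
#' @param sam Path to a SAM file of externally aligned reads.
#' @param depth Path to a per-base depth table, or a [depth_track()].
#' @param out_dir Output directory (created if missing).
#' @param gap_threshold Depth at or below which a position is uncovered
#'   (default 0).
#' @param merge_distance Maximum distance d between gaps to merge
#'   (default 100), tolerating spurious read placements inside a gap.
#' @param min_length Minimum retained gap size in bp, inclusive
#'   (default 1000).
#' @param flank Bias flank size in bp (default 10000).
#' @param min_cluster Minimum sequences per repetitive cluster (default 3).
#' @param min_identity,min_cov Clustering thresholds (defaults 80, 0.5); see
#'   [pairwise_hits()].
#' @param k Seed length of the built-in mapper (default 17).
#' @param max_edit_frac Mapper edit-distance tolerance (default 0.1).
#' @param seed Optional integer seed (the pipeline itself is deterministic;
#'   the seed is set for reproducibility of any downstream randomness).
#' @param write_sam Also write the internal mapper's placements as
#'   intermediates/mapped.sam (default FALSE; can be large).
#' @param verbose Print per-stage counters (default FALSE).
#' @return A `RunResult`: list with `clusters` (each with members,
#'   copy_number, mean_length, median_bias, consensus), `non_repetitive`
#'   (gap row indices), `gaps` (retained gaps with bias and sequence),
#'   `files`, `counters` and `log`.
#' @export
run_pipeline <- function(assembly, reads = NULL, sam = NULL, depth = NULL,
                         out_dir = tempfile("gapdelta_run_"),
                         gap_threshold = 0, merge_distance = 100,
                         min_length = 1000, flank = 10000, min_cluster = 3,
                         min_identity = 80, min_cov = 0.5, k = 17,
                         max_edit_frac = 0.1, seed = NULL,
                         write_sam = FALSE, verbose = FALSE) {
  n_inputs <- sum(!is.null(reads), !is.null(sam), !is.null(depth))
  if (n_inputs != 1)
    stop("exactly one of 'reads', 'sam' or 'depth' must be provided")
  if (!is.null(seed)) set.seed(seed)
  if (is.character(assembly) && length(assembly) == 1 &&
      file.exists(assembly) && !inherits(assembly, "ContigSet"))
    assembly <- read_fasta(assembly)
  if (!inherits(assembly, "ContigSet")) assembly <- contig_set(assembly)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  int_dir <- file.path(out_dir, "intermediates")
  dir.create(int_dir, showWarnings = FALSE)
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  counters <- list()

  # --- depth ---------------------------------------------------------------
  placements <- NULL
  if (!is.null(reads)) {
    if (is.character(reads) && is.null(names(reads)) &&
        all(file.exists(reads))) {
      reads <- do.call(c, lapply(reads, read_fastq))
    }
    dr <- depth_from_reads(reads, assembly, k = k,
                           max_edit_frac = max_edit_frac)
    dt <- dr$depth
    placements <- dr$placements
    counters$reads <- unname(dr$counters["reads"])
    counters$reads_mapped <- unname(dr$counters["mapped"])
    note("mapped ", counters$reads_mapped, "/", counters$reads, " reads")
    if (write_sam)
      write_sam(placements, reads, assembly,
                file.path(int_dir, "mapped.sam"))
  } else if (!is.null(sam)) {
    dt <- depth_from_sam(sam, assembly)
    note("depth computed from SAM: ", sam)
  } else {
    dt <- if (inherits(depth, "DepthTrack")) depth
          else read_depth_table(depth, assembly)
    note("depth loaded")
  }
  if (dt$genome_mean == 0) stop("no reads aligned: genome mean coverage is 0")
  counters$genome_mean <- dt$genome_mean

  # --- gaps ----------------------------------------------------------------
  raw <- detect_gaps(dt, gap_threshold)
  counters$gaps_raw <- nrow(raw)
  merged <- merge_gaps(raw, merge_distance)
  counters$gaps_merged <- nrow(merged)
  gaps <- filter_by_length(merged, min_length)
  counters$gaps_retained <- nrow(gaps)
  note("gaps: ", nrow(raw), " raw -> ", nrow(merged), " merged -> ",
       nrow(gaps), " retained (>= ", min_length, " bp)")

  files <- list(candidates = file.path(out_dir, "GD-candidates.fasta"),
                non_repetitive = file.path(out_dir, "GD-non-repetitive.fasta"),
                bed = file.path(out_dir, "GD.bed"),
                summary = file.path(out_dir, "GD-summary.tsv"))
  empty_summary <- data.frame(cluster = character(), copy_number = integer(),
                              mean_length = numeric(),
                              consensus_length = integer(),
                              median_bias = numeric())
  if (nrow(gaps) == 0) {
    note("no coverage gaps passed the filters; writing empty outputs")
    write_fasta(character(0), files$candidates)
    write_fasta(character(0), files$non_repetitive)
    write_gap_bed(gaps_bed(gaps), files$bed)
    write_summary_tsv(empty_summary, files$summary)
    return(structure(list(clusters = list(), non_repetitive = integer(),
                          gaps = gaps, files = files, counters = counters,
                          log = log), class = "RunResult"))
  }

  bias <- gap_bias(gaps, dt, flank)
  gaps$bias <- as.numeric(bias)
  gaps$flank_mean <- attr(bias, "flank_mean")
  gaps <- extract_sequences(gaps, assembly)
  write_fasta(setNames(gaps$sequence, gaps$name),
              file.path(int_dir, "gaps.fasta"))

  # --- clustering ----------------------------------------------------------
  hits <- pairwise_hits(gaps$sequence, min_identity, min_cov)
  write.table(hits, file.path(int_dir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  groups <- connected_components(hits, nrow(gaps))
  part <- partition_repetitive(groups, gaps, min_cluster)
  counters$clusters <- length(part$clusters)
  counters$non_repetitive <- length(part$non_repetitive)
  note(length(part$clusters), " repetitive cluster(s), ",
       length(part$non_repetitive), " non-repetitive record(s)")

  # --- consensus -----------------------------------------------------------
  for (ci in seq_along(part$clusters)) {
    cl <- part$clusters[[ci]]
    msa <- progressive_msa(gaps$sequence[cl$members])
    write_fasta(setNames(msa, gaps$name[cl$members]),
                file.path(int_dir, sprintf("cluster_%d.msa.fasta", ci)))
    part$clusters[[ci]]$consensus <- majority_consensus(msa)
  }

  # --- outputs -------------------------------------------------------------
  cons <- vapply(part$clusters, `[[`, character(1), "consensus")
  names(cons) <- sprintf("GD_cluster_%d", seq_along(cons))
  write_fasta(cons, files$candidates)
  nr <- part$non_repetitive
  write_fasta(setNames(gaps$sequence[nr], gaps$name[nr]),
              files$non_repetitive)
  write_gap_bed(gaps_bed(gaps), files$bed)
  summary_df <- run_summary_df(part$clusters)
  write_summary_tsv(summary_df, files$summary)
  structure(list(clusters = part$clusters, non_repetitive = nr, gaps = gaps,
                 files = files, counters = counters, log = log),
            class = "RunResult")
}

gaps_bed <- function(gaps) {
  if (nrow(gaps) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(), bias = numeric()))
  data.frame(contig = gaps$contig, start = gaps$start, end = gaps$end,
             name = sprintf("%s:%d-%d", gaps$contig, gaps$start, gaps$end),
             bias = gaps$bias, stringsAsFactors = FALSE)
}

run_summary_df <- function(clusters) {
  rows <- lapply(seq_along(clusters), function(i) {
    s <- cluster_summary(clusters[[i]])
    data.frame(cluster = sprintf("GD_cluster_%d", i),
               copy_number = s$copy_number, mean_length = s$mean_length,
               consensus_length = s$consensus_length,
               median_bias = s$median_bias, stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0) do.call(rbind, rows)
        else data.frame(cluster = character(), copy_number = integer(),
                        mean_length = numeric(), consensus_length = integer(),
                        median_bias = numeric())
  df[order(-df$copy_number, df$cluster), , drop = FALSE]
}

write_summary_tsv <- function(df, path) {
  df$mean_length <- sprintf("%.1f", df$mean_length)
  df$median_bias <- sprintf("%.4f", df$median_bias)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.RunResult <- function(x, ...) {
  cat("RunResult:", length(x$clusters), "repetitive cluster(s),",
      length(x$non_repetitive), "non-repetitive record(s),",
      nrow(x$gaps), "retained gap(s)\n")
  invisible(x)
}

#' Summary table (and optional plot) of a pipeline run
#'
#' One row per repetitive cluster, sorted by copy number descending. When
#' `plot_file` is given and ggplot2 is installed, a scatter of mean member
#' length (x) vs copy number (y) coloured by median bias is written; the
#' table is identical whether or not the plot is rendered.
#'
#' @param result A [run_pipeline()] result.
#' @param plot_file Optional path for a PNG/PDF summary plot.
#' @return Data frame with columns cluster, copy_number, mean_length,
#'   consensus_length, median_bias.
#' @export
summary_report <- function(result, plot_file = NULL) {
  df <- run_summary_df(result$clusters)
  rownames(df) <- NULL
  if (!is.null(plot_file) && nrow(df) > 0 &&
      requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_length,
                                          y = .data$copy_number,
                                          colour = .data$median_bias)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::scale_colour_gradient2(low = "red", mid = "blue",
                                      high = "red", limits = c(-1, 1)) +
      ggplot2::labs(x = "mean sequence length (bp)", y = "copy number",
                    colour = "coverage bias") +
      ggplot2::theme_bw()
    ggplot2::ggsave(plot_file, p, width = 6, height = 4)
  }
  df
}
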