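# Built-in local read mapper: exact k-mer seeding plus banded local extension
# with soft-clipping, so that read ends extending into sequence absent from
# the reference are clipped and depth stops exactly at insertion junctions.
# External aligner output (SAM) bypasses this module via depth_from_sam().

#' Build a k-mer seed index over an assembly
#'
#' Every exact k-mer occurrence of every contig is indexed; k-mers containing
#' N are skipped.
#'
#' @param contigs A [contig_set()].
#' @param k Seed length (default 17; minimum 11).
#' @return A `SeedIndex` object.
#' @export
build_index <- function(contigs, k = 17) {
  if (k < 11) stop("seed length k must be >= 11")
  ptr <- cpp_build_index(unname(as.character(contigs)), names(contigs),
                         as.integer(k))
  structure(list(ptr = ptr, k = k, contig_names = names(contigs)),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  st <- cpp_index_stats(x$ptr)
  cat("SeedIndex: k =", st$k, "|", st$n_positions, "indexed positions |",
      st$n_distinct, "distinct k-mers\n")
  invisible(x)
}

#' Summary statistics of a seed index
#' @param index A [build_index()] result.
#' @return List with k, number of indexed positions, distinct k-mers and
#'   skipped (N-containing) k-mers.
#' @export
index_stats <- function(index) cpp_index_stats(index$ptr)

# positions of one exact k-mer (1-based contig index, 0-based offset)
index_lookup <- function(index, kmer) cpp_index_lookup(index$ptr, kmer)

#' Map reads against an indexed assembly
#'
#' Seeds each read with its exact k-mer hits, extends every candidate locus
#' by banded local alignment (substitutions and gaps allowed) and reports the
#' best-scoring placement whose aligned read fraction is at least
#' `min_aligned_frac` and whose edit distance is at most
#' `max_edit_frac` times the aligned length. Ties between equally good loci
#' (e.g. reads from identical repeat copies) are broken by a deterministic
#' hash of the read id, so multi-mapping reads spread over the tied loci in a
#' reproducible, input-order-independent way.
#'
#' @param reads Named character vector of read sequences.
#' @param index A [build_index()] result.
#' @param max_edit_frac Maximum edit distance as a fraction of the aligned
#'   length (default 0.1).
#' @param min_aligned_frac Minimum aligned fraction of the read (default 0.5).
#' @param rescue_clips Re-map soft-clipped read remainders of at least 20 bp
#'   as supplementary placements (default TRUE). A read spanning an
#'   insertion junction aligns one side locally and soft-clips the other;
#'   the clipped side belongs elsewhere on the reference and is rescued so
#'   that coverage stops exactly at the junction on both sides.
#' @return Data frame with one row per read (plus one per supplementary
#'   placement): read_id, mapped, supplementary, contig, ref_start/ref_end
#'   and query_start/query_end (0-based half-open, aligned portion only),
#'   edits, cigar (soft-clipped), n_ties.
#' @export
map_reads <- function(reads, index, max_edit_frac = 0.1,
                      min_aligned_frac = 0.5, rescue_clips = TRUE) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  reads <- as.character(reads)
  res <- cpp_map_reads(index$ptr, reads, ids,
                       max_edit_frac, min_aligned_frac,
                       100L, 64L)
  pl <- data.frame(read_id = ids, mapped = res$mapped,
                   supplementary = FALSE,
                   contig = ifelse(is.na(res$contig), NA_character_,
                                   index$contig_names[res$contig]),
                   ref_start = res$ref_start, ref_end = res$ref_end,
                   query_start = res$query_start, query_end = res$query_end,
                   edits = res$edits, cigar = as.character(res$cigar),
                   n_ties = res$n_ties, stringsAsFactors = FALSE)
  if (!rescue_clips) return(pl)
  min_clip <- max(index$k + 3L, 20L)
  rlen <- nchar(reads)
  sup <- list()
  for (side in c("prefix", "suffix")) {
    if (side == "prefix") {
      sel <- which(pl$mapped & pl$query_start >= min_clip)
      off <- rep(0L, length(sel))
      frag <- substr(reads[sel], 1L, pl$query_start[sel])
    } else {
      sel <- which(pl$mapped & rlen - pl$query_end >= min_clip)
      off <- pl$query_end[sel]
      frag <- substr(reads[sel], pl$query_end[sel] + 1L, rlen[sel])
    }
    if (length(sel) == 0) next
    fres <- cpp_map_reads(index$ptr, frag,
                          paste0(ids[sel], "/", side),
                          max_edit_frac, 0.8, 100L, 64L)
    ok <- which(fres$mapped)
    if (length(ok) == 0) next
    qs <- off[ok] + fres$query_start[ok]
    qe <- off[ok] + fres$query_end[ok]
    core <- strip_clips(as.character(fres$cigar[ok]))
    cig <- paste0(ifelse(qs > 0, paste0(qs, "S"), ""), core,
                  ifelse(rlen[sel][ok] - qe > 0,
                         paste0(rlen[sel][ok] - qe, "S"), ""))
    sup[[side]] <- data.frame(read_id = ids[sel][ok], mapped = TRUE,
                              supplementary = TRUE,
                              contig = index$contig_names[fres$contig[ok]],
                              ref_start = fres$ref_start[ok],
                              ref_end = fres$ref_end[ok],
                              query_start = qs, query_end = qe,
                              edits = fres$edits[ok], cigar = cig,
                              n_ties = fres$n_ties[ok],
                              stringsAsFactors = FALSE)
  }
  out <- rbind(pl, do.call(rbind, sup))
  rownames(out) <- NULL
  out
}

# remove leading/trailing soft-clip operations from CIGAR strings
strip_clips <- function(cigar) {
  cigar <- sub("^[0-9]+S", "", cigar)
  sub("[0-9]+S$", "", cigar)
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read A single read sequence (optionally named).
#' @return A one-row placement data frame (see [map_reads()]); `mapped` is
#'   FALSE when no placement satisfies the criteria.
#' @export
map_read <- function(read, index, max_edit_frac = 0.1,
                     min_aligned_frac = 0.5) {
  if (is.null(names(read))) names(read) <- "read_1"
  map_reads(read, index, max_edit_frac, min_aligned_frac,
            rescue_clips = FALSE)
}

#' Compute per-base depth by mapping reads with the built-in mapper
#'
#' @inheritParams map_reads
#' @param contigs The [contig_set()] to map against.
#' @param k Seed length passed to [build_index()].
#' @param index Optional prebuilt [build_index()] result for `contigs`.
#' @return List with elements `depth` (a [depth_track()]), `placements`
#'   (the [map_reads()] data frame) and `counters` (reads total / mapped /
#'   too-short).
#' @export
depth_from_reads <- function(reads, contigs, k = 17, max_edit_frac = 0.1,
                             min_aligned_frac = 0.5, index = NULL) {
  if (is.null(index)) index <- build_index(contigs, k)
  pl <- map_reads(reads, index, max_edit_frac, min_aligned_frac)
  lens <- unname(contig_lengths(contigs))
  ci <- match(pl$contig, names(contigs))
  d <- cpp_depth_from_cigar(ci, pl$ref_start, pl$cigar, pl$read_id,
                            as.integer(lens))
  names(d) <- names(contigs)
  counters <- c(reads = length(reads),
                mapped = sum(pl$mapped & !pl$supplementary),
                supplementary = sum(pl$supplementary),
                too_short = sum(nchar(reads) < index$k))
  list(depth = depth_track(d), placements = pl, counters = counters)
}
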