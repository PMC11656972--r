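# Coverage-gap calling: maximal low-depth runs, distance-based merging,
# length filtering, the flanking-coverage bias score and sequence extraction.

#' Detect coverage gaps in a depth track
#'
#' Returns the maximal runs of consecutive positions with depth at or below
#' the threshold (default 0, i.e. zero coverage), per contig, sorted by
#' (contig, start).
#'
#' @param depth A [depth_track()].
#' @param threshold Maximum depth for a position to count as uncovered
#'   (default 0).
#' @return Data frame with columns contig, start, end (0-based half-open).
#' @export
detect_gaps <- function(depth, threshold = 0) {
  out <- lapply(names(depth$depth), function(nm) {
    d <- depth$depth[[nm]]
    r <- rle(d <= threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(contig = nm, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby coverage gaps
#'
#' Two consecutive same-contig gaps separated by at most `d` positions are
#' merged into one interval spanning both; with `d = 0` only touching
#' intervals merge. Merging is idempotent.
#'
#' @param gaps Sorted, non-overlapping gap data frame (see [detect_gaps()]).
#' @param d Maximum separation to merge across (default 100).
#' @return Merged gap data frame.
#' @export
merge_gaps <- function(gaps, d = 100) {
  if (nrow(gaps) == 0) return(gaps)
  pieces <- lapply(split(gaps, gaps$contig), function(g) {
    if (is.unsorted(g$start) || any(g$start[-1] < g$end[-nrow(g)]))
      stop("merge_gaps requires sorted, non-overlapping intervals")
    grp <- cumsum(c(0L, as.integer(g$start[-1] - g$end[-nrow(g)] > d)))
    data.frame(contig = g$contig[1],
               start = as.integer(tapply(g$start, grp, min)),
               end = as.integer(tapply(g$end, grp, max)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter gaps by minimum length
#'
#' @param gaps Gap data frame.
#' @param min_length Minimum gap size in bp, inclusive (default 1000).
#' @return Gap data frame restricted to intervals with end - start >=
#'   `min_length`.
#' @export
filter_by_length <- function(gaps, min_length = 1000) {
  out <- gaps[gaps$end - gaps$start >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage-bias score of a gap
#'
#' bias = 2 f / (g + f) - 1, where f is the mean depth over up to `flank`
#' positions on each side of the gap (truncated at contig boundaries) and g
#' is the genome-wide average coverage. 0 indicates flanking coverage equal
#' to the genomic average; -1 and 1 indicate strongly decreased or increased
#' flanking coverage.
#'
#' @param gaps Gap data frame (one or more rows).
#' @param depth A [depth_track()].
#' @param flank Flank size in bp on each side (default 10000).
#' @return Numeric vector of bias values in [-1, 1], one per gap. A
#'   `flank_mean` attribute carries f for each gap.
#' @export
gap_bias <- function(gaps, depth, flank = 10000) {
  g <- depth$genome_mean
  f <- vapply(seq_len(nrow(gaps)), function(i) {
    d <- depth$depth[[gaps$contig[i]]]
    if (is.null(d)) stop("gap on unknown contig '", gaps$contig[i], "'")
    ls <- max(0L, gaps$start[i] - flank)
    le <- gaps$start[i]
    rs <- gaps$end[i]
    re <- min(length(d), gaps$end[i] + flank)
    vals <- c(if (le > ls) d[(ls + 1):le] else integer(0),
              if (re > rs) d[(rs + 1):re] else integer(0))
    if (length(vals) == 0) 0 else mean(vals)
  }, numeric(1))
  if (g == 0 && any(f == 0))
    stop("coverage-bias score undefined: genome mean and flank coverage both zero")
  bias <- 2 * f / (g + f) - 1
  attr(bias, "flank_mean") <- f
  bias
}

#' Extract gap sequences from the assembly
#'
#' @param gaps Gap data frame.
#' @param contigs The [contig_set()] (assembly P).
#' @return The gap data frame with added columns `name`
#'   ("contig:start-end", same coordinates as the BED output) and `sequence`.
#' @export
extract_sequences <- function(gaps, contigs) {
  lens <- contig_lengths(contigs)
  bad <- is.na(match(gaps$contig, names(contigs))) |
    gaps$start < 0 | gaps$end > lens[gaps$contig]
  if (any(bad))
    stop("gap interval out of bounds: ", gaps$contig[bad][1], ":",
         gaps$start[bad][1], "-", gaps$end[bad][1])
  gaps$name <- sprintf("%s:%d-%d", gaps$contig, gaps$start, gaps$end)
  gaps$sequence <- substr(contigs[gaps$contig], gaps$start + 1, gaps$end)
  gaps
}
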