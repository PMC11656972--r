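# FASTA/FASTQ/SAM/BED/depth-table readers and writers. All interval
# arithmetic in the package is 0-based half-open; SAM's 1-based POS is
# converted here and nowhere else.

#' Construct a contig set
#'
#' A contig set is a named character vector of uppercase nucleotide sequences
#' over the alphabet A/C/G/T/N. Sequences are normalized on construction:
#' lowercase is uppercased, U becomes T and any other symbol becomes N.
#'
#' @param x Named character vector of nucleotide sequences.
#' @return A `ContigSet` (named character vector).
#' @export
contig_set <- function(x) {
  if (length(x) == 0) stop("contig set must contain at least one sequence")
  nm <- names(x)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm)))
    stop("all contigs must have non-empty names")
  if (anyDuplicated(nm))
    stop("duplicate contig name: ", nm[duplicated(nm)][1])
  x <- normalize_seq(as.character(x))
  if (any(!nzchar(x))) {
    bad <- nm[!nzchar(x)][1]
    stop("contig '", bad, "' has an empty sequence")
  }
  names(x) <- nm
  class(x) <- "ContigSet"
  x
}

normalize_seq <- function(s) {
  s <- chartr("U", "T", toupper(s))
  gsub("[^ACGTN]", "N", s)
}

#' @export
print.ContigSet <- function(x, ...) {
  cat("ContigSet with", length(x), "contig(s), total",
      sum(nchar(x)), "bp\n")
  for (i in seq_len(min(6, length(x))))
    cat("  ", names(x)[i], ": ", nchar(x[[i]]), " bp\n", sep = "")
  if (length(x) > 6) cat("  ...\n")
  invisible(x)
}

contig_lengths <- function(contigs) setNames(nchar(contigs), names(contigs))

#' Read a FASTA file into a contig set
#'
#' @param path Path to a FASTA file.
#' @return A [contig_set()] with one entry per record. Headers are truncated
#'   at the first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file is empty: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) stop("FASTA record with empty sequence: ", nm[empty][1])
  contig_set(setNames(seqs, nm))
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of sequences (may be empty).
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @export
write_fasta <- function(records, path, wrap = 60) {
  if (length(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (anyDuplicated(names(records)))
    stop("duplicate record names in FASTA output")
  set <- Biostrings::BStringSet(as.character(records))
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, filepath = path, width = wrap)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file (Phred+33).
#' @return Named character vector of read sequences with a `"qualities"`
#'   attribute holding the quality strings.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  reads <- as.character(set)
  names(reads) <- sub("\\s.*$", "", names(set))
  q <- as.character(S4Vectors::mcols(set)$qualities)
  reads <- normalize_seq(reads)
  attr(reads, "qualities") <- q
  reads
}

#' Write reads to a FASTQ file
#'
#' @param reads Named character vector; optional `"qualities"` attribute.
#'   Missing qualities are written as constant 'I' (Q40).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  q <- attr(reads, "qualities")
  if (is.null(q)) q <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads) > 0) {
    lines <- as.vector(rbind(paste0("@", names(reads)), as.character(reads),
                             "+", q))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Construct a depth track
#'
#' @param depth Named list of non-negative integer vectors, one per contig,
#'   one value per reference position.
#' @return A `DepthTrack`: list with elements `depth` and `genome_mean` (the
#'   genome-wide average coverage g, zeros included).
#' @export
depth_track <- function(depth) {
  stopifnot(is.list(depth), !is.null(names(depth)))
  total <- sum(vapply(depth, function(d) sum(as.numeric(d)), numeric(1)))
  npos <- sum(vapply(depth, length, integer(1)))
  structure(list(depth = depth,
                 genome_mean = if (npos > 0) total / npos else 0),
            class = "DepthTrack")
}

#' @export
print.DepthTrack <- function(x, ...) {
  cat("DepthTrack over", length(x$depth), "contig(s);",
      "genome mean coverage", format(x$genome_mean, digits = 4), "\n")
  invisible(x)
}

# minimal SAM field extraction: QNAME, FLAG, RNAME, POS, CIGAR
parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(qname = vapply(f, `[[`, character(1), 1),
             flag = as.integer(vapply(f, `[[`, character(1), 2)),
             rname = vapply(f, `[[`, character(1), 3),
             pos = as.integer(vapply(f, `[[`, character(1), 4)),
             cigar = vapply(f, `[[`, character(1), 6),
             stringsAsFactors = FALSE)
}

#' Compute per-base depth from a SAM file
#'
#' Each reference position consumed by a CIGAR M/=/X operation of a mapped
#' record increments depth by one; soft/hard clips and insertions contribute
#' nothing and deletions/skips (D/N) consume reference without incrementing.
#'
#' @param path Path to a SAM file (header optional).
#' @param contigs [contig_set()] the records were aligned to.
#' @return A [depth_track()].
#' @export
depth_from_sam <- function(path, contigs) {
  rec <- parse_sam(path)
  keep <- rec$rname != "*" & rec$cigar != "*" &
    bitwAnd(rec$flag, 4L) == 0L
  rec <- rec[keep, , drop = FALSE]
  ci <- match(rec$rname, names(contigs))
  if (anyNA(ci)) {
    bad <- rec$qname[is.na(ci)][1]
    stop("record '", bad, "' references a contig absent from the assembly")
  }
  lens <- unname(contig_lengths(contigs))
  d <- cpp_depth_from_cigar(ci, rec$pos - 1L, rec$cigar, rec$qname,
                            as.integer(lens))
  names(d) <- names(contigs)
  depth_track(d)
}

#' Read a per-base depth table
#'
#' Tab-separated columns contig / position (0-based) / depth; positions not
#' listed are taken as depth 0.
#'
#' @param path Path to the table.
#' @param contigs [contig_set()] defining contig names and lengths.
#' @return A [depth_track()].
#' @export
read_depth_table <- function(path, contigs) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("contig", "pos", "depth"),
                    colClasses = c("character", "integer", "integer"))
  lens <- contig_lengths(contigs)
  d <- lapply(names(contigs), function(nm) {
    v <- integer(lens[[nm]])
    rows <- tab$contig == nm
    if (any(rows)) {
      p <- tab$pos[rows]
      if (any(p < 0 | p >= lens[[nm]]))
        stop("depth table position out of range for contig '", nm, "'")
      v[p + 1L] <- tab$depth[rows]
    }
    v
  })
  names(d) <- names(contigs)
  depth_track(d)
}

#' Write coverage gaps to a BED5 file
#'
#' Lines are `contig<TAB>start<TAB>end<TAB>name<TAB>bias` with 0-based
#' half-open coordinates, bias printed with 4 decimals, sorted by
#' (contig, start).
#'
#' @param gaps Data frame with columns contig, start, end, name, bias.
#' @param path Output path.
#' @export
write_gap_bed <- function(gaps, path) {
  if (nrow(gaps) == 0) {
    file.create(path)
    return(invisible(path))
  }
  o <- order(gaps$contig, gaps$start)
  g <- gaps[o, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.4f", g$contig, g$start, g$end,
                     g$name, g$bias), path)
  invisible(path)
}

#' Write mapper placements as SAM
#'
#' @param placements Placement data frame from [map_reads()].
#' @param reads The named character vector of reads that was mapped.
#' @param contigs The [contig_set()] used as reference.
#' @param path Output path.
#' @export
write_sam <- function(placements, reads, contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                       unname(contig_lengths(contigs)))), con)
  p <- placements
  flag <- ifelse(!p$mapped, 4L, ifelse(p$supplementary, 2048L, 0L))
  rname <- ifelse(p$mapped, p$contig, "*")
  pos <- ifelse(p$mapped, p$ref_start + 1L, 0L)
  mapq <- ifelse(p$mapped, 60L, 0L)
  cig <- ifelse(p$mapped, p$cigar, "*")
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     p$read_id, flag, rname, pos, mapq, cig,
                     as.character(reads[p$read_id])), con)
  invisible(path)
}
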