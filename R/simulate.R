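# Synthetic-data generator: template genomes with multi-copy insertions of a
# novel sequence, and uniform / random / ancient-DNA-style read sets
# simulated from the template (sample A) for analysis against the modified
# genome (sample P).

#' Random nucleotide sequence
#'
#' @param length Sequence length (>= 1).
#' @param seed Optional integer seed; when given the result is a pure
#'   function of (length, seed).
#' @return Character scalar of i.i.d. uniform A/C/G/T.
#' @export
random_sequence <- function(length, seed = NULL) {
  if (length < 1) stop("sequence length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, length, replace = TRUE)])
}

#' Insert identical copies of a sequence into a template genome
#'
#' Draws `n` insertion points on the template's largest contig, pairwise at
#' least `min_spacing` apart and at least `end_margin` from the contig ends
#' (so that bias flanks of neighbouring insertions never overlap), and
#' splices the insert in at each point. Removing the truth loci from the
#' modified genome reproduces the template exactly.
#'
#' @param template A [contig_set()] (sample A source).
#' @param insert Insert sequence (character scalar).
#' @param n Number of copies (>= 1).
#' @param seed Optional integer seed.
#' @param min_spacing Minimum distance between insertion points
#'   (default 25000).
#' @param end_margin Minimum distance from contig ends (default 10000).
#' @return List with `modified` (the [contig_set()] P) and `truth` (a
#'   `TruthSet`: insert sequence, loci in modified-genome coordinates, and
#'   the template).
#' @export
insert_copies <- function(template, insert, n, seed = NULL,
                          min_spacing = 25000, end_margin = 10000) {
  stopifnot(n >= 1, nchar(insert) >= 1)
  if (!is.null(seed)) set.seed(seed)
  lens <- contig_lengths(template)
  tgt <- names(template)[which.max(lens)]
  L <- lens[[tgt]]
  span <- (L - 2 * end_margin) - (n - 1) * min_spacing
  if (span < 0)
    stop("template too short for ", n, " insertion points ", min_spacing,
         " bp apart with ", end_margin, " bp end margins")
  pts <- sort(end_margin + floor(sort(runif(n, 0, span + 1))) +
                (seq_len(n) - 1) * min_spacing)
  K <- nchar(insert)
  seq0 <- template[[tgt]]
  bounds <- c(0, pts, L)
  pieces <- substring(seq0, head(bounds, -1) + 1, bounds[-1])
  modified_seq <- paste0(paste0(pieces[seq_len(n)], insert, collapse = ""),
                         pieces[n + 1])
  modified <- template
  modified[[tgt]] <- modified_seq
  modified <- contig_set(unclass(modified))
  loci <- data.frame(contig = tgt,
                     start = as.integer(pts + (seq_len(n) - 1) * K),
                     end = as.integer(pts + seq_len(n) * K),
                     stringsAsFactors = FALSE)
  truth <- structure(list(insert = insert, loci = loci, template = template),
                     class = "TruthSet")
  list(modified = modified, truth = truth)
}

#' @export
print.TruthSet <- function(x, ...) {
  cat("TruthSet:", nrow(x$loci), "insertion loci of", nchar(x$insert),
      "bp on", x$loci$contig[1], "\n")
  invisible(x)
}

apply_errors <- function(reads, error_rate) {
  if (error_rate > 0) {
    nm <- names(reads)
    reads <- cpp_substitute(reads, error_rate)
    names(reads) <- nm
  }
  reads
}

#' Uniformly tiling reads
#'
#' Reads tile each contig with a fixed stride of `read_length / coverage`
#' (rounded), so every interior position is covered by floor or ceiling of
#' the target coverage; substitution errors are i.i.d. at `error_rate`.
#'
#' @param genome A [contig_set()].
#' @param coverage Target coverage (> 0).
#' @param read_length Read length in bp (default 100).
#' @param error_rate Per-base substitution probability (default 0).
#' @return Named character vector of reads.
#' @export
reads_uniform <- function(genome, coverage, read_length = 100,
                          error_rate = 0) {
  stopifnot(coverage > 0)
  stride <- max(1L, as.integer(round(read_length / coverage)))
  out <- lapply(names(genome), function(nm) {
    L <- nchar(genome[[nm]])
    if (L < read_length) return(character(0))
    starts <- seq.int(0L, L - read_length, by = stride)
    r <- substring(genome[[nm]], starts + 1, starts + read_length)
    names(r) <- sprintf("u_%s_%d", nm, starts)
    r
  })
  apply_errors(do.call(c, out), error_rate)
}

#' Randomly placed reads (heterogeneous coverage)
#'
#' N = round(coverage x contig_length / read_length) reads per contig with
#' uniformly random start positions.
#'
#' @inheritParams reads_uniform
#' @param seed Optional integer seed.
#' @return Named character vector of reads.
#' @export
reads_random <- function(genome, coverage, read_length = 100,
                         error_rate = 0, seed = NULL) {
  stopifnot(coverage > 0)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(genome), function(nm) {
    L <- nchar(genome[[nm]])
    if (L < read_length) return(character(0))
    n <- as.integer(round(coverage * L / read_length))
    if (n == 0) return(character(0))
    starts <- as.integer(floor(runif(n, 0, L - read_length + 1)))
    r <- substring(genome[[nm]], starts + 1, starts + read_length)
    names(r) <- sprintf("r_%s_%d", nm, seq_len(n))
    r
  })
  apply_errors(do.call(c, out), error_rate)
}

#' Default ancient-DNA simulation parameters
#'
#' Fragment lengths are lognormal with the given mean and sd, truncated to
#' [fragment_min, fragment_max]; terminal cytosine deamination converts
#' C to T at 5' offsets and G to A at 3' offsets with probability
#' p0 * decay^offset; a bacterial fraction is drawn from an independent
#' random contaminant sequence and a modern-contamination fraction from the
#' insertion-carrying genome.
#'
#' @param fragment_mean,fragment_sd,fragment_min,fragment_max Fragment-length
#'   distribution in bp (defaults 50 / 15 / 25 / 150).
#' @param deamination_p0,deamination_decay Terminal damage model
#'   (defaults 0.3 / 0.5).
#' @param frac_bacterial,frac_modern Contamination fractions
#'   (defaults 0.10 / 0.08; the remaining 0.82 is endogenous).
#' @param bacterial_bp Length of the generated contaminant sequence
#'   (default 100000).
#' @return Parameter list for [reads_ancient()].
#' @export
ancient_params <- function(fragment_mean = 50, fragment_sd = 15,
                           fragment_min = 25, fragment_max = 150,
                           deamination_p0 = 0.3, deamination_decay = 0.5,
                           frac_bacterial = 0.10, frac_modern = 0.08,
                           bacterial_bp = 100000) {
  p <- list(fragment_mean = fragment_mean, fragment_sd = fragment_sd,
            fragment_min = fragment_min, fragment_max = fragment_max,
            deamination_p0 = deamination_p0,
            deamination_decay = deamination_decay,
            frac_bacterial = frac_bacterial, frac_modern = frac_modern,
            bacterial_bp = bacterial_bp)
  if (p$frac_bacterial + p$frac_modern > 1)
    stop("contamination fractions must sum to at most 1")
  p
}

rlnorm_trunc <- function(n, mean, sd, lo, hi) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(max(n, 100), meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(round(out[seq_len(n)]))
}

draw_fragments <- function(genome, n, flens, prefix) {
  if (n == 0) return(character(0))
  lens <- contig_lengths(genome)
  ci <- sample.int(length(genome), n, replace = TRUE, prob = lens)
  L <- unname(lens[ci])
  flens <- pmin(flens, L)
  starts <- as.integer(floor(runif(n, 0, L - flens + 1)))
  r <- substring(genome[ci], starts + 1, starts + flens)
  names(r) <- sprintf("%s_%d", prefix, seq_len(n))
  r
}

#' Ancient-DNA-style reads
#'
#' Emulates degraded sequencing libraries: short lognormal fragments,
#' terminal cytosine deamination on the endogenous fraction, reads from an
#' independent bacterial contaminant, and modern contamination drawn from
#' the insertion-carrying genome (those reads can cover the insertions).
#'
#' @param genome Template [contig_set()] the endogenous fraction is drawn
#'   from (sample A).
#' @param coverage Target total coverage (all fractions combined).
#' @param params Parameter list from [ancient_params()].
#' @param seed Optional integer seed.
#' @param modern_genome Optional [contig_set()] the modern-contamination
#'   fraction is drawn from (typically the modified genome P); defaults to
#'   `genome`.
#' @return Named character vector of reads (names encode the source class).
#' @export
reads_ancient <- function(genome, coverage, params = ancient_params(),
                          seed = NULL, modern_genome = NULL) {
  stopifnot(coverage > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(modern_genome)) modern_genome <- genome
  total <- sum(nchar(genome))
  n <- as.integer(round(coverage * total / params$fragment_mean))
  frac_endo <- 1 - params$frac_bacterial - params$frac_modern
  cls <- sample.int(3L, n, replace = TRUE,
                    prob = c(frac_endo, params$frac_bacterial,
                             params$frac_modern))
  flens <- rlnorm_trunc(n, params$fragment_mean, params$fragment_sd,
                        params$fragment_min, params$fragment_max)
  bact <- contig_set(c(contaminant = random_sequence(params$bacterial_bp)))
  endo <- draw_fragments(genome, sum(cls == 1L), flens[cls == 1L], "anc_endo")
  if (length(endo) > 0) {
    nm <- names(endo)
    endo <- cpp_deaminate(endo, params$deamination_p0,
                          params$deamination_decay)
    names(endo) <- nm
  }
  bac <- draw_fragments(bact, sum(cls == 2L), flens[cls == 2L], "anc_bact")
  mod <- draw_fragments(modern_genome, sum(cls == 3L), flens[cls == 3L],
                        "anc_mod")
  c(endo, bac, mod)
}

#' Bundle a full validation scenario from one seed
#'
#' Generates a seeded random template, inserts `n_copies` identical copies
#' of a random insert, and simulates reads from the template in the chosen
#' mode. The result feeds directly into [run_pipeline()] (assembly = the
#' modified genome, reads = the simulated read set) and [metrics_row()].
#'
#' @param mode One of "uniform", "random", "ancient".
#' @param coverage Target read coverage.
#' @param seed Integer seed; the scenario is a pure function of its
#'   arguments.
#' @param template_bp Template length in bp (default 2e6).
#' @param n_copies Number of insert copies (default 25).
#' @param insert_bp Insert length in bp (default 5000).
#' @param read_length Read length for uniform/random modes (default 100).
#' @param error_rate Substitution error rate for uniform/random modes
#'   (default 0).
#' @param ancient Parameter list from [ancient_params()].
#' @return List with template, assembly (modified genome), insert, truth,
#'   reads, mode and coverage.
#' @details In the ancient mode all contamination is drawn from
#'   insert-free sources: the validation insert is an artificial sequence a
#'   contemporary contaminant genome would not contain, so modern
#'   contamination is simulated from the template. When modelling a real
#'   invasion, point [reads_ancient()]'s `modern_genome` at the
#'   insertion-carrying assembly instead.
#' @export
simulate_scenario <- function(mode = c("uniform", "random", "ancient"),
                              coverage, seed, template_bp = 2e6,
                              n_copies = 25, insert_bp = 5000,
                              read_length = 100, error_rate = 0,
                              ancient = ancient_params()) {
  mode <- match.arg(mode)
  set.seed(seed)
  template <- contig_set(c(tpl = random_sequence(template_bp)))
  insert <- random_sequence(insert_bp)
  ins <- insert_copies(template, insert, n_copies)
  reads <- switch(mode,
    uniform = reads_uniform(template, coverage, read_length, error_rate),
    random = reads_random(template, coverage, read_length, error_rate),
    ancient = reads_ancient(template, coverage, ancient,
                            modern_genome = template))
  list(template = template, assembly = ins$modified, insert = insert,
       truth = ins$truth, reads = reads, mode = mode, coverage = coverage)
}
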