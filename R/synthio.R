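# Synthetic-data generators: genomes, mosaic-population long reads (with an
# optional proviral insertion), edited amplicon read sets and growth counts,
# all with known ground truth and full seed determinism.

#' Generate a random genome for a genome spec
#'
#' Draws i.i.d. bases at a target GC content for every chromosome of the
#' spec. Sequences are returned as a named character vector (FASTA-writable
#' with [write_fasta()]) carrying the spec as an attribute.
#'
#' @param spec A [genome_spec()].
#' @param gc Target G+C proportion, in (0, 1).
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#' @return Object of class `genome_seqs`: named character vector of
#'   chromosome sequences, with attribute `spec`.
#' @export
make_genome <- function(spec, gc = 0.42, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  if (gc <= 0 || gc >= 1) stop_input("gc must be in (0, 1)")
  seqs <- with_seed(seed, {
    vapply(spec$chromosomes, function(len) random_dna(len, gc), character(1))
  })
  structure(seqs, spec = spec, class = "genome_seqs")
}

#' @export
print.genome_seqs <- function(x, ...) {
  cat(sprintf("genome_seqs: %d chromosomes (%s)\n", length(x),
              paste(sprintf("%s:%d bp", names(x), nchar(x)), collapse = ", ")))
  invisible(x)
}

# Sample one read placement on a chromosome of length `len`: start uniform
# over [-(L-1), len-1] then clipped, so the expected per-base depth is
# uniform across the chromosome (no edge depression).
sample_placement <- function(len, L) {
  s <- floor(runif(1L, min = -(L - 1), max = len))
  c(start = max(s, 0), end = min(s + L, len))
}

#' Simulate long reads from a mosaic cell population
#'
#' Reads are drawn per chromosome at a rate proportional to the
#' population-average copy number, so binned coverage recovers
#' `depth_per_copy * avg_copies(chromosome)` in expectation. Read lengths
#' are lognormal (heavy-tailed, long-read-like); sequencing errors are
#' substitutions only, so read coordinates stay exact. If a `vector_spec`
#' is given, each read on the target chromosome originates from a carrier
#' haplotype with probability `carrier_fraction`; carrier reads whose
#' interval spans the insertion point contain the vector sequence spliced
#' in at that point. Truth placements always use reference (pre-insertion)
#' coordinates, 0-based half-open.
#'
#' @param genome A `genome_seqs` from [make_genome()].
#' @param population A [population_spec()].
#' @param depth_per_copy Fold coverage contributed by a single chromosome
#'   copy (>= 0).
#' @param read_length `c(mean, dispersion)`: mean read length in bp and the
#'   lognormal sdlog.
#' @param error_rate Per-base substitution rate, in [0, 0.2].
#' @param vector Optional [vector_spec()].
#' @param seed Integer seed.
#' @return Object of class `read_set`: list with `reads` (data.frame
#'   `id`, `sequence`) and `truth` (data.frame `id`, `chrom`, `start`,
#'   `end`, `strand`, `has_vector`).
#' @export
simulate_population_reads <- function(genome, population, depth_per_copy = 10,
                                      read_length = c(8000, 0.5),
                                      error_rate = 0.01, vector = NULL,
                                      seed = 1L) {
  stopifnot(inherits(genome, "genome_seqs"), inherits(population, "population_spec"))
  if (depth_per_copy < 0) stop_input("depth_per_copy must be >= 0")
  if (error_rate < 0 || error_rate > 0.2) stop_input("error_rate must be in [0, 0.2]")
  spec <- attr(genome, "spec")
  ac <- avg_copies(population)
  if (!all(names(spec$chromosomes) %in% names(ac))) {
    stop_input("population must define copies for every genome chromosome")
  }
  if (!is.null(vector)) {
    stopifnot(inherits(vector, "vector_spec"))
    if (!vector$chromosome %in% names(spec$chromosomes)) {
      stop_input("vector target chromosome '%s' not in genome", vector$chromosome)
    }
    if (vector$position > spec$chromosomes[[vector$chromosome]]) {
      stop_input("vector insertion position outside chromosome")
    }
  }
  m <- read_length[[1]]
  sdlog <- read_length[[2]]
  meanlog <- log(m) - sdlog^2 / 2

  with_seed(seed, {
    ids <- character(0); seqs <- character(0)
    t_id <- character(0); t_chr <- character(0)
    t_start <- numeric(0); t_end <- numeric(0)
    t_strand <- character(0); t_vec <- logical(0)
    for (chrom in names(spec$chromosomes)) {
      len <- spec$chromosomes[[chrom]]
      target_depth <- depth_per_copy * ac[[chrom]]
      if (target_depth <= 0) next
      # start positions may overhang both edges, so inflate n accordingly
      n <- rpois(1L, target_depth * (len + m - 1) / m)
      if (n == 0L) next
      L <- pmax(50, round(rlnorm(n, meanlog, sdlog)))
      starts <- floor(runif(n, min = -(L - 1), max = len))
      ends <- pmin(starts + L, len)
      starts <- pmax(starts, 0)
      keep <- ends - starts >= 50
      starts <- starts[keep]; ends <- ends[keep]
      n <- length(starts)
      if (n == 0L) next
      strand <- sample(c("+", "-"), n, replace = TRUE)
      carrier <- if (!is.null(vector) && chrom == vector$chromosome) {
        runif(n) < vector$carrier_fraction
      } else rep(FALSE, n)
      has_vec <- carrier & starts < vector_pos(vector) & ends > vector_pos(vector)
      rd <- character(n)
      for (i in seq_len(n)) {
        s <- substr(genome[[chrom]], starts[i] + 1L, ends[i])
        if (has_vec[i]) {
          p <- vector$position
          s <- paste0(substr(genome[[chrom]], starts[i] + 1L, p),
                      vector$sequence,
                      substr(genome[[chrom]], p + 1L, ends[i]))
        }
        s <- mutate_seq(s, error_rate)
        if (strand[i] == "-") s <- revcomp(s)
        rd[i] <- s
      }
      id <- sprintf("%s_read%06d", chrom, seq_len(n))
      ids <- c(ids, id); seqs <- c(seqs, rd)
      t_id <- c(t_id, id); t_chr <- c(t_chr, rep(chrom, n))
      t_start <- c(t_start, starts); t_end <- c(t_end, ends)
      t_strand <- c(t_strand, strand); t_vec <- c(t_vec, has_vec)
    }
    read_set(
      reads = data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE),
      truth = data.frame(id = t_id, chrom = t_chr, start = t_start,
                         end = t_end, strand = t_strand, has_vector = t_vec,
                         stringsAsFactors = FALSE)
    )
  })
}

vector_pos <- function(vector) if (is.null(vector)) -1 else vector$position

#' Construct a read set
#'
#' @param reads data.frame with columns `id`, `sequence`.
#' @param truth data.frame of truth placements (`id`, `chrom`, `start`,
#'   `end`, `strand`, 0-based half-open).
#' @return Object of class `read_set`.
#' @export
read_set <- function(reads, truth) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  if (anyDuplicated(reads$id)) stop_input("read ids must be unique")
  structure(list(reads = reads, truth = truth), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, %.3g bp total\n",
              nrow(x$reads), sum(nchar(x$reads$sequence))))
  invisible(x)
}

#' Simulate CRISPR amplicon reads with a known edited fraction
#'
#' Each read is the reference with probability `1 - edited_fraction`;
#' otherwise it carries exactly one indel of a size sampled from
#' `indel_spectrum`, placed at the cut site. Deletions remove bases
#' centered on the cut; insertions add random bases at the cut.
#'
#' @param reference_locus Amplicon reference sequence (single string).
#' @param cut_position 0-based cut coordinate (bases to the left of the
#'   blunt cut).
#' @param edited_fraction Proportion of edited reads, in [0, 1].
#' @param indel_spectrum Named numeric vector: names are signed indel sizes
#'   in bp (negative = deletion), values are sampling weights.
#' @param n_reads Number of reads to emit.
#' @param seed Integer seed.
#' @return Named character vector of reads; attribute `edited` is the
#'   logical truth vector.
#' @export
simulate_amplicon_reads <- function(reference_locus, cut_position,
                                    edited_fraction, indel_spectrum,
                                    n_reads, seed = 1L) {
  ref <- toupper(reference_locus)
  n <- nchar(ref)
  if (edited_fraction < 0 || edited_fraction > 1) {
    stop_input("edited_fraction must be in [0, 1]")
  }
  sizes <- as.integer(names(indel_spectrum))
  w <- as.numeric(indel_spectrum)
  if (anyNA(sizes) || any(sizes == 0L)) stop_input("indel sizes must be non-zero integers")
  if (any(w < 0) || all(w == 0)) stop_input("weights must be >= 0 and not all zero")
  for (d in sizes[sizes < 0]) {
    a <- cut_position - floor(-d / 2)
    if (a < 0 || a - d > n) stop_input("deletion of %d bp does not fit in the locus", d)
  }
  with_seed(seed, {
    edited <- runif(n_reads) < edited_fraction
    out <- rep(ref, n_reads)
    idx <- which(edited)
    if (length(idx)) {
      sz <- sample(sizes, length(idx), replace = TRUE, prob = w)
      for (j in seq_along(idx)) {
        s <- sz[j]
        out[idx[j]] <- if (s < 0) {
          d <- -s
          a <- cut_position - floor(d / 2)  # remove [a, a + d), centered on cut
          paste0(substr(ref, 1L, a), substr(ref, a + d + 1L, n))
        } else {
          paste0(substr(ref, 1L, cut_position), random_dna(s),
                 substr(ref, cut_position + 1L, n))
        }
      }
    }
    structure(setNames(out, sprintf("amp%06d", seq_len(n_reads))),
              edited = edited)
  })
}

#' Simulate exponential growth cell counts
#'
#' Counts follow `n0 * 2^(t / g)` with multiplicative lognormal noise of
#' the stated coefficient of variation (the noise has mean 1, so replicate
#' means are unbiased).
#'
#' @param n0 Starting cell count.
#' @param g Doubling time in hours (> 0).
#' @param times Collection times in hours, strictly increasing.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param replicates Replicate wells per time point.
#' @param seed Integer seed.
#' @return data.frame with columns `time_h`, `replicate`, `count`.
#' @export
simulate_growth_counts <- function(n0, g, times, cv = 0, replicates = 1L,
                                   seed = 1L) {
  if (g <= 0) stop_input("doubling time g must be > 0")
  if (is.unsorted(times, strictly = TRUE)) stop_input("times must be strictly increasing")
  if (cv < 0) stop_input("cv must be >= 0")
  mu <- n0 * 2^(times / g)
  with_seed(seed, {
    df <- expand.grid(replicate = seq_len(replicates), time_h = times,
                      KEEP.OUT.ATTRS = FALSE)
    df <- df[order(df$time_h, df$replicate), c("time_h", "replicate")]
    base <- rep(mu, each = replicates)
    noise <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(nrow(df), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    df$count <- base * noise
    rownames(df) <- NULL
    df
  })
}
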