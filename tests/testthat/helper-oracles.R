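# Shared fixtures and independent oracles used across the test files.

# Exhaustive brute-force global affine-gap alignment score: enumerates
# every alignment path recursively (no dynamic programming), attributing
# the gap-open cost to the rightmost column of each gap run. Only viable
# for tiny sequences; that is the point.
brute_align_score <- function(a, b, scoring = list(match = 2, mismatch = -4,
                                                   gap_open = -10,
                                                   gap_extend = -1)) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ma <- scoring$match; mi <- scoring$mismatch
  go <- scoring$gap_open; ge <- scoring$gap_extend
  rec <- function(i, j, right) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      v <- rec(i - 1L, j - 1L, 0L) + (if (av[i] == bv[j]) ma else mi)
      if (v > best) best <- v
    }
    if (j > 0L) {
      v <- rec(i, j - 1L, 1L) + ge + (if (right == 1L) 0 else go)
      if (v > best) best <- v
    }
    if (i > 0L) {
      v <- rec(i - 1L, j, 2L) + ge + (if (right == 2L) 0 else go)
      if (v > best) best <- v
    }
    best
  }
  rec(length(av), length(bv), 0L)
}

rand_dna <- function(n, gc = 0.5) clonecheck:::random_dna(n, gc)

with_test_seed <- function(seed, expr) clonecheck:::with_seed(seed, expr)

rc <- function(x) clonecheck:::revcomp(x)

gc_fraction <- function(s) {
  b <- table(strsplit(s, "")[[1]])
  sum(b[intersect(c("G", "C"), names(b))]) / nchar(s)
}

# small two-chromosome diploid fixture shared by a few tests
small_diploid_sim <- function(seed = 42, depth = 10) {
  spec <- genome_spec(c(chrA = 2e5, chrB = 1e5))
  genome <- make_genome(spec, gc = 0.42, seed = seed)
  reads <- simulate_population_reads(genome, uniform_population(spec),
                                     depth_per_copy = depth,
                                     read_length = c(5000, 0.4),
                                     error_rate = 0.01, seed = seed + 1)
  list(spec = spec, genome = genome, reads = reads)
}
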