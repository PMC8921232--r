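test_that("genome generation honors lengths, GC content and seed determinism", {
  spec <- genome_spec(c(chr1 = 100000, chr2 = 50000, chr3 = 20000))
  g1 <- make_genome(spec, gc = 0.40, seed = 7)
  expect_identical(unname(nchar(g1)), c(100000L, 50000L, 20000L))
  g2 <- make_genome(spec, gc = 0.40, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- make_genome(spec, gc = 0.40, seed = 8)
  expect_false(identical(as.character(g1), as.character(g3)))
  expect_lt(abs(gc_fraction(g1[["chr1"]]) - 0.40), 0.02)
  expect_error(genome_spec(c(chr1 = 0)), "positive")
  expect_error(make_genome(spec, gc = 1.2), "gc")
})

test_that("population read simulation recovers target coverage per chromosome", {
  spec <- genome_spec(c(chr1 = 6e5, chr2 = 6e5))
  genome <- make_genome(spec, seed = 1)
  pop <- population_spec(list(
    list(fraction = 0.5, copies = c(chr1 = 3, chr2 = 2)),
    list(fraction = 0.5, copies = c(chr1 = 2, chr2 = 2))
  ))
  expect_equal(unname(avg_copies(pop)[c("chr1", "chr2")]), c(2.5, 2))
  rs <- simulate_population_reads(genome, pop, depth_per_copy = 10,
                                  read_length = c(3000, 0.3),
                                  error_rate = 0, seed = 2)
  tr <- coverage_from_intervals(rs, spec, bin_size = 1000)
  expect_lt(abs(mean(tr$depths$chr2) - 20), 1)    # diploid at 10x/copy
  expect_lt(abs(mean(tr$depths$chr1) - 25), 1.5)  # 10 * (0.5*3 + 0.5*2)
  # conservation: emitted bases match depth x sum(length x avg copies)
  emitted <- sum(rs$truth$end - rs$truth$start)
  expected <- 10 * sum(spec$chromosomes * avg_copies(pop))
  expect_lt(abs(emitted / expected - 1), 0.05)
  # determinism
  rs2 <- simulate_population_reads(genome, pop, depth_per_copy = 10,
                                   read_length = c(3000, 0.3),
                                   error_rate = 0, seed = 2)
  expect_identical(rs$reads$sequence, rs2$reads$sequence)
  # placements lie within chromosome bounds
  expect_true(all(rs$truth$start >= 0))
  expect_true(all(rs$truth$end <= spec$chromosomes[rs$truth$chrom]))
})

test_that("zero depth gives an empty read set and bad vector targets error", {
  spec <- genome_spec(c(chr1 = 5e4))
  genome <- make_genome(spec, seed = 1)
  rs <- simulate_population_reads(genome, uniform_population(spec),
                                  depth_per_copy = 0, seed = 1)
  expect_identical(nrow(rs$reads), 0L)
  bad <- vector_spec(rand_dna(500), "chrX", 10, 0.5)
  expect_error(
    simulate_population_reads(genome, uniform_population(spec),
                              depth_per_copy = 1, vector = bad, seed = 1),
    "chrX")
})

test_that("reads spanning the insertion carry the vector; anchors match truth", {
  spec <- genome_spec(c(chr1 = 1e5))
  genome <- make_genome(spec, seed = 3)
  vec <- with_test_seed(4, rand_dna(1500, 0.45))
  vs <- vector_spec(vec, "chr1", 50000, carrier_fraction = 0.6)
  rs <- simulate_population_reads(genome, uniform_population(spec),
                                  depth_per_copy = 8,
                                  read_length = c(6000, 0.3),
                                  error_rate = 0, vector = vs, seed = 5)
  # every truth-carrier read contains the vector verbatim (error_rate 0),
  # on its own strand
  carries <- vapply(seq_len(nrow(rs$reads)), function(i) {
    grepl(vec, rs$reads$sequence[i], fixed = TRUE) ||
      grepl(rc(vec), rs$reads$sequence[i], fixed = TRUE)
  }, logical(1))
  expect_identical(sum(carries), sum(rs$truth$has_vector))
  expect_true(all(rs$truth$has_vector[carries]))
  # truth placements use pre-insertion reference coordinates spanning the site
  sp <- rs$truth[rs$truth$has_vector, ]
  expect_true(all(sp$start < 50000 & sp$end > 50000))
})

test_that("amplicon simulator hits the requested edited fraction and sizes", {
  ref <- with_test_seed(1, rand_dna(200))
  reads0 <- simulate_amplicon_reads(ref, 100, 0, c(`-3` = 1), 50, seed = 1)
  expect_true(all(reads0 == ref))
  reads1 <- simulate_amplicon_reads(ref, 100, 1, c(`-3` = 1), 50, seed = 1)
  expect_true(all(nchar(reads1) == nchar(ref) - 3))
  n <- 10000
  reads <- simulate_amplicon_reads(ref, 100, 0.27,
                                   c(`-3` = 2, `-1` = 1, `5` = 1), n,
                                   seed = 9)
  n_edit <- sum(attr(reads, "edited"))
  expect_lt(abs(n_edit - 2700), 3 * sqrt(n * 0.27 * 0.73))
  expect_identical(sum(nchar(reads) != nchar(ref)), n_edit)
  expect_error(simulate_amplicon_reads(ref, 100, 1.2, c(`-3` = 1), 10),
               "edited_fraction")
  expect_error(simulate_amplicon_reads(ref, 100, 0.5, c(`0` = 1), 10),
               "non-zero")
  expect_error(simulate_amplicon_reads(ref, 3, 0.5, c(`-50` = 1), 10),
               "fit")
})

test_that("growth counts follow the exponential closed form", {
  g0 <- simulate_growth_counts(1000, 24, c(0, 24, 48), cv = 0)
  expect_equal(g0$count, c(1000, 2000, 4000))
  g1 <- simulate_growth_counts(1000, 12, c(0, 24), cv = 0)
  expect_equal(g1$count[2] / g1$count[1], 4)
  # lognormal noise is mean-1: replicate means stay near the closed form
  reps <- 6
  gr <- simulate_growth_counts(1000, 24, c(0, 24, 48), cv = 0.1,
                               replicates = reps, seed = 11)
  mu <- 1000 * 2^(c(0, 24, 48) / 24)
  for (k in seq_along(mu)) {
    x <- gr$count[gr$time_h == c(0, 24, 48)[k]]
    se <- 0.1 * mu[k] / sqrt(reps)
    expect_lt(abs(mean(x) - mu[k]), 3 * se)
  }
  expect_error(simulate_growth_counts(1000, -1, c(0, 24)), "g must be")
  expect_error(simulate_growth_counts(1000, 24, c(24, 24)), "increasing")
})
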