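test_that("interval pileup bins depth correctly and conserves mass", {
  spec <- genome_spec(c(chr1 = 3000, chr2 = 1500))
  one <- data.frame(chrom = "chr1", start = 0, end = 1000)
  tr <- coverage_from_intervals(one, spec, bin_size = 1000)
  expect_equal(tr$depths$chr1, c(1, 0, 0))
  two <- rbind(one, one)
  tr2 <- coverage_from_intervals(two, spec, bin_size = 1000)
  expect_equal(tr2$depths$chr1, c(2, 0, 0))
  # partial last bin is normalized by its true width
  part <- data.frame(chrom = "chr2", start = 1000, end = 1500)
  trp <- coverage_from_intervals(part, spec, bin_size = 1000)
  expect_equal(trp$depths$chr2, c(0, 1))
  # mass conservation on a random interval set
  set.seed(21)
  n <- 300
  st <- floor(runif(n, 0, 2800))
  iv <- data.frame(chrom = "chr1", start = st,
                   end = pmin(st + floor(runif(n, 1, 400)), 3000))
  trr <- coverage_from_intervals(iv, spec, bin_size = 700)
  widths <- c(rep(700, 4), 200)
  expect_equal(sum(trr$depths$chr1 * widths), sum(iv$end - iv$start))
  expect_error(coverage_from_intervals(
    data.frame(chrom = "nope", start = 0, end = 10), spec), "unknown")
})

test_that("coverage density is normalized and finds constructed modes", {
  spec <- genome_spec(c(c1 = 200000))
  tr <- structure(list(bin_size = 1000, lengths = spec$chromosomes,
                       depths = list(c1 = rep(88.2, 200)), spec = spec),
                  class = "coverage_track")
  h <- coverage_histogram(tr, "c1")
  area <- sum(diff(h$grid) * (head(h$density, -1) + tail(h$density, -1)) / 2)
  expect_lt(abs(area - 1), 1e-6)
  expect_lt(abs(chromosome_peak(tr, "c1") - 88.2), 0.01)
  expect_lt(abs(estimate_mcn(tr)$mcn - 88.2), 0.01)
  # bimodal mixture: local maxima near both constructed levels
  set.seed(5)
  x <- c(rnorm(400, 20, 0.5), rnorm(400, 30, 0.5))
  tr$depths$c1 <- x
  h2 <- coverage_histogram(tr, "c1", bw = 0.5)
  dy <- diff(h2$density)
  peaks <- h2$grid[which(diff(sign(dy)) == -2) + 1]
  expect_true(any(abs(peaks - 20) < 1))
  expect_true(any(abs(peaks - 30) < 1))
  # all-zero chromosome: peak 0; MCN errors with no coverage anywhere
  tr$depths$c1 <- rep(0, 200)
  expect_equal(chromosome_peak(tr, "c1"), 0)
  expect_error(estimate_mcn(tr), "no coverage")
  # low-confidence flag on few bins
  tr$depths$c1 <- rep(5, 10)
  expect_true(coverage_histogram(tr, "c1")$low_confidence)
})

test_that("peak ratios and copy states reproduce the worked arithmetic", {
  expect_equal(round(ratio_to_mcn(140, 115)), 122)
  expect_equal(round(ratio_to_mcn(85, 115)), 74)
  expect_equal(ratio_to_mcn(33, 33), 100)
  expect_error(ratio_to_mcn(10, 0), "mcn")
  expect_identical(classify_copy_state(100), "at")
  expect_identical(classify_copy_state(122), "above")
  expect_identical(classify_copy_state(74), "below")
  expect_identical(classify_copy_state(c(110, 110.1)), c("at", "above"))
})

test_that("copy-state recovery and scale equivariance hold on simulation", {
  # average copies 1.0 .. 3.0 across five 500-kb chromosomes, >= 500 bins
  spec <- genome_spec(setNames(rep(5e5, 5), paste0("chr", 1:5)))
  genome <- make_genome(spec, seed = 31)
  pop <- population_spec(list(
    list(fraction = 0.5,
         copies = c(chr1 = 1, chr2 = 1, chr3 = 2, chr4 = 3, chr5 = 3)),
    list(fraction = 0.5,
         copies = c(chr1 = 1, chr2 = 2, chr3 = 2, chr4 = 2, chr5 = 3))
  ))
  truth <- avg_copies(pop)   # 1.0 1.5 2.0 2.5 3.0
  rs <- simulate_population_reads(genome, pop, depth_per_copy = 10,
                                  read_length = c(6000, 0.4),
                                  error_rate = 0.01, seed = 32)
  tr <- coverage_from_intervals(rs, spec, bin_size = 1000)
  calls <- call_karyotype(tr)
  for (i in seq_len(nrow(calls))) {
    ch <- calls$chromosome[i]
    expect_lt(abs(calls$est_avg_copies[i] - truth[[ch]]), 0.25)
    want <- if (truth[[ch]] > 2) "above" else if (truth[[ch]] < 2) "below" else "at"
    expect_identical(calls$state[i], want)
  }
  # majority mass defines the global mode: MCN tracks the 2-copy level
  expect_lt(abs(attr(calls, "mcn")$mcn - 20) / 20, 0.05)
  # scale equivariance: depths x3 scales mcn and peaks, fixes ratios/states
  tr3 <- tr
  tr3$depths <- lapply(tr$depths, `*`, 3)
  calls3 <- call_karyotype(tr3)
  expect_equal(attr(calls3, "mcn")$mcn, 3 * attr(calls, "mcn")$mcn,
               tolerance = 0.02)
  expect_equal(calls3$ratio_pct, calls$ratio_pct, tolerance = 0.02)
  expect_identical(calls3$state, calls$state)
})

test_that("Z/W coverage separates ZZ from ZW and flags anything else", {
  spec <- genome_spec(setNames(c(3e5, 3e5, 2e5, 2e5),
                               c("chr1", "chr2", "chrZ", "chrW")),
                      sex_chromosomes = c(z = "chrZ", w = "chrW"))
  genome <- make_genome(spec, seed = 41)
  male <- uniform_population(spec, 2, overrides = c(chrZ = 2, chrW = 0))
  rs_m <- simulate_population_reads(genome, male, depth_per_copy = 10,
                                    read_length = c(5000, 0.4), seed = 42)
  call_m <- infer_sex(coverage_from_intervals(rs_m, spec, 1000))
  expect_identical(call_m$call, "ZZ")
  female <- uniform_population(spec, 2, overrides = c(chrZ = 1, chrW = 1))
  rs_f <- simulate_population_reads(genome, female, depth_per_copy = 10,
                                    read_length = c(5000, 0.4), seed = 43)
  call_f <- infer_sex(coverage_from_intervals(rs_f, spec, 1000))
  expect_identical(call_f$call, "ZW")
  expect_lt(abs(call_f$z_ratio_pct - 50), 5)
  expect_lt(abs(call_f$w_ratio_pct - 50), 5)
  # a 75%/25% pattern matches neither rule
  tr <- coverage_from_intervals(rs_m, spec, 1000)
  tr$depths$chrZ <- rep(15, 200)
  tr$depths$chrW <- rep(5, 200)
  expect_identical(infer_sex(tr)$call, "ambiguous")
  spec2 <- genome_spec(c(chr1 = 1e5))
  tr2 <- coverage_from_intervals(data.frame(chrom = "chr1", start = 0,
                                            end = 1e5), spec2, 1000)
  expect_error(infer_sex(tr2), "sex chromosomes")
})
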