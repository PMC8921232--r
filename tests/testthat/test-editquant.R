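make_amplicon <- function(seed = 11, len = 220) {
  # random amplicon with a unique SaCas9 protospacer+PAM planted on the
  # forward strand; PAM "TAGAGT" matches NNGRRT
  with_test_seed(seed, {
    proto <- rand_dna(21)
    ref <- paste0(rand_dna(100), proto, "TAGAGT", rand_dna(len - 127))
    list(ref = ref, proto = proto)
  })
}

test_that("cut-site location is strand-aware and demands uniqueness", {
  amp <- make_amplicon()
  ar <- amplicon_ref(amp$ref, amp$proto)
  # protospacer occupies [100, 121): cut at 121 - 3 = 118
  expect_equal(ar$cut, 118)
  expect_identical(ar$strand, "+")
  # reverse-strand amplicon: mirrored coordinate
  ar_rc <- amplicon_ref(rc(amp$ref), amp$proto)
  expect_identical(ar_rc$strand, "-")
  expect_equal(ar_rc$cut, nchar(amp$ref) - 118)
  # absent or duplicated protospacer errors
  expect_error(amplicon_ref(rand_dna(200), amp$proto), "exactly once")
  dup <- paste0(amp$ref, amp$ref)
  expect_error(amplicon_ref(dup, amp$proto), "exactly once")
})

test_that("alignment recovers constructed indels and rejects bad input", {
  amp <- make_amplicon()
  ref <- amp$ref
  a0 <- align_global(ref, ref)
  expect_identical(a0$runs$op, "M")
  expect_equal(a0$score, 2 * nchar(ref))
  # 3-bp deletion at the cut: exactly one deletion run of length 3
  del <- paste0(substr(ref, 1, 117), substr(ref, 121, nchar(ref)))
  a1 <- align_global(del, ref)
  expect_identical(a1$runs$op[a1$runs$op != "M"], "D")
  expect_identical(a1$runs$length[a1$runs$op == "D"], 3L)
  expect_error(align_global("ACXGT", ref), "A, C, G, T")
  expect_error(align_global("", ref), "non-empty")
})

test_that("alignment scores match the exhaustive brute-force oracle", {
  sc <- list(match = 2, mismatch = -4, gap_open = -10, gap_extend = -1)
  with_test_seed(77, {
    for (i in 1:60) {
      a <- rand_dna(sample(1:8, 1))
      b <- rand_dna(sample(1:8, 1))
      expect_equal(align_global(a, b, sc)$score, brute_align_score(a, b, sc),
                   info = sprintf("a=%s b=%s", a, b))
    }
  })
})

test_that("alignment scores agree with an independent aligner on long pairs", {
  sc <- list(match = 2, mismatch = -4, gap_open = -10, gap_extend = -1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  with_test_seed(99, {
    for (i in 1:15) {
      ref <- rand_dna(150)
      # mutate: substitutions plus one random indel
      rd <- clonecheck:::mutate_seq(ref, 0.03)
      p <- sample(20:120, 1); L <- sample(1:8, 1)
      rd <- if (runif(1) < 0.5) {
        paste0(substr(rd, 1, p), substr(rd, p + L + 1, nchar(rd)))
      } else {
        paste0(substr(rd, 1, p), rand_dna(L), substr(rd, p + 1, nchar(rd)))
      }
      got <- align_global(rd, ref, sc)$score
      want <- Biostrings::score(Biostrings::pairwiseAlignment(
        rd, ref, substitutionMatrix = mat, gapOpening = 10,
        gapExtension = 1, type = "global"))
      expect_equal(got, want, info = paste("pair", i))
    }
  })
})

test_that("edit quantification counts cut-site indels and nothing else", {
  amp <- make_amplicon()
  ar <- amplicon_ref(amp$ref, amp$proto)
  wt <- rep(amp$ref, 73)
  del3 <- paste0(substr(amp$ref, 1, ar$cut - 1),
                 substr(amp$ref, ar$cut + 3, nchar(amp$ref)))
  prof <- quantify_edits(c(wt, rep(del3, 27)), ar)
  expect_identical(prof$n_modified, 27L)
  expect_equal(prof$percent_modified, 27)
  expect_identical(names(prof$indel_sizes), "-3")
  prof0 <- quantify_edits(wt, ar)
  expect_equal(prof0$percent_modified, 0)
  # an indel far from the cut never counts at the default window
  far <- paste0(substr(amp$ref, 1, 10), substr(amp$ref, 14, nchar(amp$ref)))
  prof_far <- quantify_edits(c(far, amp$ref), ar)
  expect_identical(prof_far$n_modified, 0L)
  expect_error(quantify_edits(character(0), ar), "empty")
})

test_that("simulated editing is recovered within binomial error; window is monotone", {
  amp <- make_amplicon(seed = 21, len = 240)
  ar <- amplicon_ref(amp$ref, amp$proto)
  spectrum <- c(`-3` = 3, `-1` = 2, `-6` = 1, `2` = 2, `10` = 1)
  for (p in c(0.01, 0.27, 0.9)) {
    n <- 4000
    reads <- simulate_amplicon_reads(amp$ref, ar$cut, p, spectrum, n,
                                     seed = round(1000 * p))
    prof <- quantify_edits(reads, ar)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(prof$percent_modified / 100 - p), 3 * se + 1e-9)
    wide <- quantify_edits(reads, ar, window = 15)
    expect_gte(wide$n_modified, prof$n_modified)
  }
  # size spectrum reporting: range reflects the generated sizes
  reads2 <- simulate_amplicon_reads(amp$ref, ar$cut, 1,
                                    c(`-83` = 1, `106` = 1), 200, seed = 5)
  prof2 <- quantify_edits(reads2, ar, window = 15)
  expect_equal(prof2$size_range, c(-83, 106))
})

test_that("clone classification follows the three-way thresholds exactly", {
  grid <- list(
    list(100, 0, "complete_knockout"),
    list(99, 1, "incomplete_knockout"),
    list(50, 50, "incomplete_knockout"),
    list(25, 75, "incomplete_knockout"),
    list(24.9, 75.1, "unedited_ambiguous"),
    list(0, 100, "unedited_ambiguous"),
    list(10, 90, "unedited_ambiguous"),
    list(99.5, 0.5, "incomplete_knockout")
  )
  for (g in grid) {
    expect_identical(classify_clone(g[[1]], g[[2]]), g[[3]])
  }
  expect_error(classify_clone(120, 0), "0, 100")
  expect_error(classify_clone(80, 30), "exceed")
})
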