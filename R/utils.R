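#' @useDynLib clonecheck, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats density bw.nrd0 median rbinom rlnorm rpois runif t.test setNames
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. Seed must be a single finite integer-like value < 2^31.
with_seed <- function(seed, expr) {
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

BASES <- c("A", "C", "G", "T")

# Random DNA of length n as a single string; gc gives the G+C proportion.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Substitution errors at a fixed per-base rate; substitutions only so that
# coordinates (and hence flank anchors) remain exact.
mutate_seq <- function(seq, error_rate) {
  if (error_rate <= 0 || nchar(seq) == 0L) return(seq)
  n <- nchar(seq)
  k <- rbinom(1L, n, error_rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  raw <- charToRaw(seq)
  # replace with a base drawn from the three alternatives
  shift <- sample.int(3L, k, replace = TRUE)
  lut <- charToRaw(paste(BASES, collapse = ""))
  cur <- match(raw[pos], lut)
  cur[is.na(cur)] <- 1L  # N or other: treat as A
  raw[pos] <- lut[((cur - 1L + shift) %% 4L) + 1L]
  rawToChar(raw)
}

#' Integer percentage of a count over a total
#'
#' Convenience helper used in reports: `100 * n / total`, rounded to the
#' nearest integer percent (half away from zero).
#'
#' @param n Numerator count.
#' @param total Denominator count, > 0.
#' @return Integer percentage.
#' @examples
#' percent_of(280, 325)   # 86
#' percent_of(15719, 22139)  # 71
#' @export
percent_of <- function(n, total) {
  stopifnot(is.numeric(n), is.numeric(total), all(total > 0))
  as.integer(floor(100 * n / total + 0.5))
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
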