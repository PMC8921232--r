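#' Define a genome layout for simulation and coverage analysis
#'
#' A genome spec is the minimal description the pipeline needs: ordered
#' chromosome names and lengths, optionally which chromosomes are the avian
#' Z and W sex chromosomes, and the baseline ploidy that a "normal"
#' chromosome pair is assumed to carry.
#'
#' @param chromosomes Named integer/numeric vector of chromosome lengths in
#'   base pairs; names are the chromosome names.
#' @param sex_chromosomes Optional character vector `c(z = ..., w = ...)`
#'   naming the Z and W chromosomes (both must be in `chromosomes`).
#' @param baseline_ploidy Integer >= 1; copies per chromosome in a euploid
#'   cell (default 2).
#' @return An object of class `genome_spec`.
#' @examples
#' genome_spec(c(chr1 = 1e5, chr2 = 5e4, chrZ = 2e4, chrW = 2e4),
#'             sex_chromosomes = c(z = "chrZ", w = "chrW"))
#' @export
genome_spec <- function(chromosomes, sex_chromosomes = NULL, baseline_ploidy = 2L) {
  nm <- names(chromosomes)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop_input("`chromosomes` must be a named vector of lengths")
  }
  if (anyDuplicated(nm)) stop_input("chromosome names must be unique")
  if (!all(is.finite(chromosomes)) || any(chromosomes <= 0)) {
    stop_input("chromosome lengths must be positive")
  }
  if (baseline_ploidy < 1) stop_input("baseline_ploidy must be >= 1")
  if (!is.null(sex_chromosomes)) {
    if (!all(c("z", "w") %in% names(sex_chromosomes))) {
      stop_input("sex_chromosomes must name both 'z' and 'w'")
    }
    if (!all(sex_chromosomes[c("z", "w")] %in% nm)) {
      stop_input("sex chromosomes must be present among chromosome names")
    }
  }
  structure(
    list(
      chromosomes = setNames(as.numeric(chromosomes), nm),
      sex_chromosomes = sex_chromosomes,
      baseline_ploidy = as.integer(baseline_ploidy)
    ),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosomes, %.3g bp total, baseline ploidy %d\n",
              length(x$chromosomes), sum(x$chromosomes), x$baseline_ploidy))
  if (!is.null(x$sex_chromosomes)) {
    cat(sprintf("  sex chromosomes: Z=%s W=%s\n",
                x$sex_chromosomes[["z"]], x$sex_chromosomes[["w"]]))
  }
  invisible(x)
}

#' Define a mosaic cell population by subclone copy numbers
#'
#' A mosaic population is a mixture of subclones, each present at a given
#' fraction and each carrying an integer copy number for every chromosome.
#' The population-average copy number per chromosome (the quantity that read
#' coverage actually reflects) is the fraction-weighted mean and need not be
#' an integer.
#'
#' @param subclones A list; each element is `list(fraction = , copies = )`
#'   where `copies` is a named vector of non-negative integer copy numbers,
#'   one per chromosome of the genome it will be used with.
#' @return An object of class `population_spec`.
#' @examples
#' # 50% trisomy-chr1 subclone on an otherwise diploid background
#' population_spec(list(
#'   list(fraction = 0.5, copies = c(chr1 = 3, chr2 = 2)),
#'   list(fraction = 0.5, copies = c(chr1 = 2, chr2 = 2))
#' ))
#' @export
population_spec <- function(subclones) {
  if (!length(subclones)) stop_input("at least one subclone is required")
  fr <- vapply(subclones, function(s) as.numeric(s$fraction), numeric(1))
  if (any(fr < 0)) stop_input("subclone fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop_input("subclone fractions must sum to 1 (got %.12g)", sum(fr))
  }
  nm <- names(subclones[[1]]$copies)
  if (is.null(nm)) stop_input("subclone copies must be a named vector")
  for (s in subclones) {
    cp <- s$copies
    if (!setequal(names(cp), nm)) {
      stop_input("all subclones must name the same chromosomes")
    }
    if (any(cp < 0) || any(cp != round(cp))) {
      stop_input("copy numbers must be non-negative integers")
    }
  }
  structure(list(subclones = subclones), class = "population_spec")
}

#' Population-average copy number per chromosome
#'
#' @param population A [population_spec()].
#' @return Named numeric vector of fraction-weighted average copies.
#' @export
avg_copies <- function(population) {
  stopifnot(inherits(population, "population_spec"))
  nm <- names(population$subclones[[1]]$copies)
  out <- setNames(numeric(length(nm)), nm)
  for (s in population$subclones) out <- out + s$fraction * s$copies[nm]
  out
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("population_spec: %d subclones\n", length(x$subclones)))
  ac <- avg_copies(x)
  cat("  average copies:",
      paste(sprintf("%s=%.2f", names(ac), ac), collapse = " "), "\n")
  invisible(x)
}

#' Uniform-ploidy population helper
#'
#' Single subclone carrying `copies` of every chromosome in `genome`
#' (per-chromosome overrides allowed).
#'
#' @param genome A [genome_spec()].
#' @param copies Default integer copy number for every chromosome.
#' @param overrides Optional named vector of per-chromosome copy numbers.
#' @return A [population_spec()].
#' @export
uniform_population <- function(genome, copies = 2L, overrides = NULL) {
  cp <- setNames(rep(as.integer(copies), length(genome$chromosomes)),
                 names(genome$chromosomes))
  if (!is.null(overrides)) cp[names(overrides)] <- as.integer(overrides)
  population_spec(list(list(fraction = 1, copies = cp)))
}

#' Describe a proviral/vector insertion carried by part of a population
#'
#' @param sequence Vector nucleotide sequence (a single string).
#' @param chromosome Target chromosome name.
#' @param position 0-based insertion position on the target chromosome
#'   (the vector is spliced between reference bases `position - 1` and
#'   `position`).
#' @param carrier_fraction Proportion of haplotype copies of the target
#'   chromosome that carry the insert, in (0, 1].
#' @return An object of class `vector_spec`.
#' @export
vector_spec <- function(sequence, chromosome, position, carrier_fraction = 1) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop_input("vector sequence must be non-empty")
  if (position < 0) stop_input("insertion position must be >= 0")
  if (carrier_fraction <= 0 || carrier_fraction > 1) {
    stop_input("carrier_fraction must be in (0, 1]")
  }
  structure(
    list(sequence = sequence, chromosome = chromosome,
         position = as.numeric(position),
         carrier_fraction = as.numeric(carrier_fraction)),
    class = "vector_spec"
  )
}

#' @export
print.vector_spec <- function(x, ...) {
  cat(sprintf("vector_spec: %d bp insert at %s:%d (carrier fraction %.2f)\n",
              nchar(x$sequence), x$chromosome, as.integer(x$position),
              x$carrier_fraction))
  invisible(x)
}
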