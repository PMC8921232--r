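# Coverage-based karyotyping: binned depth per chromosome, modal-coverage
# estimation of the mean-copy-number (MCN) level, per-chromosome peak
# classification and Z/W coverage sex inference.

#' Binned coverage from read placements
#'
#' Piles up 0-based half-open placement intervals onto fixed-width bins.
#' Each bin's depth is the total overlapping interval bases divided by the
#' bin's true width (the partial last bin is normalized by its own width),
#' so depth is in fold-coverage units.
#'
#' @param placements A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), or a `read_set` (its truth placements are used).
#' @param genome A [genome_spec()] or a `genome_seqs`.
#' @param bin_size Bin width in bp (default 1000).
#' @return Object of class `coverage_track`: list with `bin_size`,
#'   `lengths`, `depths` (named list of per-bin depth vectors) and the
#'   genome `spec`.
#' @export
coverage_from_intervals <- function(placements, genome, bin_size = 1000) {
  if (inherits(placements, "read_set")) placements <- placements$truth
  spec <- if (inherits(genome, "genome_seqs")) attr(genome, "spec") else genome
  stopifnot(inherits(spec, "genome_spec"))
  if (bin_size < 1) stop_input("bin_size must be >= 1")
  stopifnot(all(c("chrom", "start", "end") %in% names(placements)))
  unknown <- setdiff(unique(placements$chrom), names(spec$chromosomes))
  if (length(unknown)) {
    stop_input("placements on unknown chromosome(s): %s",
               paste(unknown, collapse = ", "))
  }
  if (any(placements$start < 0) || any(placements$end < placements$start)) {
    stop_input("malformed interval (negative start or end < start)")
  }
  depths <- lapply(names(spec$chromosomes), function(chrom) {
    len <- spec$chromosomes[[chrom]]
    sel <- placements$chrom == chrom
    nb <- ceiling(len / bin_size)
    bin_start <- (seq_len(nb) - 1L) * bin_size + 1L
    bin_end <- pmin(seq_len(nb) * bin_size, len)
    if (!any(sel)) return(numeric(nb))
    if (any(placements$end[sel] > len)) {
      stop_input("interval beyond end of chromosome %s", chrom)
    }
    ir <- IRanges::IRanges(start = placements$start[sel] + 1L,
                           end = placements$end[sel])
    cov <- IRanges::coverage(ir, width = len)
    as.numeric(IRanges::viewMeans(IRanges::Views(cov, bin_start, bin_end)))
  })
  names(depths) <- names(spec$chromosomes)
  structure(list(bin_size = bin_size, lengths = spec$chromosomes,
                 depths = depths, spec = spec),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosomes, bin size %d bp\n",
              length(x$depths), x$bin_size))
  mn <- vapply(x$depths, mean, numeric(1))
  cat("  mean depth:",
      paste(sprintf("%s=%.1f", names(mn), mn), collapse = " "), "\n")
  invisible(x)
}

# Gaussian KDE over depth values with a Silverman default bandwidth, a
# degenerate-spread fallback (constant tracks have zero nrd0 bandwidth),
# and trapezoid renormalization so the density integrates to 1 exactly.
depth_density <- function(x, bw = NULL, n_grid = 2048L) {
  if (length(x) == 1L) x <- rep(x, 2L)
  if (is.null(bw)) {
    # nrd0 degenerates to abs(x[1]) on zero-spread data; use a narrow
    # kernel instead so a constant track peaks at its own value
    bw <- if (stats::sd(x) == 0) 0 else tryCatch(bw.nrd0(x), error = function(e) 0)
    if (!is.finite(bw) || bw <= 0) bw <- max(abs(mean(x)), 1) * 1e-3
  }
  d <- stats::density(x, bw = bw, n = n_grid)
  area <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  d$y <- d$y / area
  d
}

#' Smoothed coverage density for one chromosome
#'
#' Gaussian kernel density of that chromosome's per-bin depths (zero-depth
#' bins included). Bandwidth defaults to Silverman's rule; chromosomes with
#' fewer than `min_bins` bins are flagged low-confidence.
#'
#' @param track A `coverage_track`.
#' @param chromosome Chromosome name.
#' @param bw Optional bandwidth override (fold-coverage units).
#' @param min_bins Minimum bin count below which the density is flagged
#'   low-confidence (default 50).
#' @return List with `grid`, `density`, `bw`, `n_bins`, `low_confidence`.
#' @export
coverage_histogram <- function(track, chromosome, bw = NULL, min_bins = 50L) {
  stopifnot(inherits(track, "coverage_track"))
  x <- track$depths[[chromosome]]
  if (is.null(x)) stop_input("chromosome '%s' not in track", chromosome)
  d <- depth_density(x, bw)
  list(grid = d$x, density = d$y, bw = d$bw, n_bins = length(x),
       low_confidence = length(x) < min_bins)
}

#' Modal coverage of a chromosome (its coverage peak)
#'
#' The depth at the maximum of the chromosome's smoothed coverage density.
#' An all-zero chromosome has peak 0.
#'
#' @inheritParams coverage_histogram
#' @return Fold coverage at the density mode.
#' @export
chromosome_peak <- function(track, chromosome, bw = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  x <- track$depths[[chromosome]]
  if (is.null(x)) stop_input("chromosome '%s' not in track", chromosome)
  if (all(x == 0)) return(0)
  h <- coverage_histogram(track, chromosome, bw = bw)
  h$grid[which.max(h$density)]
}

#' Estimate the mean-copy-number (MCN) coverage level
#'
#' The MCN coverage level is the global mode of the pooled per-bin depth
#' density across all chromosomes. In a mosaic population most chromosomal
#' mass sits at the population-typical copy number, so the global mode
#' tracks that level even when individual chromosomes deviate. Zero-depth
#' bins are excluded from pooling: they encode unsequenced or absent
#' sequence (e.g. the W chromosome in a ZZ male) rather than a coverage
#' level.
#'
#' @param track A `coverage_track`.
#' @param bw Optional bandwidth override.
#' @return Object of class `mcn_estimate`: list with `mcn`, `bw`,
#'   `n_bins`.
#' @export
estimate_mcn <- function(track, bw = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  x <- unlist(track$depths, use.names = FALSE)
  x <- x[x > 0]
  if (!length(x)) stop_input("no coverage: all bins have zero depth")
  d <- depth_density(x, bw)
  structure(list(mcn = d$x[which.max(d$y)], bw = d$bw, n_bins = length(x)),
            class = "mcn_estimate")
}

#' @export
print.mcn_estimate <- function(x, ...) {
  cat(sprintf("MCN coverage level: %.2fX (Gaussian KDE, bw %.3g, %d non-zero bins)\n",
              x$mcn, x$bw, x$n_bins))
  invisible(x)
}

#' Peak coverage as a percentage of the MCN level
#'
#' @param peak Chromosome peak fold coverage.
#' @param mcn MCN fold coverage (> 0).
#' @return Percentage `100 * peak / mcn`, full precision (round for
#'   reports, e.g. with [percent_of()] semantics).
#' @examples
#' round(ratio_to_mcn(140, 115))  # 122
#' round(ratio_to_mcn(85, 115))   # 74
#' @export
ratio_to_mcn <- function(peak, mcn) {
  if (any(mcn <= 0)) stop_input("mcn must be > 0")
  if (any(peak < 0)) stop_input("peak must be >= 0")
  100 * peak / mcn
}

#' Classify a chromosome's copy state relative to the MCN
#'
#' A chromosome peaking within `at_band_pct` of 100% of the MCN is "at" the
#' MCN; above the band is "above"; below is "below".
#'
#' @param ratio_pct Peak-to-MCN ratio in percent.
#' @param at_band_pct Half-width of the "at" band in percentage points
#'   (default 10).
#' @return Character vector in `{"below", "at", "above"}`.
#' @export
classify_copy_state <- function(ratio_pct, at_band_pct = 10) {
  if (any(ratio_pct < 0)) stop_input("ratio_pct must be >= 0")
  ifelse(abs(ratio_pct - 100) <= at_band_pct, "at",
         ifelse(ratio_pct > 100 + at_band_pct, "above", "below"))
}

#' Infer genetic sex from Z and W coverage
#'
#' A homogametic ZZ individual shows the Z at the MCN level and the W
#' essentially absent; a heterogametic ZW individual shows both Z and W
#' peaking at half the MCN. Anything else is called ambiguous.
#'
#' @param track A `coverage_track` whose genome spec names the sex
#'   chromosomes (or pass `z_name`/`w_name`).
#' @param z_name,w_name Z and W chromosome names; default from the spec.
#' @param mcn MCN fold coverage; estimated from the track if missing.
#' @param at_band_pct Band half-width in percentage points (default 10).
#' @param absent_threshold Ratio (percent of MCN) below which the W is
#'   considered absent (default 10).
#' @return Object of class `sex_call`: list with `call` in
#'   `{"ZZ","ZW","ambiguous"}`, `z_ratio_pct`, `w_ratio_pct`.
#' @export
infer_sex <- function(track, z_name = NULL, w_name = NULL, mcn = NULL,
                      at_band_pct = 10, absent_threshold = 10) {
  stopifnot(inherits(track, "coverage_track"))
  sx <- track$spec$sex_chromosomes
  if (is.null(z_name)) z_name <- sx[["z"]]
  if (is.null(w_name)) w_name <- sx[["w"]]
  if (is.null(z_name) || is.null(w_name)) {
    stop_input("sex chromosomes not specified in the genome spec")
  }
  if (!all(c(z_name, w_name) %in% names(track$depths))) {
    stop_input("sex chromosomes missing from the coverage track")
  }
  if (is.null(mcn)) mcn <- estimate_mcn(track)$mcn
  if (inherits(mcn, "mcn_estimate")) mcn <- mcn$mcn
  z <- ratio_to_mcn(chromosome_peak(track, z_name), mcn)
  w <- ratio_to_mcn(chromosome_peak(track, w_name), mcn)
  call <- if (w < absent_threshold && abs(z - 100) <= at_band_pct) "ZZ"
          else if (abs(z - 50) <= at_band_pct && abs(w - 50) <= at_band_pct) "ZW"
          else "ambiguous"
  structure(list(call = call, z_ratio_pct = z, w_ratio_pct = w),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("sex call: %s (Z %.0f%% of MCN, W %.0f%% of MCN)\n",
              x$call, x$z_ratio_pct, x$w_ratio_pct))
  invisible(x)
}

#' Coverage karyotype: classify every chromosome against the MCN
#'
#' Runs the full coverage-karyotyping stage: estimates the MCN level,
#' locates each chromosome's coverage peak, computes peak-to-MCN ratios,
#' classifies copy states and (when the genome spec names sex chromosomes)
#' infers genetic sex. `est_avg_copies` converts the ratio to an average
#' copy number under the assumption that the MCN level corresponds to
#' `baseline_ploidy` copies; in a heavily aneuploid line the MCN need not
#' represent a diploid pair, so treat that column as assumption-dependent.
#'
#' @param track A `coverage_track`.
#' @param at_band_pct Half-width of the "at" band in percent (default 10).
#' @param min_bins Low-confidence flag threshold (default 50 bins).
#' @param bw Optional KDE bandwidth override.
#' @return Object of class `copy_calls`: data.frame with one row per
#'   chromosome (`chromosome`, `n_bins`, `peak`, `ratio_pct`, `state`,
#'   `est_avg_copies`, `low_confidence`), with attributes `mcn`
#'   (an `mcn_estimate`) and `sex` (a `sex_call` or NULL).
#' @export
call_karyotype <- function(track, at_band_pct = 10, min_bins = 50L, bw = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  mcn <- estimate_mcn(track, bw = bw)
  chroms <- names(track$depths)
  peak <- vapply(chroms, function(ch) chromosome_peak(track, ch, bw = bw),
                 numeric(1))
  ratio <- ratio_to_mcn(peak, mcn$mcn)
  df <- data.frame(
    chromosome = chroms,
    n_bins = vapply(track$depths, length, integer(1)),
    peak = peak,
    ratio_pct = ratio,
    state = classify_copy_state(ratio, at_band_pct),
    est_avg_copies = ratio / 100 * track$spec$baseline_ploidy,
    low_confidence = vapply(track$depths, length, integer(1)) < min_bins,
    stringsAsFactors = FALSE, row.names = NULL
  )
  sex <- if (!is.null(track$spec$sex_chromosomes)) {
    infer_sex(track, mcn = mcn$mcn, at_band_pct = at_band_pct)
  }
  structure(df, class = c("copy_calls", "data.frame"),
            mcn = mcn, sex = sex, at_band_pct = at_band_pct)
}

#' @export
print.copy_calls <- function(x, ...) {
  mcn <- attr(x, "mcn")
  cat(sprintf("Coverage karyotype (MCN %.1fX, at-band ±%g%%)\n",
              mcn$mcn, attr(x, "at_band_pct")))
  if (!is.null(attr(x, "sex"))) print(attr(x, "sex"))
  df <- as.data.frame(x)
  df$peak <- round(df$peak, 1)
  df$ratio_pct <- round(df$ratio_pct)
  df$est_avg_copies <- round(df$est_avg_copies, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.copy_calls <- function(object, ...) {
  tab <- table(factor(object$state, levels = c("below", "at", "above")))
  cat(sprintf("%d of %d chromosomes at the MCN, %d above, %d below\n",
              tab[["at"]], nrow(object), tab[["above"]], tab[["below"]]))
  invisible(tab)
}

#' Plot per-chromosome coverage densities
#'
#' One smoothed depth density per chromosome with the MCN level marked,
#' mirroring a coverage-peak ridgeline read.
#'
#' @param x A `coverage_track`.
#' @param mcn Optional MCN level to mark (estimated if missing).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, NULL.
#' @importFrom graphics matplot abline legend
#' @export
plot.coverage_track <- function(x, mcn = NULL, ...) {
  if (is.null(mcn)) mcn <- estimate_mcn(x)$mcn
  hs <- lapply(names(x$depths), function(ch) coverage_histogram(x, ch))
  grid <- seq(0, max(vapply(hs, function(h) max(h$grid), numeric(1))),
              length.out = 512)
  ys <- vapply(hs, function(h) approx_density(h, grid), numeric(length(grid)))
  matplot(grid, ys, type = "l", lty = 1, xlab = "fold coverage",
          ylab = "density", ...)
  abline(v = mcn, col = "red", lty = 3)
  legend("topright", legend = names(x$depths), lty = 1,
         col = seq_along(x$depths), cex = 0.7, bty = "n")
  invisible(NULL)
}

approx_density <- function(h, grid) {
  out <- stats::approx(h$grid, h$density, xout = grid, yleft = 0, yright = 0)$y
  out
}
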