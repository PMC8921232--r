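# Readers/writers for FASTA, BED, BEDGRAPH and TSV tables, plus the YAML
# run configuration. All coordinates are 0-based half-open (BED
# convention). Every file written by the package starts with a '#'
# provenance comment block (tool version, stage, effective parameters,
# seed); readers skip '#' lines.

provenance_lines <- function(stage, params = list(), seed = NULL) {
  p <- if (length(params)) {
    paste(vapply(names(params), function(k) {
      sprintf("%s=%s", k, paste(format(params[[k]]), collapse = ","))
    }, character(1)), collapse = " ")
  } else "-"
  c(sprintf("# clonecheck %s", as.character(packageVersion("clonecheck"))),
    sprintf("# stage: %s", stage),
    sprintf("# params: %s", p),
    sprintf("# seed: %s", if (is.null(seed)) "-" else format(seed)))
}

write_with_provenance <- function(lines, path, stage, params = list(),
                                  seed = NULL) {
  writeLines(c(provenance_lines(stage, params, seed), lines), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Gzip-transparent; sequences are case-normalized to uppercase.
#' Duplicate ids and empty sequences are input errors.
#'
#' @param path FASTA file path (optionally .gz).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop_input("duplicate FASTA ids: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(BiocGenerics::width(ss) == 0L)) stop_input("empty FASTA sequence")
  setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (or `genome_seqs`) of sequences.
#' @param path Output path (.gz for gzip).
#' @param width Line-wrap width (default 80).
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  x <- Biostrings::DNAStringSet(unclass(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a BED file of 0-based half-open intervals
#'
#' Accepts 3+ column BED; '#' comment and track lines are skipped.
#' Malformed lines (fewer than 3 fields, non-numeric or negative
#' coordinates, end <= start) raise an error naming the line number.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, and `name`, `strand`
#'   when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  out <- list(chrom = character(0), start = numeric(0), end = numeric(0),
              name = character(0), strand = character(0))
  ln <- which(keep)
  if (!length(ln)) return(data.frame(chrom = character(0), start = numeric(0),
                                     end = numeric(0)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) stop_input("BED line %d: fewer than 3 fields", ln[i])
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop_input("BED line %d: non-numeric coordinates", ln[i])
    if (s < 0) stop_input("BED line %d: negative start", ln[i])
    if (e <= s) stop_input("BED line %d: end <= start", ln[i])
  }
  df <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1L),
    start = as.numeric(vapply(fields, `[`, character(1), 2L)),
    end = as.numeric(vapply(fields, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  nf <- lengths(fields)
  if (all(nf >= 4L)) df$name <- vapply(fields, `[`, character(1), 4L)
  if (all(nf >= 6L)) df$strand <- vapply(fields, `[`, character(1), 6L)
  df
}

#' Write intervals to BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optional `name`, `strand`.
#' @param path Output path.
#' @param stage,params,seed Provenance recorded in the header.
#' @return Invisibly, the path.
#' @export
write_bed <- function(intervals, path, stage = "bed", params = list(),
                      seed = NULL) {
  nm <- if (!is.null(intervals$name)) intervals$name else "."
  cols <- cbind(intervals$chrom, format(intervals$start, scientific = FALSE,
                                        trim = TRUE),
                format(intervals$end, scientific = FALSE, trim = TRUE), nm)
  if (!is.null(intervals$strand)) cols <- cbind(cols, 0L, intervals$strand)
  lines <- apply(cols, 1L, paste, collapse = "\t")
  write_with_provenance(lines, path, stage, params, seed)
}

#' Write a coverage track to BEDGRAPH
#'
#' Fixed-step bins partitioning each chromosome, 0-based half-open.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @inheritParams write_bed
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path, stage = "coverage", params = list(),
                           seed = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  lines <- unlist(lapply(names(track$depths), function(ch) {
    d <- track$depths[[ch]]
    nb <- length(d)
    start <- (seq_len(nb) - 1L) * track$bin_size
    end <- pmin(seq_len(nb) * track$bin_size, track$lengths[[ch]])
    sprintf("%s\t%s\t%s\t%.6g", ch,
            format(start, scientific = FALSE, trim = TRUE),
            format(end, scientific = FALSE, trim = TRUE), d)
  }))
  write_with_provenance(lines, path,
                        stage, c(params, list(bin_size = track$bin_size)),
                        seed)
}

#' Read a BEDGRAPH coverage track
#'
#' Expects fixed-step bins that partition each chromosome (as written by
#' [write_bedgraph()]). Chromosome lengths are taken from the last bin
#' end; pass `genome` to attach sex-chromosome/ploidy information.
#'
#' @param path BEDGRAPH path.
#' @param genome Optional [genome_spec()].
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ln <- which(keep)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 4L) {
      stop_input("BEDGRAPH line %d: fewer than 4 fields", ln[i])
    }
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- as.numeric(vapply(fields, `[`, character(1), 2L))
  end <- as.numeric(vapply(fields, `[`, character(1), 3L))
  depth <- as.numeric(vapply(fields, `[`, character(1), 4L))
  if (anyNA(start) || anyNA(end) || anyNA(depth)) {
    stop_input("BEDGRAPH: non-numeric fields")
  }
  chroms <- unique(chrom)
  bin_size <- (end - start)[1]
  depths <- lapply(chroms, function(ch) depth[chrom == ch])
  names(depths) <- chroms
  lengths <- vapply(chroms, function(ch) max(end[chrom == ch]), numeric(1))
  spec <- if (!is.null(genome)) genome else genome_spec(lengths)
  structure(list(bin_size = bin_size, lengths = spec$chromosomes,
                 depths = depths, spec = spec),
            class = "coverage_track")
}

#' Read/write growth-count TSV tables
#'
#' Columns `time_h`, `replicate`, `count`; '#' header lines are skipped
#' on read.
#'
#' @param path TSV path.
#' @return `read_growth_tsv`: data.frame; `write_growth_tsv`: the path,
#'   invisibly.
#' @export
read_growth_tsv <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_h", "replicate", "count")
  if (!all(need %in% names(df))) {
    stop_input("growth TSV must have columns: %s", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_growth_tsv
#' @param counts data.frame with `time_h`, `replicate`, `count`.
#' @inheritParams write_bed
#' @export
write_growth_tsv <- function(counts, path, stage = "growth", params = list(),
                             seed = NULL) {
  lines <- c(paste(names(counts), collapse = "\t"),
             apply(counts, 1L, function(r) paste(format(r, trim = TRUE),
                                                 collapse = "\t")))
  write_with_provenance(lines, path, stage, params, seed)
}

#' Write the coverage-karyotype report
#'
#' TSV with one row per chromosome plus a sex-call header line.
#'
#' @param calls A `copy_calls` object from [call_karyotype()].
#' @param path Output path.
#' @inheritParams write_bed
#' @return Invisibly, the path.
#' @export
write_karyotype_report <- function(calls, path, stage = "mcn",
                                   params = list(), seed = NULL) {
  stopifnot(inherits(calls, "copy_calls"))
  mcn <- attr(calls, "mcn"); sex <- attr(calls, "sex")
  extra <- c(sprintf("# mcn: %.4f", mcn$mcn),
             if (!is.null(sex)) {
               sprintf("# sex_call: %s (z_ratio_pct=%.1f w_ratio_pct=%.1f)",
                       sex$call, sex$z_ratio_pct, sex$w_ratio_pct)
             })
  df <- as.data.frame(calls)
  df$peak <- sprintf("%.4f", df$peak)
  df$ratio_pct <- round(df$ratio_pct)
  df$est_avg_copies <- sprintf("%.3f", df$est_avg_copies)
  lines <- c(extra, paste(names(df), collapse = "\t"),
             apply(df, 1L, function(r) paste(format(r, trim = TRUE),
                                             collapse = "\t")))
  write_with_provenance(lines, path, stage, params, seed)
}

#' Default run configuration
#'
#' Every pipeline parameter with its documented default. A YAML config
#' file may override any subset; unknown keys are rejected.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_chromosomes = 3L, chromosome_length = 100000, gc = 0.42,
      baseline_ploidy = 2L, copies = NULL,
      depth_per_copy = 10, read_length_mean = 8000, read_length_sdlog = 0.5,
      error_rate = 0.01,
      insert_vector = FALSE, vector_length = 2000, vector_position = NULL,
      carrier_fraction = 0.5,
      growth_n0 = 1000, growth_g = 24, growth_times = seq(0, 144, 24),
      growth_cv = 0.1, growth_replicates = 3L
    ),
    coverage = list(bin_size = 1000),
    karyotype = list(at_band_pct = 10, min_bins = 50L),
    insertions = list(k = 21L, min_kmers = 5L, min_votes = 5L,
                      cluster_window = 500),
    edits = list(window = 1L, pam = "NNGRRT", cut_offset = -3L,
                 match = 2, mismatch = -4, gap_open = -10, gap_extend = -1,
                 include_substitutions = FALSE),
    growth = list(n_intervals = 3L)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stop_input("unknown config key: %s", full)
    if (is.list(base[[k]]) && !is.null(base[[k]])) {
      if (!is.list(user[[k]])) stop_input("config key %s must be a mapping", full)
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Starts from [default_config()] and overrides with the file's values;
#' unknown keys are rejected with their full path.
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user)
}
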