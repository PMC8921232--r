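# CRISPR amplicon indel quantification: guide/PAM cut-site location,
# global affine-gap alignment with left-aligned indels, windowed indel
# counting, and knockout clone classification.

#' Describe an amplicon reference with its guide target
#'
#' @param reference Amplicon reference sequence.
#' @param protospacer 20-21 nt guide target sequence (as on the targeted
#'   strand, PAM-proximal end last).
#' @param pam PAM pattern in IUPAC code (default `"NNGRRT"`, SaCas9).
#' @param cut_offset Signed cut offset in bp relative to the PAM-proximal
#'   protospacer end (default -3, the standard blunt cut 3 bp 5' of the
#'   PAM).
#' @return Object of class `amplicon_ref` with the derived `cut` (0-based
#'   gap coordinate: number of reference bases left of the blunt cut) and
#'   `strand` of the protospacer match.
#' @export
amplicon_ref <- function(reference, protospacer, pam = "NNGRRT",
                         cut_offset = -3L) {
  reference <- toupper(reference)
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  obj <- list(reference = reference, protospacer = protospacer, pam = pam,
              cut_offset = as.integer(cut_offset))
  cut <- locate_cut_site(obj)
  obj$cut <- cut
  obj$strand <- attr(cut, "strand")
  obj$cut <- as.numeric(cut)
  structure(obj, class = "amplicon_ref")
}

#' Locate the predicted nuclease cut site in an amplicon reference
#'
#' Searches both strands for the protospacer immediately followed by the
#' PAM (IUPAC-aware). Exactly one occurrence must exist. The cut position
#' is reported as a 0-based gap coordinate: the blunt cut falls between
#' reference bases `cut - 1` and `cut`.
#'
#' @param ref An `amplicon_ref` (or a list with `reference`,
#'   `protospacer`, `pam`, `cut_offset`).
#' @return Cut coordinate with attribute `strand`.
#' @export
locate_cut_site <- function(ref) {
  subject <- Biostrings::DNAString(ref$reference)
  pat <- Biostrings::DNAString(paste0(ref$protospacer, ref$pam))
  fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                  subject, fixed = FALSE)
  n_f <- length(fwd); n_r <- length(rev)
  if (n_f + n_r != 1L) {
    stop_input("protospacer+PAM must occur exactly once in the reference (found %d forward, %d reverse)",
               n_f, n_r)
  }
  np <- nchar(ref$protospacer); npam <- nchar(ref$pam)
  if (n_f == 1L) {
    e <- BiocGenerics::start(fwd)[1] - 1L + np      # 0-based exclusive end
    cut <- e + ref$cut_offset
    strand <- "+"
  } else {
    s0 <- BiocGenerics::start(rev)[1] - 1L          # 0-based match start
    cut <- s0 + npam - ref$cut_offset               # mirrored coordinate
    strand <- "-"
  }
  if (cut < 0 || cut > nchar(ref$reference)) {
    stop_input("derived cut position falls outside the reference")
  }
  structure(cut, strand = strand)
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat(sprintf("amplicon_ref: %d bp, protospacer on %s strand, cut at %d\n",
              nchar(x$reference), x$strand, as.integer(x$cut)))
  invisible(x)
}

default_scoring <- function() {
  list(match = 2, mismatch = -4, gap_open = -10, gap_extend = -1)
}

#' Global affine-gap alignment of a read against a reference
#'
#' Optimal global alignment under affine gap scoring (a gap of length L
#' scores `gap_open + L * gap_extend`). Tie-breaking is deterministic
#' (deletion preferred over insertion over diagonal) and gaps are
#' left-aligned. The default scoring strongly prefers one long gap over
#' scattered mismatches, which suits amplicon indel typing.
#'
#' @param read,reference Nucleotide strings (ACGTN).
#' @param scoring List with `match`, `mismatch`, `gap_open`,
#'   `gap_extend`.
#' @return Object of class `pairwise_alignment`: list with `score`, `ops`
#'   (one letter per alignment column: M/D/I) and `runs`, a data.frame of
#'   collapsed op runs with 0-based `ref_start` and `read_start`.
#' @export
align_global <- function(read, reference, scoring = default_scoring()) {
  read <- toupper(read); reference <- toupper(reference)
  if (!nchar(read) || !nchar(reference)) {
    stop_input("both sequences must be non-empty")
  }
  if (grepl("[^ACGTN]", read) || grepl("[^ACGTN]", reference)) {
    stop_input("sequences may contain only A, C, G, T, N")
  }
  res <- cpp_align_global(read, reference, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend)
  r <- rle(strsplit(res$ops, "")[[1]])
  n_run <- length(r$lengths)
  ref_start <- read_start <- integer(n_run)
  rp <- qp <- 0L
  for (i in seq_len(n_run)) {
    ref_start[i] <- rp; read_start[i] <- qp
    if (r$values[i] == "M") { rp <- rp + r$lengths[i]; qp <- qp + r$lengths[i] }
    else if (r$values[i] == "D") rp <- rp + r$lengths[i]
    else qp <- qp + r$lengths[i]
  }
  structure(list(score = res$score, ops = res$ops,
                 runs = data.frame(op = r$values, length = r$lengths,
                                   ref_start = ref_start,
                                   read_start = read_start,
                                   stringsAsFactors = FALSE)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cig <- paste0(x$runs$length, x$runs$op, collapse = "")
  cat(sprintf("pairwise_alignment: score %g, cigar %s\n", x$score, cig))
  invisible(x)
}

# Positional ambiguity of an indel run inside repeats: the run was
# left-aligned by the aligner; slide it right as far as base identity
# allows and return the union of placements. Deletions: ref interval
# [a, b_max); insertions: gap-coordinate interval [j_min, j_max].
indel_reach <- function(run_op, ref, read, ref_start, read_start, len) {
  if (run_op == "D") {
    a <- ref_start; b <- ref_start + len
    b_max <- b
    aa <- a
    while (b_max < nchar(ref) &&
           substr(ref, aa + 1L, aa + 1L) == substr(ref, b_max + 1L, b_max + 1L)) {
      aa <- aa + 1L; b_max <- b_max + 1L
    }
    c(a, b_max)                      # deleted-base interval, widened right
  } else {
    j <- ref_start                   # insertion gap coordinate
    rp <- read_start; rq <- read_start + len
    j_max <- j
    while (rq < nchar(read) &&
           substr(read, rp + 1L, rp + 1L) == substr(read, rq + 1L, rq + 1L)) {
      rp <- rp + 1L; rq <- rq + 1L; j_max <- j_max + 1L
    }
    c(j, j_max)                      # gap-coordinate range
  }
}

#' Quantify indel editing in an amplicon read set
#'
#' Aligns each read globally to the amplicon reference and counts a read
#' as modified when an insertion or deletion run overlaps the window
#' `[cut - window, cut + window]`. An indel inside a repeat has an
#' ambiguous position; its whole equivalence range (all score-identical
#' placements) is used for the overlap test. Substitutions never count as
#' modified unless `include_substitutions = TRUE`. Net indel size per
#' modified read is the summed insertion length minus summed deletion
#' length within the window.
#'
#' @param reads Character vector of amplicon reads.
#' @param ref An [amplicon_ref()].
#' @param window Half-width of the quantification window in bp around the
#'   blunt cut (default 1; use 15 for a wide-window read of dispersed
#'   indels).
#' @param scoring Alignment scoring (see [align_global()]).
#' @param include_substitutions Also count reads with a substitution
#'   inside the window (default FALSE).
#' @return Object of class `edit_profile`: list with `n_reads`,
#'   `n_modified`, `percent_modified`, `indel_sizes` (named count table
#'   of net sizes), `size_range`.
#' @export
quantify_edits <- function(reads, ref, window = 1L,
                           scoring = default_scoring(),
                           include_substitutions = FALSE) {
  stopifnot(inherits(ref, "amplicon_ref"))
  if (window < 0) stop_input("window must be >= 0")
  if (!length(reads)) stop_input("empty read set")
  cut <- ref$cut
  lo <- cut - window; hi <- cut + window
  n_mod <- 0L
  sizes <- integer(0)
  for (rd in reads) {
    rd <- toupper(rd)
    if (rd == ref$reference) next            # fast path: exact wildtype
    aln <- align_global(rd, ref$reference, scoring = scoring)
    runs <- aln$runs
    net <- 0L; hit <- FALSE
    for (i in seq_len(nrow(runs))) {
      op <- runs$op[i]
      if (op == "M") next
      reach <- indel_reach(op, ref$reference, rd, runs$ref_start[i],
                           runs$read_start[i], runs$length[i])
      overlaps <- if (op == "D") reach[1] <= hi && reach[2] >= lo
                  else reach[1] <= hi && reach[2] >= lo
      if (overlaps) {
        hit <- TRUE
        net <- net + if (op == "I") runs$length[i] else -runs$length[i]
      }
    }
    if (!hit && include_substitutions) {
      # any mismatching M column inside the window?
      hit <- has_window_substitution(aln, rd, ref$reference, lo, hi)
    }
    if (hit) {
      n_mod <- n_mod + 1L
      sizes <- c(sizes, net)
    }
  }
  tab <- table(sizes)
  structure(list(
    n_reads = length(reads), n_modified = n_mod,
    percent_modified = 100 * n_mod / length(reads),
    indel_sizes = tab,
    size_range = if (length(sizes)) range(sizes) else c(NA_integer_, NA_integer_)
  ), class = "edit_profile")
}

has_window_substitution <- function(aln, read, ref, lo, hi) {
  runs <- aln$runs
  for (i in seq_len(nrow(runs))) {
    if (runs$op[i] != "M") next
    for (off in seq_len(runs$length[i]) - 1L) {
      rp <- runs$ref_start[i] + off
      if (rp >= lo && rp <= hi &&
          substr(ref, rp + 1L, rp + 1L) !=
          substr(read, runs$read_start[i] + off + 1L,
                 runs$read_start[i] + off + 1L)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' @export
print.edit_profile <- function(x, ...) {
  cat(sprintf("edit_profile: %d/%d reads modified (%.2f%%), indel sizes %s to %s bp\n",
              x$n_modified, x$n_reads, x$percent_modified,
              x$size_range[1], x$size_range[2]))
  invisible(x)
}

#' Classify a clone from its edited and wildtype allele percentages
#'
#' Three-way knockout classification: a clone with no wildtype
#' contribution is a complete knockout; 25-99% edited contribution
#' (inclusive on both ends) is an incomplete knockout; under 25% edited
#' is unedited/ambiguous. A clone with over 99% edited but residual
#' wildtype is classified incomplete.
#'
#' @param percent_edited,percent_wildtype Percentages in [0, 100] summing
#'   to at most 100 (other alleles may make up the rest).
#' @return One of `"complete_knockout"`, `"incomplete_knockout"`,
#'   `"unedited_ambiguous"`.
#' @export
classify_clone <- function(percent_edited, percent_wildtype) {
  if (percent_edited < 0 || percent_edited > 100 ||
      percent_wildtype < 0 || percent_wildtype > 100) {
    stop_input("percentages must be in [0, 100]")
  }
  if (percent_edited + percent_wildtype > 100 + 1e-9) {
    stop_input("edited + wildtype percentages exceed 100")
  }
  if (percent_wildtype == 0) return("complete_knockout")
  if (percent_edited >= 25) return("incomplete_knockout")
  "unedited_ambiguous"
}
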