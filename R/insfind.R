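# Proviral integration-site mapping: detect vector-containing reads,
# anchor their genomic flanks on the reference with unique-k-mer voting,
# and cluster the anchored junctions into insertion calls.

#' Find reads that contain a vector/provirus sequence
#'
#' A read is a hit when at least `min_kmers` distinct vector k-mers (from
#' either strand) occur in it. The match span is the minimal read interval
#' covering all seed matches, extended by ungapped extension against the
#' matching vector strand; orientation is the majority seed strand. Flanks
#' are the read sequence outside the span.
#'
#' @param reads A `read_set`, or a character vector of read sequences
#'   (names used as ids).
#' @param vector_seq Vector nucleotide sequence (string or
#'   [vector_spec()]).
#' @param k Anchor k-mer length (>= 11, <= 31; default 21).
#' @param min_kmers Minimum distinct shared k-mers to call a hit
#'   (default 5).
#' @return data.frame of class `vector_hits`: `id`, `start`, `end`
#'   (0-based half-open span in the read), `orientation`, `n_kmers`,
#'   `left_flank`, `right_flank`.
#' @export
find_vector_reads <- function(reads, vector_seq, k = 21L, min_kmers = 5L) {
  if (inherits(reads, "read_set")) {
    seqs <- setNames(reads$reads$sequence, reads$reads$id)
  } else {
    seqs <- reads
    if (is.null(names(seqs))) names(seqs) <- sprintf("read%d", seq_along(seqs))
  }
  if (inherits(vector_seq, "vector_spec")) vector_seq <- vector_seq$sequence
  if (k < 11) stop_input("k must be >= 11")
  if (nchar(vector_seq) < k) stop_input("vector shorter than k")
  hits <- cpp_find_vector_hits(unname(seqs), toupper(vector_seq),
                               as.integer(k), as.integer(min_kmers))
  id <- names(seqs)[hits$read_idx]
  lf <- substr(seqs[hits$read_idx], 1L, hits$start)
  rf <- substr(seqs[hits$read_idx], hits$end + 1L, nchar(seqs[hits$read_idx]))
  out <- data.frame(id = id, start = hits$start, end = hits$end,
                    orientation = hits$orientation, n_kmers = hits$n_kmers,
                    left_flank = unname(lf), right_flank = unname(rf),
                    stringsAsFactors = FALSE)
  class(out) <- c("vector_hits", "data.frame")
  out
}

#' Build a unique-k-mer index of a reference genome
#'
#' @param genome A `genome_seqs` or named character vector of chromosome
#'   sequences.
#' @param k K-mer length (default 21; max 31).
#' @return An opaque index handle for [map_flank()].
#' @export
genome_kmer_index <- function(genome, k = 21L) {
  seqs <- unclass(genome)
  attributes(seqs) <- list(names = names(genome))
  idx <- cpp_build_kmer_index(toupper(seqs), as.integer(k))
  structure(list(ptr = idx, k = as.integer(k)), class = "genome_kmer_index")
}

#' Anchor one flank of a vector-containing read on the reference
#'
#' Each flank k-mer that occurs uniquely in the reference votes for an
#' implied insertion-junction coordinate (both reference strands are
#' considered). The modal coordinate wins if it collects at least
#' `min_votes` votes and at least twice the runner-up's; otherwise the
#' flank is unplaced. Flanks shorter than k are unplaced, not an error.
#'
#' @param flank Flank nucleotide sequence (may be empty).
#' @param index A [genome_kmer_index()].
#' @param side `"left"` (flank 5' of the vector in the read) or
#'   `"right"`.
#' @param min_votes Minimum winning votes (default 5).
#' @return List: `placed` (logical), `chrom`, `junction` (0-based
#'   reference coordinate of the insertion point), `strand`, `votes`.
#' @export
map_flank <- function(flank, index, side = c("left", "right"),
                      min_votes = 5L) {
  side <- match.arg(side)
  stopifnot(inherits(index, "genome_kmer_index"))
  cpp_map_flank(toupper(flank), index$ptr,
                if (side == "left") 0L else 1L, as.integer(min_votes))
}

#' Cluster anchored junctions into insertion-site calls
#'
#' Junctions on the same chromosome within `cluster_window` of a cluster's
#' running median join that cluster; each call's position is the median of
#' its junctions. Calls are sorted by supporting-read count, descending.
#' The accounting identity `sum(support) + unplaced == total hits` always
#' holds.
#'
#' @param junctions data.frame with columns `chrom`, `junction` for the
#'   anchored hits; rows with NA are counted as unplaced.
#' @param n_unplaced Additional hits that had no confident anchor.
#' @param cluster_window Clustering half-width in bp (default 500).
#' @return Object of class `insertion_calls`: data.frame `chrom`,
#'   `position`, `support`, plus attribute `unplaced`.
#' @export
call_insertions <- function(junctions, n_unplaced = 0L, cluster_window = 500) {
  if (cluster_window < 0) stop_input("cluster_window must be >= 0")
  keep <- !is.na(junctions$junction) & !is.na(junctions$chrom)
  n_unplaced <- n_unplaced + sum(!keep)
  junctions <- junctions[keep, , drop = FALSE]
  calls <- data.frame(chrom = character(0), position = numeric(0),
                      support = integer(0), stringsAsFactors = FALSE)
  for (ch in unique(junctions$chrom)) {
    x <- sort(junctions$junction[junctions$chrom == ch])
    members <- list()
    for (v in x) {
      placed_in <- FALSE
      for (ci in seq_along(members)) {
        if (abs(v - median(members[[ci]])) <= cluster_window) {
          members[[ci]] <- c(members[[ci]], v)
          placed_in <- TRUE
          break
        }
      }
      if (!placed_in) members[[length(members) + 1L]] <- v
    }
    for (mem in members) {
      calls <- rbind(calls, data.frame(
        chrom = ch, position = median(mem), support = length(mem),
        stringsAsFactors = FALSE))
    }
  }
  calls <- calls[order(-calls$support, calls$chrom, calls$position), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("insertion_calls", "data.frame"),
            unplaced = as.integer(n_unplaced))
}

#' @export
print.insertion_calls <- function(x, ...) {
  cat(sprintf("insertion_calls: %d site(s), %d unplaced hit(s)\n",
              nrow(x), attr(x, "unplaced")))
  if (nrow(x)) print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Locate vector insertion sites in a read set
#'
#' Runs the full integration-site stage: detects vector-containing reads,
#' normalizes reverse-orientation hits, anchors left and right flanks by
#' unique-k-mer voting, reconciles the two flanks (the junction is the
#' reference base immediately 3' of the left flank; a hit whose flanks
#' disagree by more than `cluster_window` is counted unplaced) and
#' clusters junctions into calls.
#'
#' @inheritParams find_vector_reads
#' @param genome Reference `genome_seqs` (or named character vector).
#' @param min_votes Minimum winning votes for a flank anchor (default 5).
#' @param cluster_window Junction clustering window in bp (default 500).
#' @return An `insertion_calls` object; attribute `hits` carries the
#'   per-hit table (`id`, `chrom`, `junction`).
#' @export
locate_insertions <- function(reads, vector_seq, genome, k = 21L,
                              min_kmers = 5L, min_votes = 5L,
                              cluster_window = 500) {
  hits <- find_vector_reads(reads, vector_seq, k = k, min_kmers = min_kmers)
  index <- genome_kmer_index(genome, k = k)
  n <- nrow(hits)
  chrom <- rep(NA_character_, n); junction <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lf <- hits$left_flank[i]; rf <- hits$right_flank[i]
    if (hits$orientation[i] == "-") {
      # normalize so flanks are in vector-forward order
      tmp <- revcomp_or_empty(rf); rf <- revcomp_or_empty(lf); lf <- tmp
    }
    L <- map_flank(lf, index, "left", min_votes = min_votes)
    R <- map_flank(rf, index, "right", min_votes = min_votes)
    if (L$placed && R$placed) {
      if (identical(L$chrom, R$chrom) &&
          abs(L$junction - R$junction) <= cluster_window) {
        chrom[i] <- L$chrom; junction[i] <- L$junction
      }                                   # else: flank disagreement, unplaced
    } else if (L$placed) {
      chrom[i] <- L$chrom; junction[i] <- L$junction
    } else if (R$placed) {
      chrom[i] <- R$chrom; junction[i] <- R$junction
    }
  }
  per_hit <- data.frame(id = hits$id, chrom = chrom, junction = junction,
                        stringsAsFactors = FALSE)
  calls <- call_insertions(per_hit, cluster_window = cluster_window)
  attr(calls, "hits") <- per_hit
  calls
}

revcomp_or_empty <- function(x) if (nchar(x)) revcomp(x) else x
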