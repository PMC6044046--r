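# Inversion signal extraction.
#
# An inversion signal is a pair of read-adjacent sub-alignments of one read
# that map to the same chromosome in opposite orientation. Each such pair
# straddles one strand-switch junction of the read. The junction-adjacent
# ends of the two sub-alignments, mapped to reference space, pin the two
# breakpoints of the underlying inversion: for the first sub-alignment (in
# read order) the junction is at its read-space end (reference end if
# forward, reference start if reverse), for the second at its read-space
# start (reference start if forward, reference end if reverse). The
# signal's (ref_start, ref_end) are the smaller and larger of these two
# junction coordinates; outer alignment endpoints vary with the read
# length and are not used.

#' Extract inversion signals from one read's sub-alignments
#'
#' Evaluates every read-adjacent pair of sub-alignments (pairs are allowed
#' to overlap on the read). A pair on the same chromosome with opposite
#' orientations yields one signal; same-orientation or cross-chromosome
#' pairs yield none. The signal's strand label is the strand of the first
#' sub-alignment in read order; its side label is `"left"` when the first
#' sub-alignment's reference start exceeds the second's, `"right"`
#' otherwise. If the two read intervals overlap by more than
#' `cfg$nahr_overlap_min` bp -- the footprint of an inverted repeat aligned
#' in both orientations -- the signal is classified `NAHR`, else `NHEJ`.
#'
#' @param alns Sub-alignments of a single read, sorted by `read_start`
#'   (the output of [filter_subalignments()]).
#' @param cfg A [scan_config()].
#' @return A data.frame of signals with columns `read_id`, `chrom`,
#'   `ref_start`, `ref_end` (junction coordinates, 0-based), `side`,
#'   `strand`, `mechanism`, `ir_overlap`.
#' @export
extract_signals <- function(alns, cfg = scan_config()) {
  n <- nrow(alns)
  if (n < 2L) {
    return(.empty_signals())
  }
  stopifnot(!is.unsorted(alns$read_start))
  i <- seq_len(n - 1L)
  j <- i + 1L
  ok <- alns$chrom[i] == alns$chrom[j] & alns$strand[i] != alns$strand[j]
  i <- i[ok]
  j <- j[ok]
  if (!length(i)) {
    return(.empty_signals())
  }
  first_fwd <- alns$strand[i] == "+"
  jct1 <- ifelse(first_fwd, alns$ref_end[i], alns$ref_start[i])
  # the second member's junction is at its read-space start: reference
  # start when forward, reference end when reverse
  jct2 <- ifelse(alns$strand[j] == "+", alns$ref_start[j], alns$ref_end[j])
  overlap <- pmax(0, alns$read_end[i] - alns$read_start[j])
  data.frame(
    read_id = alns$read_id[i],
    chrom = alns$chrom[i],
    ref_start = pmin(jct1, jct2),
    ref_end = pmax(jct1, jct2),
    side = ifelse(alns$ref_start[i] > alns$ref_start[j], "left", "right"),
    strand = alns$strand[i],
    mechanism = ifelse(overlap > cfg$nahr_overlap_min, "NAHR", "NHEJ"),
    ir_overlap = as.numeric(overlap),
    stringsAsFactors = FALSE
  )
}

.empty_signals <- function() {
  data.frame(
    read_id = character(), chrom = character(),
    ref_start = numeric(), ref_end = numeric(),
    side = character(), strand = character(),
    mechanism = character(), ir_overlap = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Sort inversion signals by chromosome and left-most reference position
#'
#' @param signals A signal data.frame ([extract_signals()] output, possibly
#'   concatenated over reads).
#' @return The same rows, stably sorted by `(chrom, ref_start)`.
#' @export
sort_signals <- function(signals) {
  signals <- signals[order(signals$chrom, signals$ref_start), , drop = FALSE]
  rownames(signals) <- NULL
  signals
}

#' Scan a BAM file for inversion signals
#'
#' Runs [collect_subalignments()], [filter_subalignments()] and
#' [extract_signals()] over every multi-part read and returns the sorted
#' signal set.
#'
#' @inheritParams collect_subalignments
#' @return A sorted signal data.frame (see [extract_signals()]).
#' @export
scan_inversion_signals <- function(bam_file, cfg = scan_config(),
                                   which = NULL) {
  subs <- collect_subalignments(bam_file, cfg, which = which)
  if (!nrow(subs)) {
    return(.empty_signals())
  }
  groups <- split(seq_len(nrow(subs)), subs$read_id)
  sig_list <- lapply(groups, function(idx) {
    extract_signals(filter_subalignments(subs[idx, , drop = FALSE], cfg), cfg)
  })
  sig <- data.table::rbindlist(sig_list)
  sort_signals(as.data.frame(sig))
}
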