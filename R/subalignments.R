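# Extraction of per-read sub-alignments from BAM.
#
# A long read crossing an inversion breakpoint is split by the aligner into
# several sub-alignments (a primary record plus supplementary records,
# cross-referenced through SA tags). All coordinates here are 0-based
# half-open; read-space coordinates refer to the original (sequenced) read
# orientation, so for reverse-strand records the clip lengths are mirrored.

# Per-cigar summaries needed for coordinate bookkeeping. Treats '=' and 'X'
# as alignment matches. Returns a data.frame aligned with `cigar`.
.cigar_stats <- function(cigar) {
  opt <- GenomicAlignments::cigarOpTable(cigar)
  m <- opt[, "M"] + opt[, "="] + opt[, "X"]
  ins <- opt[, "I"]
  del <- opt[, "D"] + opt[, "N"]
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  lead <- mapply(function(o, l) {
    i <- 1L
    tot <- 0L
    while (i <= length(o) && o[i] %in% c("S", "H")) {
      tot <- tot + l[i]
      i <- i + 1L
    }
    tot
  }, ops, lens, USE.NAMES = FALSE)
  trail <- mapply(function(o, l) {
    i <- length(o)
    tot <- 0L
    while (i >= 1L && o[i] %in% c("S", "H")) {
      tot <- tot + l[i]
      i <- i - 1L
    }
    tot
  }, ops, lens, USE.NAMES = FALSE)
  data.frame(
    qlen = m + ins,                      # read bases consumed by the alignment
    rlen = m + del,                      # reference bases consumed
    read_len = m + ins + lead + trail,   # full read length implied by cigar
    lead_clip = lead, trail_clip = trail
  )
}

# Read-space interval of an alignment on the original read. `pos0` is the
# 0-based reference start.
.subaln_coords <- function(chrom, pos0, strand, cigar, mapq, read_id) {
  st <- .cigar_stats(cigar)
  fwd <- strand == "+"
  read_start <- ifelse(fwd, st$lead_clip, st$trail_clip)
  data.frame(
    read_id = read_id,
    chrom = chrom,
    ref_start = as.numeric(pos0),
    ref_end = as.numeric(pos0) + st$rlen,
    read_start = as.integer(read_start),
    read_end = as.integer(read_start + st$qlen),
    strand = strand,
    mapq = as.integer(mapq),
    stringsAsFactors = FALSE
  )
}

# Parse "chr,pos,strand,CIGAR,mapQ,NM;" SA tags into per-entry fields.
.parse_sa_tag <- function(sa, read_id) {
  entries <- strsplit(sa, ";", fixed = TRUE)
  n <- lengths(entries)
  fields <- strsplit(unlist(entries, use.names = FALSE), ",", fixed = TRUE)
  ok <- lengths(fields) == 6L
  fields <- fields[ok]
  if (!length(fields)) {
    return(NULL)
  }
  mat <- matrix(unlist(fields, use.names = FALSE), ncol = 6L, byrow = TRUE)
  data.frame(
    read_id = rep(rep(read_id, n), ok),
    chrom = mat[, 1L],
    pos0 = as.numeric(mat[, 2L]) - 1,
    strand = mat[, 3L],
    cigar = mat[, 4L],
    mapq = as.integer(mat[, 5L]),
    stringsAsFactors = FALSE
  )
}

#' Collect multi-sub-alignment reads from a BAM file
#'
#' Reads primary and supplementary records (secondary alignments are
#' ignored), merges in sub-alignments described only in SA tags, collapses
#' duplicates between the two sources, and retains the reads that have at
#' least two sub-alignments on the same chromosome -- the reads that can
#' carry an inversion signal. Uniquely aligned reads and reads whose
#' sub-alignments all map to different chromosomes are dropped.
#'
#' @param bam_file Path to a BAM file (indexed if `which` is used).
#' @param cfg A [scan_config()]; only `min_mapq` is applied at this stage.
#' @param which Optional [GenomicRanges::GRanges] restricting the scan.
#'
#' @return A data.frame of sub-alignments with columns `read_id`, `chrom`,
#'   `ref_start`, `ref_end` (0-based half-open reference coordinates),
#'   `read_start`, `read_end` (0-based half-open coordinates on the
#'   original read), `strand`, `mapq`, ordered by read and read-space
#'   position. One row per sub-alignment; group by `read_id` to recover the
#'   per-read sets.
#' @export
collect_subalignments <- function(bam_file, cfg = scan_config(), which = NULL) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE
  )
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar")
  param <- if (is.null(which)) {
    Rsamtools::ScanBamParam(flag = flag, what = what, tag = "SA")
  } else {
    Rsamtools::ScanBamParam(flag = flag, what = what, tag = "SA",
                            which = which)
  }
  res <- tryCatch(
    Rsamtools::scanBam(bam_file, param = param),
    error = function(e) {
      stop("failed to read BAM '", bam_file, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  chunks <- lapply(res, function(r) {
    data.frame(
      qname = r$qname, rname = as.character(r$rname),
      strand = as.character(r$strand), pos = r$pos, mapq = r$mapq,
      cigar = r$cigar, sa = if (is.null(r$tag$SA)) NA_character_ else r$tag$SA,
      stringsAsFactors = FALSE
    )
  })
  x <- do.call(rbind, chunks)
  if (!nrow(x)) {
    return(.empty_subalignments())
  }
  no_cigar <- is.na(x$cigar) | x$cigar == "*"
  if (any(no_cigar)) {
    warning(sum(no_cigar), " alignment record(s) without CIGAR skipped")
  }
  x <- x[!no_cigar, , drop = FALSE]
  rec <- .subaln_coords(
    chrom = x$rname,
    pos0 = x$pos - 1,
    strand = x$strand,
    cigar = x$cigar,
    mapq = x$mapq,
    read_id = x$qname
  )
  sa <- x$sa
  has_sa <- !is.na(sa) & nzchar(sa)
  if (any(has_sa)) {
    sa_fields <- .parse_sa_tag(sa[has_sa], rec$read_id[has_sa])
    if (!is.null(sa_fields)) {
      sa_rec <- .subaln_coords(
        chrom = sa_fields$chrom, pos0 = sa_fields$pos0,
        strand = sa_fields$strand, cigar = sa_fields$cigar,
        mapq = sa_fields$mapq, read_id = sa_fields$read_id
      )
      rec <- rbind(rec, sa_rec)
    }
  }
  rec <- rec[rec$mapq >= cfg$min_mapq | is.na(rec$mapq), , drop = FALSE]
  # collapse SA-tag entries duplicating supplementary records
  key <- paste(rec$read_id, rec$chrom, rec$ref_start, rec$strand, sep = "\r")
  rec <- rec[!duplicated(key), , drop = FALSE]
  # reads with >= 2 sub-alignments on one chromosome
  rc_key <- paste(rec$read_id, rec$chrom, sep = "\r")
  tab <- table(rc_key)
  multi_reads <- unique(rec$read_id[rc_key %in% names(tab)[tab >= 2L]])
  rec <- rec[rec$read_id %in% multi_reads, , drop = FALSE]
  rec <- rec[order(rec$read_id, rec$read_start, rec$read_end), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

.empty_subalignments <- function() {
  data.frame(
    read_id = character(), chrom = character(),
    ref_start = numeric(), ref_end = numeric(),
    read_start = integer(), read_end = integer(),
    strand = character(), mapq = integer(),
    stringsAsFactors = FALSE
  )
}

#' Filter the sub-alignments of one read
#'
#' Removes sub-alignments whose interval on the read is shorter than
#' `cfg$min_subalignment_len` or strictly contained in another
#' sub-alignment's read interval. Exactly equal read intervals are
#' collapsed to the one with the higher mapping quality (first encountered
#' on a tie). The result is sorted by left-most read coordinate. The
#' operation is idempotent.
#'
#' @param alns Data.frame of sub-alignments for a single read (as one group
#'   of [collect_subalignments()] output).
#' @param cfg A [scan_config()].
#' @return The surviving rows, sorted by `read_start`.
#' @export
filter_subalignments <- function(alns, cfg = scan_config()) {
  stopifnot(length(unique(alns$read_id)) <= 1L)
  alns <- alns[(alns$read_end - alns$read_start) >= cfg$min_subalignment_len, ,
               drop = FALSE]
  if (nrow(alns) <= 1L) {
    return(.sort_by_read_pos(alns))
  }
  # exactly equal read intervals: keep highest mapq, first on ties
  ord <- order(alns$read_start, alns$read_end, -alns$mapq)
  alns <- alns[ord, , drop = FALSE]
  dup <- duplicated(paste(alns$read_start, alns$read_end))
  alns <- alns[!dup, , drop = FALSE]
  # strict containment: with intervals sorted by (start asc, end desc), an
  # interval is a strict subset of an earlier one iff its end does not
  # exceed the running maximum of earlier ends
  ord <- order(alns$read_start, -alns$read_end)
  alns <- alns[ord, , drop = FALSE]
  n <- nrow(alns)
  prev_max <- c(-Inf, cummax(alns$read_end)[-n])
  alns <- alns[alns$read_end > prev_max, , drop = FALSE]
  .sort_by_read_pos(alns)
}

.sort_by_read_pos <- function(alns) {
  alns <- alns[order(alns$read_start, alns$read_end), , drop = FALSE]
  rownames(alns) <- NULL
  alns
}
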