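# Counting of reads that support the non-inverted (reference) allele.
#
# A read spanning an inversion breakpoint without a strand-switching split
# supports the reference allele there -- unless its alignment is merely
# forced through an inverted region, which inflates its local error rates.
# Alignments are therefore kept only when their substitution, insertion
# and deletion rates inside the inversion region stay below the
# genome-wide per-alignment mean plus one standard deviation.

#' Estimate the genome-wide alignment error profile
#'
#' Computes per-alignment substitution, insertion and deletion rates
#' (event bases divided by aligned match/mismatch bases) for the first
#' `min(n_max, all)` primary alignments in file order, and returns their
#' means and standard deviations. Substitutions are taken from MD tags
#' when present; otherwise the read sequences are layered onto the
#' reference (`ref_fasta` required).
#'
#' @param bam_file Path to a BAM file.
#' @param ref_fasta Optional path to an indexed reference FASTA, used only
#'   when alignments carry no MD tag.
#' @param n_max Maximum number of primary alignments used (default 10000).
#' @return An object of class `error_profile` with fields `mean_sub`,
#'   `mean_ins`, `mean_del`, `sd_sub`, `sd_ins`, `sd_del`,
#'   `n_alignments_used`.
#' @export
estimate_error_profile <- function(bam_file, ref_fasta = NULL,
                                   n_max = 10000L) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "cigar"), tag = "MD"
  )
  r <- Rsamtools::scanBam(bam_file, param = param)[[1L]]
  n <- length(r$pos)
  if (!n) {
    stop("no primary alignments in '", bam_file, "'")
  }
  use <- seq_len(min(n_max, n))
  cigar <- r$cigar[use]
  md <- r$tag$MD[use]
  opt <- GenomicAlignments::cigarOpTable(cigar)
  aligned <- opt[, "M"] + opt[, "="] + opt[, "X"]
  ins <- opt[, "I"]
  del <- opt[, "D"]
  if (!is.null(md) && !all(is.na(md))) {
    ok <- !is.na(md)
    subs <- rep(NA_real_, length(use))
    stripped <- gsub("\\^[A-Za-z]+", "", md[ok])
    subs[ok] <- nchar(gsub("[^A-Za-z]", "", stripped))
  } else {
    if (is.null(ref_fasta)) {
      stop("alignments carry no MD tag and no reference FASTA was supplied; ",
           "cannot compute substitution rates")
    }
    subs <- .mismatches_from_fasta(bam_file, ref_fasta, n_max)
  }
  keep <- aligned > 0 & !is.na(subs)
  rate_sub <- subs[keep] / aligned[keep]
  rate_ins <- ins[keep] / aligned[keep]
  rate_del <- del[keep] / aligned[keep]
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(
    list(
      mean_sub = mean(rate_sub), mean_ins = mean(rate_ins),
      mean_del = mean(rate_del),
      sd_sub = sd0(rate_sub), sd_ins = sd0(rate_ins), sd_del = sd0(rate_del),
      n_alignments_used = sum(keep)
    ),
    class = "error_profile"
  )
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    paste0("error profile over %d primary alignments\n",
           "  substitution: %.4f (sd %.4f)\n",
           "  insertion:    %.4f (sd %.4f)\n",
           "  deletion:     %.4f (sd %.4f)\n"),
    x$n_alignments_used, x$mean_sub, x$sd_sub, x$mean_ins, x$sd_ins,
    x$mean_del, x$sd_del
  ))
  invisible(x)
}

# Substitution counts via reference layering, for BAMs without MD tags.
.mismatches_from_fasta <- function(bam_file, ref_fasta, n_max) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "cigar", "seq")
  )
  r <- Rsamtools::scanBam(bam_file, param = param)[[1L]]
  use <- seq_len(min(n_max, length(r$pos)))
  cigar <- r$cigar[use]
  if (any(as.character(r$seq[use]) == "")) {
    stop("alignments carry neither MD tags nor sequences; ",
         "cannot compute substitution rates")
  }
  laid <- GenomicAlignments::sequenceLayer(r$seq[use], cigar)
  rlen <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  gr <- GenomicRanges::GRanges(
    as.character(r$rname)[use],
    IRanges::IRanges(start = r$pos[use], width = rlen)
  )
  refseq <- Rsamtools::scanFa(ref_fasta, gr)
  vapply(seq_along(use), function(i) {
    a <- charToRaw(toupper(as.character(laid[[i]])))
    b <- charToRaw(toupper(as.character(refseq[[i]])))
    sum(a != b & a != charToRaw("-") & a != charToRaw("N"))
  }, numeric(1))
}

# Decompose one alignment (CIGAR + MD + 0-based start) into
# reference-space events: aligned blocks, deletion blocks, insertion
# anchors with lengths, and mismatch positions. MD offsets count M and D
# operations, both of which consume reference 1:1, so an MD offset is a
# reference offset directly.
.alignment_events <- function(cigar, md, pos0) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  ref_consume <- ifelse(ops %in% c("M", "D", "N", "=", "X"), lens, 0L)
  off <- cumsum(c(0L, ref_consume))[seq_along(ops)]
  is_m <- ops %in% c("M", "=", "X")
  is_d <- ops %in% c("D", "N")
  is_i <- ops == "I"
  mism <- numeric(0)
  if (!is.null(md) && !is.na(md)) {
    toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]",
                                    md))[[1L]]
    is_num <- grepl("^[0-9]", toks)
    is_del <- startsWith(toks, "^")
    cons <- ifelse(is_num, suppressWarnings(as.numeric(toks)),
                   ifelse(is_del, nchar(toks) - 1L, 1L))
    toff <- cumsum(c(0, cons))[seq_along(toks)]
    mism <- pos0 + toff[!is_num & !is_del]
  }
  list(
    m_start = pos0 + off[is_m], m_end = pos0 + off[is_m] + lens[is_m],
    d_start = pos0 + off[is_d], d_end = pos0 + off[is_d] + lens[is_d],
    ins_pos = pos0 + off[is_i], ins_len = lens[is_i],
    mism = mism
  )
}

#' Error rates of one alignment inside an inversion region
#'
#' The inversion region of an alignment overlapping a call is
#' `(max(left breakpoint start, alignment start),
#'   min(right breakpoint end, alignment end))`; substitution, insertion
#' and deletion rates are computed from the CIGAR and MD tag over that
#' clipped region only, as event bases per aligned base. The insertion
#' rate may exceed 1 when a large insertion falls in a short region.
#'
#' @param cigar,md,pos0 The alignment's CIGAR string, MD tag and 0-based
#'   reference start.
#' @param region_start,region_end The call's outer breakpoint
#'   coordinates (0-based half-open); clipping to the alignment extent is
#'   done internally.
#' @return Named numeric vector `c(sub, ins, del)`, or `NULL` when the
#'   alignment has no aligned base in the clipped region.
#' @export
region_error_rates <- function(cigar, md, pos0, region_start, region_end) {
  ev <- .alignment_events(cigar, md, pos0)
  rs <- max(region_start, pos0)
  re <- min(region_end, pos0 + sum(ev$m_end - ev$m_start) +
              sum(ev$d_end - ev$d_start))
  if (re <= rs) {
    return(NULL)
  }
  clip <- function(s, e) sum(pmax(0, pmin(e, re) - pmax(s, rs)))
  aligned <- clip(ev$m_start, ev$m_end)
  if (aligned == 0) {
    return(NULL)
  }
  del <- clip(ev$d_start, ev$d_end)
  ins <- sum(ev$ins_len[ev$ins_pos >= rs & ev$ins_pos < re])
  subs <- sum(ev$mism >= rs & ev$mism < re)
  c(sub = subs / aligned, ins = ins / aligned, del = del / aligned)
}

#' Count reference-supporting reads for one inversion call
#'
#' A primary alignment supports the reference allele at a breakpoint when
#' it fully spans that breakpoint's uncertainty interval without a
#' strand-switching split (reads contributing inversion signals to the
#' call are excluded) and all three of its error rates inside the
#' inversion region are below the profile mean plus `k_sd` standard
#' deviations (mean plus a tiny epsilon when the standard deviation is
#' zero, as in error-free simulations). A read spanning both breakpoints
#' counts as one left and one right reference signal, i.e. contributes 2.
#'
#' @param call One-row call data.frame (from [cluster_signals()]).
#' @param bam_file Path to the indexed BAM file.
#' @param profile An [estimate_error_profile()] result.
#' @param exclude_reads Read ids that support the inversion at this call.
#' @param k_sd Multiplier on the standard deviation in the error-rate
#'   threshold (default 1).
#' @return The call row with `R_ref` filled in.
#' @export
count_reference_reads <- function(call, bam_file, profile,
                                  exclude_reads = character(),
                                  k_sd = 1) {
  stopifnot(nrow(call) == 1L)
  thr <- c(
    profile$mean_sub + if (profile$sd_sub > 0) k_sd * profile$sd_sub else 1e-9,
    profile$mean_ins + if (profile$sd_ins > 0) k_sd * profile$sd_ins else 1e-9,
    profile$mean_del + if (profile$sd_del > 0) k_sd * profile$sd_del else 1e-9
  )
  region <- GenomicRanges::GRanges(
    call$chrom,
    IRanges::IRanges(start = call$left_bp_start + 1,
                     end = max(call$right_bp_end, call$left_bp_start + 1))
  )
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "pos", "cigar"), tag = "MD", which = region
  )
  r <- Rsamtools::scanBam(bam_file, param = param)[[1L]]
  r_ref <- 0L
  if (length(r$pos)) {
    pos0 <- r$pos - 1
    end0 <- pos0 + GenomicAlignments::cigarWidthAlongReferenceSpace(r$cigar)
    spans_left <- pos0 < call$left_bp_start & end0 > call$left_bp_end
    spans_right <- pos0 < call$right_bp_start & end0 > call$right_bp_end
    cand <- which((spans_left | spans_right) &
                    !(r$qname %in% exclude_reads))
    for (i in cand) {
      rates <- region_error_rates(
        r$cigar[i], r$tag$MD[i], pos0[i],
        call$left_bp_start, call$right_bp_end
      )
      if (!is.null(rates) && all(rates < thr)) {
        r_ref <- r_ref + as.integer(spans_left[i]) + as.integer(spans_right[i])
      }
    }
  }
  call$R_ref <- r_ref
  call
}
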