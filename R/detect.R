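# End-to-end inversion detection pipeline.

#' Detect and genotype inversions in a BAM file
#'
#' Runs the full pipeline: sub-alignment collection and filtering, signal
#' extraction and sorting, inverted-repeat / distance binning, call
#' validation, error-profile estimation, reference-support counting and
#' binomial genotyping.
#'
#' @param bam_file Coordinate-sorted, indexed BAM with supplementary
#'   alignments (SA tags and/or supplementary records).
#' @param ir_db Optional inverted-repeat database: a path accepted by
#'   [read_ir_pairs()] or an equivalent data.frame.
#' @param scan A [scan_config()].
#' @param cluster A [cluster_config()].
#' @param geno A [genotyper_config()].
#' @param ref_fasta Optional reference FASTA, needed only when alignments
#'   carry no MD tags.
#' @return A call data.frame (one row per call, including rejected
#'   long-inversion calls flagged in `filter`) with genotype columns
#'   `genotype`, `Q`, `posterior_*`; the error profile is attached as
#'   attribute `"error_profile"`, the raw signals as `"signals"`.
#' @export
detect_inversions <- function(bam_file, ir_db = NULL,
                              scan = scan_config(),
                              cluster = cluster_config(),
                              geno = genotyper_config(),
                              ref_fasta = NULL) {
  if (is.character(ir_db)) {
    ir_db <- read_ir_pairs(ir_db)
  }
  signals <- scan_inversion_signals(bam_file, scan)
  clustered <- cluster_signals(signals, ir_db, cluster)
  calls <- clustered$calls
  if (nrow(calls)) {
    profile <- estimate_error_profile(bam_file, ref_fasta)
    rows <- vector("list", nrow(calls))
    for (i in seq_len(nrow(calls))) {
      rows[[i]] <- count_reference_reads(
        calls[i, , drop = FALSE], bam_file, profile,
        exclude_reads = clustered$bin_reads[[i]]
      )
    }
    calls <- as.data.frame(data.table::rbindlist(rows))
    gts <- lapply(seq_len(nrow(calls)), function(i) {
      genotype_call(calls$R_ref[i], calls$R_inv[i], geno)
    })
    calls$genotype <- vapply(gts, `[[`, "", "genotype")
    calls$Q <- vapply(gts, `[[`, numeric(1), "Q")
    post <- t(vapply(gts, `[[`, numeric(3), "posterior"))
    calls$posterior_refref <- post[, 1L]
    calls$posterior_refinv <- post[, 2L]
    calls$posterior_invinv <- post[, 3L]
    calls$filter <- ifelse(calls$long_flag, "LongInversion", "PASS")
  } else {
    profile <- NULL
    calls$genotype <- character(0)
    calls$Q <- numeric(0)
    calls$posterior_refref <- numeric(0)
    calls$posterior_refinv <- numeric(0)
    calls$posterior_invinv <- numeric(0)
    calls$filter <- character(0)
  }
  attr(calls, "error_profile") <- profile
  attr(calls, "signals") <- signals
  calls
}

#' Contig lengths from a BAM header
#'
#' @param bam_file BAM path.
#' @return Named integer vector of contig lengths.
#' @export
bam_contigs <- function(bam_file) {
  h <- Rsamtools::scanBamHeader(bam_file)[[1L]]$targets
  h
}
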