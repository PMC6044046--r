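#' Configuration for sub-alignment scanning
#'
#' Controls the filters applied to the sub-alignments of a multi-part read
#' before inversion signals are extracted.
#'
#' @param min_subalignment_len Minimum length (bp) of a sub-alignment's
#'   interval on the read; shorter sub-alignments are discarded. Default 500.
#' @param nahr_overlap_min Minimum overlap (bp) of two read-adjacent
#'   sub-alignment intervals on the read for the signal to be classified as
#'   mediated by an inverted repeat (NAHR). Default 500.
#' @param min_mapq Minimum mapping quality of a sub-alignment. Default 0
#'   (no MAPQ filter).
#'
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(min_subalignment_len = 500L,
                        nahr_overlap_min = 500L,
                        min_mapq = 0L) {
  stopifnot(min_subalignment_len >= 0, nahr_overlap_min >= 0, min_mapq >= 0)
  structure(
    list(
      min_subalignment_len = as.integer(min_subalignment_len),
      nahr_overlap_min = as.integer(nahr_overlap_min),
      min_mapq = as.integer(min_mapq)
    ),
    class = "scan_config"
  )
}

#' Configuration for signal clustering and call validation
#'
#' @param bin_distance Maximum distance X (bp) between a signal's breakpoint
#'   coordinates and a bin's running representative (or an inverted-repeat
#'   interval) for the signal to join that bin. Default 2000.
#' @param long_inversion Length L (bp) above which a call is annotated as a
#'   long inversion (FILTER `LongInversion`); such calls are considered
#'   unreliable but are still reported. Default 1e6.
#' @param min_support Minimum number of supporting breakpoint signals
#'   (R_inv) for a call to be emitted. Default 3.
#'
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(bin_distance = 2000L,
                           long_inversion = 1000000L,
                           min_support = 3L) {
  stopifnot(bin_distance > 0, long_inversion > 0, min_support > 0)
  structure(
    list(
      bin_distance = as.integer(bin_distance),
      long_inversion = as.numeric(long_inversion),
      min_support = as.integer(min_support)
    ),
    class = "cluster_config"
  )
}

#' Configuration for the binomial genotyper
#'
#' `eps1` is the probability that an inversion-supporting read is
#' misassigned as reference-supporting; `eps2` the converse. The prior is
#' the Hardy-Weinberg prior for a uniform allele prior: 0.25 / 0.5 / 0.25
#' for reference-homozygous, heterozygous and inversion-homozygous.
#'
#' @param eps1,eps2 Misassignment rates in `[0, 1)`. Defaults 0.01.
#' @param priors Named numeric vector of prior genotype probabilities for
#'   `refref`, `refinv`, `invinv`; must sum to 1.
#' @param max_quality Cap for the Phred genotype quality when the
#'   second-best posterior underflows. Default 1000.
#'
#' @return A list of class `genotyper_config`.
#' @export
genotyper_config <- function(eps1 = 0.01, eps2 = 0.01,
                             priors = c(refref = 0.25, refinv = 0.5,
                                        invinv = 0.25),
                             max_quality = 1000) {
  stopifnot(
    eps1 >= 0, eps1 < 1, eps2 >= 0, eps2 < 1,
    length(priors) == 3L,
    all(c("refref", "refinv", "invinv") %in% names(priors)),
    abs(sum(priors) - 1) < 1e-9,
    max_quality > 0
  )
  structure(
    list(
      eps1 = eps1, eps2 = eps2,
      priors = priors[c("refref", "refinv", "invinv")],
      max_quality = max_quality
    ),
    class = "genotyper_config"
  )
}
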