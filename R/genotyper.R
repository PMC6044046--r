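# Binomial posterior genotyping of an inversion from the counts of
# reference-supporting (R_ref) and inversion-supporting (R_inv) reads.
#
# With misassignment rates eps1 (inversion read recorded as reference
# support) and eps2 (the converse), the likelihood of the counts is
#
#   P(R_ref, R_inv | G) =  (1-eps1)^R_ref * eps2^R_inv          G = ref/ref
#                          ((1-eps1)/2 + eps2/2)^R_ref *
#                            (eps1/2 + (1-eps2)/2)^R_inv        G = ref/inv
#                          eps1^R_ref * (1-eps2)^R_inv          G = inv/inv
#
# and the posterior is proportional to likelihood times the
# Hardy-Weinberg prior (0.25, 0.5, 0.25). With eps1 = eps2 the
# heterozygous likelihood is exactly 0.5^(R_ref + R_inv).

.GENOTYPES <- c("refref", "refinv", "invinv")

#' Log-likelihood of read counts given a genotype
#'
#' @param r_ref,r_inv Non-negative counts of reference- and
#'   inversion-supporting reads.
#' @param genotype One of `"refref"`, `"refinv"`, `"invinv"`.
#' @param cfg A [genotyper_config()].
#' @param log Return the natural-log likelihood (default) or the
#'   likelihood itself.
#' @return A numeric scalar.
#' @export
genotype_likelihood <- function(r_ref, r_inv, genotype,
                                cfg = genotyper_config(), log = TRUE) {
  if (r_ref < 0 || r_inv < 0) {
    stop("read counts must be non-negative")
  }
  genotype <- match.arg(genotype, .GENOTYPES)
  p <- switch(genotype,
    refref = c(1 - cfg$eps1, cfg$eps2),
    refinv = c((1 - cfg$eps1) / 2 + cfg$eps2 / 2,
               cfg$eps1 / 2 + (1 - cfg$eps2) / 2),
    invinv = c(cfg$eps1, 1 - cfg$eps2)
  )
  # 0 * log(0) is an empty product, i.e. log-likelihood contribution 0
  ll <- sum(ifelse(c(r_ref, r_inv) > 0, c(r_ref, r_inv) * log(p), 0))
  if (log) ll else exp(ll)
}

#' Phred-scaled genotype quality from a posterior
#'
#' `Q = -10 log10(P_2nd / P_1st)`, the second-largest posterior
#' probability against the largest; 0 when the top two tie, capped at
#' `max_quality` when `P_2nd` underflows to zero.
#'
#' @param posterior Numeric 3-vector of genotype posterior probabilities,
#'   normalized to 1 (within 1e-6).
#' @param max_quality Cap (default 1000).
#' @return Non-negative numeric quality.
#' @export
phred_quality <- function(posterior, max_quality = 1000) {
  if (abs(sum(posterior) - 1) > 1e-6) {
    stop("posterior probabilities must sum to 1")
  }
  p <- sort(posterior, decreasing = TRUE)
  if (p[2L] <= 0) {
    return(max_quality)
  }
  min(max_quality, -10 * log10(p[2L] / p[1L]))
}

#' Genotype an inversion from its read counts
#'
#' Posterior over the three genotypes (likelihood times prior, normalized
#' explicitly), maximum-posterior genotype, and Phred genotype quality.
#' All computation is in log space, so large counts do not underflow.
#' With no data at all (`R_ref = R_inv = 0`) the genotype is reported as
#' missing (`"nocall"`) with quality 0 rather than as the prior argmax.
#' Posterior ties are broken in the order refref < refinv < invinv, with
#' the tie visible as `Q = 0`.
#'
#' @inheritParams genotype_likelihood
#' @return A list with `genotype` (one of `"refref"`, `"refinv"`,
#'   `"invinv"`, `"nocall"`), `posterior` (named 3-vector summing to 1)
#'   and `Q` (Phred quality).
#' @export
genotype_call <- function(r_ref, r_inv, cfg = genotyper_config()) {
  ll <- vapply(.GENOTYPES, function(g) {
    genotype_likelihood(r_ref, r_inv, g, cfg)
  }, numeric(1))
  lp <- ll + log(cfg$priors)
  lp <- lp - max(lp)
  posterior <- exp(lp) / sum(exp(lp))
  if (r_ref == 0 && r_inv == 0) {
    return(list(genotype = "nocall", posterior = posterior, Q = 0))
  }
  g <- .GENOTYPES[which.max(posterior)]
  list(
    genotype = g,
    posterior = posterior,
    Q = phred_quality(posterior, cfg$max_quality)
  )
}
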