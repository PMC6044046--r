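# Relationship between inverted-repeat length and the size of the
# inversion a repeat pair can mediate: ordinary least squares in
# log10-log10 space, prediction-interval filtering of repeat pairs, and
# merging of surviving pairs into candidate regions.

#' Fit the log-log regression of inversion size on inverted-repeat length
#'
#' Regresses `log10(distance between the repeats)` (the inversion size
#' without its flanking repeats) on `log10(mean repeat length)` by
#' ordinary least squares. When the two repeats of a pair differ in
#' length, their arithmetic mean is used before the log transform.
#'
#' @param ir_length Repeat lengths (bp), or a two-column matrix /
#'   data.frame of the two repeat lengths per pair.
#' @param distance Distance between the repeats (bp).
#' @return A list of class `loglog_fit` with `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope t-test), `residual_sd`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_loglog_regression <- function(ir_length, distance) {
  if (is.matrix(ir_length) || is.data.frame(ir_length)) {
    ir_length <- rowMeans(as.matrix(ir_length))
  }
  if (any(ir_length <= 0) || any(distance <= 0)) {
    stop("repeat lengths and distances must be positive")
  }
  n <- length(ir_length)
  if (n < 3L || length(distance) != n) {
    stop("need at least 3 complete (length, distance) pairs")
  }
  d <- data.frame(x = log10(ir_length), y = log10(distance))
  fit <- stats::lm(y ~ x, data = d)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = sm$r.squared,
      p_value = unname(sm$coefficients[2L, 4L]),
      residual_sd = sm$sigma,
      n = n,
      fit = fit
    ),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "log10(distance) = %.3f * log10(IR length) + %.3f  (n = %d)\n",
    x$slope, x$intercept, x$n
  ))
  cat(sprintf("  R^2 %.3f, slope p-value %.3g, residual sd %.3f\n",
              x$r_squared, x$p_value, x$residual_sd))
  invisible(x)
}

#' Filter repeat pairs by the regression prediction interval
#'
#' Keeps the pairs whose log10 distance lies inside the two-sided
#' `level` prediction interval of the fitted regression at their log10
#' repeat length (standard OLS prediction interval with the t(n-2)
#' quantile). Survivor sets are nested in `level`.
#'
#' @param ir_length,distance As in [fit_loglog_regression()].
#' @param model A `loglog_fit`.
#' @param level Prediction-interval coverage (default 0.90).
#' @return Logical vector: `TRUE` for surviving pairs.
#' @export
prediction_interval_filter <- function(ir_length, distance, model,
                                       level = 0.90) {
  if (is.matrix(ir_length) || is.data.frame(ir_length)) {
    ir_length <- rowMeans(as.matrix(ir_length))
  }
  pi <- stats::predict(model$fit,
                       newdata = data.frame(x = log10(ir_length)),
                       interval = "prediction", level = level)
  y <- log10(distance)
  y >= pi[, "lwr"] & y <= pi[, "upr"]
}

#' Merge genomic intervals into non-overlapping regions
#'
#' Sorts and unions overlapping intervals; book-ended intervals
#' (distance 0) are merged, as in the usual BED merge convention. The
#' operation is idempotent and preserves the covered bases.
#'
#' @param regions Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return A data.frame of sorted, non-overlapping merged regions.
#' @export
merge_regions <- function(regions) {
  if (!nrow(regions)) {
    return(regions)
  }
  if (any(regions$end <= regions$start)) {
    stop("malformed interval: end must exceed start")
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1, regions$end)
  ))
  gr <- GenomicRanges::sort(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  )
}
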