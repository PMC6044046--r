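# Scoring of inversion call sets against a simulated truth set by
# reciprocal interval overlap.

#' Benchmark inversion calls against a truth set
#'
#' A prediction is a true positive when its interval and a truth interval
#' overlap reciprocally by at least `min_overlap` (each interval covered
#' by at least that fraction of the other). Matching is greedy by
#' decreasing overlap and one-to-one: each truth record matches at most
#' one prediction. Reported are the positive predictive value
#' `PPV = TP / (TP + FP)` (`NA` when there are no predictions),
#' sensitivity `S = TP / n_truth`, and genotype consistency `GC` (the
#' fraction of true positives whose predicted genotype equals the
#' simulated one), overall and per truth mechanism.
#'
#' @param calls Call data.frame with `chrom`, `start`, `end` and
#'   optionally `genotype`.
#' @param truth Truth data.frame with `chrom`, `start`, `end`,
#'   `genotype`, and optionally `mechanism`.
#' @param min_overlap Reciprocal overlap fraction (default 0.9).
#' @return A list of class `benchmark_result` with `TP`, `FP`, `FN`,
#'   `PPV`, `S`, `GC`, `GC_by_mechanism`, and `matches` (data.frame of
#'   matched call/truth row indices with their reciprocal overlap).
#' @export
benchmark_calls <- function(calls, truth, min_overlap = 0.9) {
  n_pred <- nrow(calls)
  n_truth <- nrow(truth)
  matches <- data.frame(call = integer(), truth = integer(),
                        overlap = numeric())
  if (n_pred && n_truth) {
    pred_gr <- GenomicRanges::GRanges(
      calls$chrom, IRanges::IRanges(calls$start + 1, calls$end)
    )
    truth_gr <- GenomicRanges::GRanges(
      truth$chrom, IRanges::IRanges(truth$start + 1, truth$end)
    )
    hits <- GenomicRanges::findOverlaps(pred_gr, truth_gr)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      inter <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(pred_gr)[qi], IRanges::ranges(truth_gr)[si]
      ))
      rec <- pmin(inter / IRanges::width(pred_gr)[qi],
                  inter / IRanges::width(truth_gr)[si])
      ok <- rec >= min_overlap
      qi <- qi[ok]
      si <- si[ok]
      rec <- rec[ok]
      o <- order(-rec)
      used_p <- logical(n_pred)
      used_t <- logical(n_truth)
      for (k in o) {
        if (!used_p[qi[k]] && !used_t[si[k]]) {
          used_p[qi[k]] <- TRUE
          used_t[si[k]] <- TRUE
          matches <- rbind(matches, data.frame(
            call = qi[k], truth = si[k], overlap = rec[k]
          ))
        }
      }
    }
  }
  tp <- nrow(matches)
  fp <- n_pred - tp
  fn <- n_truth - tp
  gc_flags <- if (tp && "genotype" %in% names(calls)) {
    calls$genotype[matches$call] == truth$genotype[matches$truth]
  } else {
    logical(0)
  }
  gc_by_mech <- NULL
  if (tp && "mechanism" %in% names(truth) && length(gc_flags)) {
    mech <- truth$mechanism[matches$truth]
    gc_by_mech <- vapply(split(gc_flags, mech), mean, numeric(1))
  }
  structure(
    list(
      TP = tp, FP = fp, FN = fn,
      PPV = if (n_pred) tp / n_pred else NA_real_,
      S = if (n_truth) tp / n_truth else NA_real_,
      GC = if (length(gc_flags)) mean(gc_flags) else NA_real_,
      GC_by_mechanism = gc_by_mech,
      matches = matches,
      min_overlap = min_overlap
    ),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "benchmark at reciprocal overlap >= %.2f\n  TP %d  FP %d  FN %d\n",
    x$min_overlap, x$TP, x$FP, x$FN
  ))
  cat(sprintf("  PPV %.3f  sensitivity %.3f  genotype consistency %.3f\n",
              x$PPV, x$S, x$GC))
  if (!is.null(x$GC_by_mechanism)) {
    cat("  GC by mechanism:",
        paste(names(x$GC_by_mechanism),
              sprintf("%.3f", x$GC_by_mechanism), collapse = "  "), "\n")
  }
  invisible(x)
}
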