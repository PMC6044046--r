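# Merging of sorted inversion signals into inversion calls.
#
# Two binning passes: signals matching a known inverted-repeat pair are
# grouped per repeat (and removed), remaining signals are grouped by
# breakpoint distance. A bin becomes a call only if it is supported on
# both strands, at both breakpoints and by enough signals in total.

#' Read an inverted-repeat pair database
#'
#' Tab-delimited, one pair per line:
#' `chrom  left_start  left_end  right_start  right_end  [identity]`,
#' 0-based half-open coordinates, repeats ordered and non-overlapping
#' (`left_end <= right_start`). Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per repeat pair.
#' @export
read_ir_pairs <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) {
    return(data.frame(chrom = character(), left_start = numeric(),
                      left_end = numeric(), right_start = numeric(),
                      right_end = numeric(), identity = numeric()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 5L)
  if (length(bad)) {
    stop("malformed inverted-repeat record at line ", keep[bad[1L]],
         ": expected at least 5 tab-separated fields")
  }
  mat <- t(vapply(fields, function(f) {
    suppressWarnings(as.numeric(f[2:5]))
  }, numeric(4)))
  if (anyNA(mat)) {
    stop("malformed inverted-repeat record at line ",
         keep[which(apply(is.na(mat), 1L, any))[1L]],
         ": non-numeric coordinate")
  }
  ir <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    left_start = mat[, 1L], left_end = mat[, 2L],
    right_start = mat[, 3L], right_end = mat[, 4L],
    identity = vapply(fields, function(f) {
      if (length(f) >= 6L) as.numeric(f[6L]) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  bad <- which(ir$left_end <= ir$left_start | ir$right_end <= ir$right_start |
                 ir$left_end > ir$right_start)
  if (length(bad)) {
    stop("malformed inverted-repeat record at line ", keep[bad[1L]],
         ": repeats must be non-empty, ordered and non-overlapping")
  }
  ir
}

# distance from point x to interval [a, b]
.point_interval_dist <- function(x, a, b) {
  pmax(0, a - x, x - b)
}

#' Bin signals around known inverted-repeat pairs
#'
#' A signal joins an inverted-repeat bin when its left breakpoint
#' coordinate lies within `cfg$bin_distance` bp of the pair's left repeat
#' interval and its right breakpoint within the same distance of the right
#' repeat interval. Binned signals are deleted from the working set; each
#' signal is assigned to at most one pair (the one with the smallest total
#' breakpoint-to-repeat distance).
#'
#' @param signals Sorted signal data.frame.
#' @param ir_db Data.frame from [read_ir_pairs()].
#' @param cfg A [cluster_config()].
#' @return A list with `bins` (a list, one signal data.frame per matched
#'   repeat pair, named by `ir_db` row index) and `leftover` (unmatched
#'   signals, for distance binning).
#' @export
bin_signals_with_ir <- function(signals, ir_db, cfg = cluster_config()) {
  if (is.null(ir_db) || !nrow(ir_db) || !nrow(signals)) {
    return(list(bins = list(), leftover = signals))
  }
  X <- cfg$bin_distance
  n <- nrow(signals)
  best_ir <- rep(NA_integer_, n)
  best_d <- rep(Inf, n)
  for (k in seq_len(nrow(ir_db))) {
    same <- signals$chrom == ir_db$chrom[k]
    dl <- .point_interval_dist(signals$ref_start, ir_db$left_start[k],
                               ir_db$left_end[k])
    dr <- .point_interval_dist(signals$ref_end, ir_db$right_start[k],
                               ir_db$right_end[k])
    d <- ifelse(same & dl <= X & dr <= X, dl + dr, Inf)
    upd <- d < best_d
    best_ir[upd] <- k
    best_d[upd] <- d[upd]
  }
  matched <- !is.na(best_ir)
  bins <- split(signals[matched, , drop = FALSE], best_ir[matched])
  list(bins = bins, leftover = signals[!matched, , drop = FALSE])
}

#' Bin signals by breakpoint distance
#'
#' Groups signals on the same chromosome whose breakpoint start and end
#' coordinates are both less than `cfg$bin_distance` bp from the bin's
#' running representative (the mean of the member starts and ends, updated
#' as members join). Input must be sorted by `(chrom, ref_start)`; the
#' grouping is then deterministic. When several open bins qualify, the
#' signal joins the closest (smallest summed coordinate distance).
#'
#' @inheritParams bin_signals_with_ir
#' @return A list of signal data.frames, one per bin.
#' @export
bin_signals_by_distance <- function(signals, cfg = cluster_config()) {
  if (!nrow(signals)) {
    return(list())
  }
  X <- cfg$bin_distance
  out <- list()
  for (chr in unique(signals$chrom)) {
    s <- signals[signals$chrom == chr, , drop = FALSE]
    ns <- nrow(s)
    mean_start <- numeric(0)
    mean_end <- numeric(0)
    size <- integer(0)
    assign <- integer(ns)
    for (i in seq_len(ns)) {
      ds <- abs(s$ref_start[i] - mean_start)
      de <- abs(s$ref_end[i] - mean_end)
      cand <- which(ds < X & de < X)
      if (length(cand)) {
        b <- cand[which.min(ds[cand] + de[cand])]
        mean_start[b] <- (mean_start[b] * size[b] + s$ref_start[i]) /
          (size[b] + 1L)
        mean_end[b] <- (mean_end[b] * size[b] + s$ref_end[i]) / (size[b] + 1L)
        size[b] <- size[b] + 1L
      } else {
        b <- length(size) + 1L
        mean_start[b] <- s$ref_start[i]
        mean_end[b] <- s$ref_end[i]
        size[b] <- 1L
      }
      assign[i] <- b
    }
    out <- c(out, split(s, assign))
  }
  unname(out)
}

#' Validate a signal bin and form an inversion call
#'
#' A bin is emitted as a call only when it contains supporting signals on
#' both the forward and reverse strand, at both the left and the right
#' breakpoint, and at least `cfg$min_support` signals in total. The number
#' of inversion-supporting reads `R_inv` is the number of breakpoint
#' signals: a read whose sub-alignments span both breakpoints contributes
#' one left and one right signal, i.e. two. Call coordinates are the means
#' of the member signals' left and right breakpoint coordinates;
#' breakpoint intervals are their min/max. A bin with any NAHR-classified
#' member is an NAHR call (alignment noise can push an inverted-repeat
#' overlap below threshold in individual reads), reporting the largest
#' observed repeat overlap.
#'
#' @param bin Data.frame of signals in one bin.
#' @param cfg A [cluster_config()].
#' @return A one-row call data.frame, or `NULL` when validation rejects
#'   the bin.
#' @export
validate_and_call <- function(bin, cfg = cluster_config()) {
  stopifnot(nrow(bin) >= 1L)
  n_left <- sum(bin$side == "left")
  n_right <- sum(bin$side == "right")
  n_fwd <- sum(bin$strand == "+")
  n_rev <- sum(bin$strand == "-")
  r_inv <- nrow(bin)
  if (n_left < 1L || n_right < 1L || n_fwd < 1L || n_rev < 1L ||
      r_inv < cfg$min_support) {
    return(NULL)
  }
  start <- round(mean(bin$ref_start))
  end <- round(mean(bin$ref_end))
  data.frame(
    chrom = bin$chrom[1L],
    start = start,
    end = end,
    left_bp_start = min(bin$ref_start),
    left_bp_end = max(bin$ref_start),
    right_bp_start = min(bin$ref_end),
    right_bp_end = max(bin$ref_end),
    mechanism = if (any(bin$mechanism == "NAHR")) "NAHR" else "NHEJ",
    ir_overlap = max(bin$ir_overlap),
    R_inv = r_inv,
    R_ref = NA_integer_,
    n_left = n_left, n_right = n_right, n_fwd = n_fwd, n_rev = n_rev,
    long_flag = (end - start) > cfg$long_inversion,
    stringsAsFactors = FALSE
  )
}

#' Cluster inversion signals into calls
#'
#' Runs the inverted-repeat binning pass (when `ir_db` is given), then the
#' distance binning pass on the leftover signals, and validates every bin.
#' Every input signal lands in exactly one bin.
#'
#' @inheritParams bin_signals_with_ir
#' @return A list with `calls` (data.frame, one row per validated call,
#'   with an `ir_id` column referencing `ir_db` rows or `NA`), and
#'   `bin_reads` (list of the supporting `read_id`s per call, used when
#'   counting reference-supporting reads).
#' @export
cluster_signals <- function(signals, ir_db = NULL, cfg = cluster_config()) {
  irres <- bin_signals_with_ir(signals, ir_db, cfg)
  bins <- c(irres$bins, bin_signals_by_distance(irres$leftover, cfg))
  ir_ids <- c(as.integer(names(irres$bins)),
              rep(NA_integer_, length(bins) - length(irres$bins)))
  calls <- vector("list", length(bins))
  keep <- logical(length(bins))
  for (k in seq_along(bins)) {
    cl <- validate_and_call(bins[[k]], cfg)
    if (!is.null(cl)) {
      cl$ir_id <- ir_ids[k]
      calls[[k]] <- cl
      keep[k] <- TRUE
    }
  }
  calls <- calls[keep]
  bin_reads <- lapply(bins[keep], function(b) unique(b$read_id))
  calls <- if (length(calls)) {
    as.data.frame(data.table::rbindlist(calls))
  } else {
    .empty_calls()
  }
  ord <- order(calls$chrom, calls$start)
  list(calls = calls[ord, , drop = FALSE], bin_reads = bin_reads[ord])
}

.empty_calls <- function() {
  data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    left_bp_start = numeric(), left_bp_end = numeric(),
    right_bp_start = numeric(), right_bp_end = numeric(),
    mechanism = character(), ir_overlap = numeric(),
    R_inv = integer(), R_ref = integer(),
    n_left = integer(), n_right = integer(),
    n_fwd = integer(), n_rev = integer(),
    long_flag = logical(), ir_id = integer(),
    stringsAsFactors = FALSE
  )
}
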