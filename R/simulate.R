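# Hermetic diploid inversion simulator.
#
# Generates a random reference carrying planted inverted-repeat (IR)
# pairs, a truth set of NAHR inversions (between the repeats of an IR
# pair) and NHEJ inversions (blunt breakpoints), a diploid pair of
# haplotypes, nanopore-like reads (exponential lengths, per-base
# substitution/insertion/deletion errors), and the split alignments such
# reads produce across inversion breakpoints. The aligner is idealized:
# each read's sub-alignments are derived from its known origin, which is
# exactly the geometry a correct aligner would recover. At an NAHR
# junction the reverse sub-alignment is extended through the repeat (the
# repeat copy in the read aligns to both repeats), so the adjacent pair
# overlaps on the read by about the repeat length.

#' Simulation configuration
#'
#' Defaults describe the desk-scale study: a 5 Mb diploid reference with
#' 10 NAHR inversions (planted IRs of 500-3000 bp; distance between the
#' repeats log-uniform at 12-30 times the repeat length, matching the
#' empirical near-linear IR-length/inversion-size relationship), 5 short
#' (1-4 kb) and 5 long (4 kb-1 Mb) NHEJ inversions, reads of exponential
#' length (mean 9 kb, minimum 200 bp) at 20-fold diploid coverage with
#' substitution/insertion/deletion rates 5.1/4.9/7.8%.
#'
#' @param ref_length Reference length in bp.
#' @param n_nahr,n_nhej_short,n_nhej_long Inversion counts per class.
#' @param ir_length_range Planted IR length range (bp), min 500.
#' @param ir_spacing_factor Range of the distance-between-repeats to
#'   IR-length ratio (sampled log-uniformly).
#' @param ir_divergence Fraction of diverged bases between the two repeat
#'   copies (identity = 1 - divergence). Default 0.
#' @param nhej_short_range,nhej_long_range NHEJ inversion size ranges
#'   (bp); short uniform, long log-uniform.
#' @param mean_read_len,min_read_len Read length distribution (bp).
#' @param coverage Diploid sequencing depth (total bases =
#'   `coverage * ref_length`).
#' @param err_sub,err_ins,err_del Per-aligned-base event rates.
#' @param het_prob Probability that an inversion is heterozygous.
#' @param min_gap Minimum distance between inversion footprints (bp).
#' @param edge_margin Inversion-free margin at the reference ends (bp).
#' @param chrom Contig name.
#' @param seed Optional RNG seed applied by [simulate_inversion_dataset()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ref_length = 5e6,
                       n_nahr = 10L, n_nhej_short = 5L, n_nhej_long = 5L,
                       ir_length_range = c(500, 3000),
                       ir_spacing_factor = c(12, 30),
                       ir_divergence = 0,
                       nhej_short_range = c(1000, 4000),
                       nhej_long_range = c(4000, 1e6),
                       mean_read_len = 9000, min_read_len = 200,
                       coverage = 20,
                       err_sub = 0.051, err_ins = 0.049, err_del = 0.078,
                       het_prob = 0.5,
                       min_gap = 25000, edge_margin = 50000,
                       chrom = "sim1", seed = NULL) {
  stopifnot(
    ref_length > 0, ir_length_range[1] >= 1, ir_spacing_factor[1] >= 1,
    err_sub >= 0, err_sub < 1, err_ins >= 0, err_ins < 1,
    err_del >= 0, err_del < 1, ir_divergence >= 0, ir_divergence < 1,
    mean_read_len > min_read_len, coverage > 0
  )
  structure(as.list(environment()), class = "sim_config")
}

# Non-overlapping placement of inversion loci. NAHR footprints include the
# flanking repeats. Returns the truth table plus the IR pair table.
.place_loci <- function(cfg) {
  ir_len <- round(stats::runif(cfg$n_nahr, cfg$ir_length_range[1],
                               cfg$ir_length_range[2]))
  spacing <- exp(stats::runif(cfg$n_nahr, log(cfg$ir_spacing_factor[1]),
                              log(cfg$ir_spacing_factor[2])))
  nahr_size <- round(ir_len * spacing)
  short_size <- round(stats::runif(cfg$n_nhej_short, cfg$nhej_short_range[1],
                                   cfg$nhej_short_range[2]))
  long_size <- round(exp(stats::runif(cfg$n_nhej_long,
                                      log(cfg$nhej_long_range[1]),
                                      log(cfg$nhej_long_range[2]))))
  loci <- data.frame(
    mechanism = rep(c("NAHR", "NHEJ", "NHEJ"),
                    c(cfg$n_nahr, cfg$n_nhej_short, cfg$n_nhej_long)),
    size = c(nahr_size, short_size, long_size),
    ir_len = c(ir_len, rep(0L, cfg$n_nhej_short + cfg$n_nhej_long))
  )
  loci$footprint <- loci$size + 2 * loci$ir_len
  lo_lim <- cfg$edge_margin
  hi_lim <- cfg$ref_length - cfg$edge_margin
  if (sum(loci$footprint + cfg$min_gap) > (hi_lim - lo_lim)) {
    stop("infeasible packing: ", sum(loci$footprint), " bp of inversions ",
         "requested in ", hi_lim - lo_lim, " bp of usable reference")
  }
  ord <- order(-loci$footprint)  # place large loci first
  placed_s <- numeric(0)
  placed_e <- numeric(0)
  pos <- numeric(nrow(loci))
  for (i in ord) {
    w <- loci$footprint[i]
    ok <- FALSE
    for (try in seq_len(2000L)) {
      p <- round(stats::runif(1, lo_lim, hi_lim - w))
      if (!any(p - cfg$min_gap < placed_e & p + w + cfg$min_gap > placed_s)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("infeasible packing: could not place a ", w, " bp locus after ",
           "2000 attempts; reduce counts or sizes")
    }
    placed_s <- c(placed_s, p)
    placed_e <- c(placed_e, p + w)
    pos[i] <- p
  }
  if (!nrow(loci)) {
    return(data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      mechanism = character(), ir_len = numeric(),
      genotype = character(), het_hap = integer(),
      stringsAsFactors = FALSE
    ))
  }
  # truth interval is the inverted segment between the repeats
  truth <- data.frame(
    chrom = cfg$chrom,
    start = pos + loci$ir_len,
    end = pos + loci$ir_len + loci$size,
    mechanism = loci$mechanism,
    ir_len = loci$ir_len,
    genotype = ifelse(stats::runif(nrow(loci)) < cfg$het_prob,
                      "refinv", "invinv"),
    stringsAsFactors = FALSE
  )
  truth$het_hap <- sample(1:2, nrow(truth), replace = TRUE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  truth
}

#' Simulate a reference genome with planted inverted repeats and a truth
#' set of inversions
#'
#' The right repeat of each planted pair is the reverse complement of the
#' left (with `ir_divergence` mutated positions); repeats immediately
#' flank the NAHR truth interval, so inverting the segment between them
#' produces a haplotype in which both repeats are conserved -- the NAHR
#' breakpoint ambiguity.
#'
#' @param cfg A [sim_config()].
#' @return A list with `reference` (a [Biostrings::DNAString]),
#'   `ir_pairs` (data.frame in [read_ir_pairs()] layout), and `truth`
#'   (data.frame with `chrom`, `start`, `end`, `mechanism`, `ir_len`,
#'   `genotype`, `het_hap`).
#' @export
simulate_reference_with_irs <- function(cfg = sim_config()) {
  truth <- .place_loci(cfg)
  ref <- Biostrings::DNAString(paste(
    sample(c("A", "C", "G", "T"), cfg$ref_length, replace = TRUE),
    collapse = ""
  ))
  nahr <- truth[truth$mechanism == "NAHR", , drop = FALSE]
  ir <- NULL
  if (nrow(nahr)) {
    left <- IRanges::IRanges(start = nahr$start - nahr$ir_len + 1,
                             width = nahr$ir_len)
    rc <- Biostrings::reverseComplement(Biostrings::extractAt(ref, left))
    if (cfg$ir_divergence > 0) {
      rc <- Biostrings::DNAStringSet(vapply(seq_along(rc), function(i) {
        s <- strsplit(as.character(rc[[i]]), "")[[1L]]
        k <- max(0L, round(cfg$ir_divergence * length(s)))
        if (k > 0) {
          at <- sample.int(length(s), k)
          s[at] <- vapply(s[at], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, "")
        }
        paste(s, collapse = "")
      }, ""))
    }
    right <- IRanges::IRanges(start = nahr$end + 1, width = nahr$ir_len)
    ref <- Biostrings::replaceAt(ref, right, rc)
    ir <- data.frame(
      chrom = nahr$chrom,
      left_start = nahr$start - nahr$ir_len,
      left_end = nahr$start,
      right_start = nahr$end,
      right_end = nahr$end + nahr$ir_len,
      identity = 1 - cfg$ir_divergence,
      stringsAsFactors = FALSE
    )
  } else {
    ir <- data.frame(chrom = character(), left_start = numeric(),
                     left_end = numeric(), right_start = numeric(),
                     right_end = numeric(), identity = numeric())
  }
  list(reference = ref, ir_pairs = ir, truth = truth)
}

#' Apply inversions to a reference, producing a diploid haplotype pair
#'
#' Each truth interval is reverse-complemented in one haplotype
#' (heterozygous; which one is given by `truth$het_hap`, default 1) or in
#' both (homozygous). Haplotype lengths are conserved, and applying the
#' same inversion twice restores the original sequence.
#'
#' @param reference A [Biostrings::DNAString].
#' @param truth Truth data.frame (see [simulate_reference_with_irs()]);
#'   intervals must not overlap.
#' @return A [Biostrings::DNAStringSet] of the two haplotypes.
#' @export
apply_inversions <- function(reference, truth) {
  if (nrow(truth) > 1L) {
    o <- order(truth$start)
    if (any(truth$end[o][-nrow(truth)] > truth$start[o][-1L])) {
      stop("truth intervals overlap")
    }
  }
  het_hap <- if ("het_hap" %in% names(truth)) truth$het_hap else 1L
  haps <- lapply(1:2, function(h) {
    on_h <- truth$genotype == "invinv" |
      (truth$genotype == "refinv" & het_hap == h)
    iv <- truth[on_h, , drop = FALSE]
    if (!nrow(iv)) {
      return(reference)
    }
    at <- IRanges::IRanges(start = iv$start + 1, end = iv$end)
    Biostrings::replaceAt(
      reference, at,
      Biostrings::reverseComplement(Biostrings::extractAt(reference, at))
    )
  })
  out <- Biostrings::DNAStringSet(haps)
  names(out) <- c("hap1", "hap2")
  out
}

#' Sample long reads from a diploid genome
#'
#' Read lengths are exponential with mean `cfg$mean_read_len`, truncated
#' below at `cfg$min_read_len`; reads are drawn from both haplotypes and
#' both strands until the total sampled bases reach
#' `coverage * ref_length`. Per-base errors follow the configured rates:
#' each template base is deleted with probability
#' `err_del / (1 + err_del)` (so deleted bases per aligned base average
#' `err_del`), surviving bases are substituted with probability
#' `err_sub`, and a 1-base insertion follows a surviving base with
#' probability `err_ins`.
#'
#' @param hap_len Haplotype length in bp (inversions conserve length, so
#'   this is the reference length).
#' @param cfg A [sim_config()].
#' @return A list with `reads` (data.frame: `read_id`, `hap`, `start`,
#'   `end` 0-based half-open template coordinates, `strand`, `length`)
#'   and `events` (per-read list of integer vectors `sub`, `ins`, `del`
#'   of 1-based positions within the template interval; `ins` positions
#'   are anchors, the extra base following them).
#' @export
sample_reads <- function(hap_len, cfg = sim_config()) {
  total <- cfg$coverage * cfg$ref_length
  n_guess <- ceiling(total / cfg$mean_read_len * 1.3)
  lens <- round(cfg$min_read_len +
                  stats::rexp(n_guess, 1 / (cfg$mean_read_len -
                                              cfg$min_read_len)))
  lens <- pmin(lens, hap_len)
  n <- which(cumsum(lens) >= total)
  n <- if (length(n)) n[1L] else n_guess
  lens <- lens[seq_len(n)]
  reads <- data.frame(
    read_id = sprintf("read%06d", seq_len(n)),
    hap = sample(1:2, n, replace = TRUE),
    start = floor(stats::runif(n, 0, hap_len - lens + 1)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    length = as.integer(lens),
    stringsAsFactors = FALSE
  )
  reads$end <- reads$start + reads$length
  q_del <- cfg$err_del / (1 + cfg$err_del)
  k_del <- stats::rbinom(n, lens, q_del)
  k_sub <- stats::rbinom(n, lens, cfg$err_sub)
  k_ins <- stats::rbinom(n, lens, cfg$err_ins)
  events <- lapply(seq_len(n), function(i) {
    del <- sort(sample.int(lens[i], k_del[i]))
    sub <- sort(setdiff(sample.int(lens[i], k_sub[i]), del))
    ins <- sort(setdiff(sample.int(lens[i], k_ins[i]), del))
    list(sub = sub, ins = ins, del = del)
  })
  list(reads = reads, events = events)
}

# Materialize the sequence of one read (as sequenced) from its template
# interval, events and sequencing strand.
.materialize_read <- function(hapseq_str, start0, len, ev, strand) {
  chars <- strsplit(substring(hapseq_str, start0 + 1, start0 + len),
                    "")[[1L]]
  bases <- c("A", "C", "G", "T")
  if (length(ev$sub)) {
    chars[ev$sub] <- vapply(chars[ev$sub], function(b) {
      sample(setdiff(bases, b), 1L)
    }, "")
  }
  # per template base: kept base (or "") followed by an inserted base
  piece <- chars
  if (length(ev$del)) {
    piece[ev$del] <- ""
  }
  if (length(ev$ins)) {
    piece[ev$ins] <- paste0(piece[ev$ins],
                            sample(bases, length(ev$ins), replace = TRUE))
  }
  seq_out <- paste(piece, collapse = "")
  if (strand == "-") {
    seq_out <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq_out))
    )
  }
  seq_out
}

#' Materialize read sequences
#'
#' Applies each read's error events to its template and returns the reads
#' as sequenced (reverse-complemented for minus-strand reads). With all
#' error rates zero, reads are exact substrings of their haplotype.
#'
#' @param sampled A [sample_reads()] result.
#' @param haplotypes [Biostrings::DNAStringSet] from [apply_inversions()].
#' @return A named [Biostrings::DNAStringSet].
#' @export
materialize_reads <- function(sampled, haplotypes) {
  hap_str <- as.character(haplotypes)
  seqs <- vapply(seq_len(nrow(sampled$reads)), function(i) {
    r <- sampled$reads[i, ]
    .materialize_read(hap_str[[r$hap]], r$start, r$length,
                      sampled$events[[i]], r$strand)
  }, "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sampled$reads$read_id
  out
}

#' Write sampled reads as FASTQ
#'
#' Adapter for running an external aligner on the simulated reads.
#'
#' @inheritParams materialize_reads
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(sampled, haplotypes, path) {
  seqs <- materialize_reads(sampled, haplotypes)
  qual <- vapply(Biostrings::width(seqs), function(w) {
    paste(rep("I", w), collapse = "")
  }, "")
  writeLines(
    as.vector(rbind(paste0("@", names(seqs)), as.character(seqs),
                    "+", qual)),
    path
  )
  invisible(path)
}
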