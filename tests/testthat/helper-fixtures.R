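# Shared fixtures, built in code once per test session.

.fixture_env <- new.env(parent = emptyenv())

# A modest simulated dataset reused across test files: 1.2 Mb reference,
# 3 NAHR + 4 NHEJ inversions, 20x coverage of 6 kb reads at the standard
# nanopore-like error rates.
fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(
      ref_length = 1.2e6, n_nahr = 3, n_nhej_short = 2, n_nhej_long = 2,
      ir_length_range = c(500, 1500), nhej_long_range = c(4000, 30000),
      mean_read_len = 6000, coverage = 20,
      min_gap = 15000, edge_margin = 25000, seed = 7301
    )
    dir <- tempfile("fixture_sim")
    .fixture_env$sim <- simulate_inversion_dataset(cfg, dir = dir)
    .fixture_env$sim$cfg <- cfg
  }
  .fixture_env$sim
}

fixture_calls <- function() {
  if (is.null(.fixture_env$calls)) {
    ds <- fixture_sim()
    .fixture_env$calls <- detect_inversions(ds$bam, ir_db = ds$ir_tsv)
  }
  .fixture_env$calls
}

# One sub-alignment row in the layout of collect_subalignments().
subaln <- function(read_id = "r1", chrom = "chr1", ref_start, ref_end,
                   read_start, read_end, strand = "+", mapq = 60L) {
  data.frame(
    read_id = read_id, chrom = chrom,
    ref_start = ref_start, ref_end = ref_end,
    read_start = as.integer(read_start), read_end = as.integer(read_end),
    strand = strand, mapq = as.integer(mapq),
    stringsAsFactors = FALSE
  )
}

subalns <- function(...) do.call(rbind, list(...))

# One signal row in the layout of extract_signals().
signal_row <- function(read_id = "r1", chrom = "chr1", ref_start, ref_end,
                       side = "left", strand = "+", mechanism = "NHEJ",
                       ir_overlap = 0) {
  data.frame(
    read_id = read_id, chrom = chrom,
    ref_start = ref_start, ref_end = ref_end,
    side = side, strand = strand,
    mechanism = mechanism, ir_overlap = ir_overlap,
    stringsAsFactors = FALSE
  )
}

signals_df <- function(...) do.call(rbind, list(...))

# Write a small BAM from hand-crafted SAM body lines.
write_test_bam <- function(body, contigs = c(chr1 = 100000L, chr2 = 100000L),
                           prefix = tempfile("testbam")) {
  sam <- paste0(prefix, ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs),
    body
  ), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

sam_line <- function(qname, flag, rname, pos1, cigar, mapq = 60L,
                     tags = character()) {
  paste(c(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0, "*", "*", tags),
        collapse = "\t")
}

# Minimal truth/sampled-read scaffolding for aligner geometry tests:
# error-free reads with fully controlled origins.
manual_reads <- function(origins, hap = 1L, strand = "+") {
  n <- nrow(origins)
  reads <- data.frame(
    read_id = sprintf("m%03d", seq_len(n)),
    hap = rep(hap, length.out = n),
    start = origins$start,
    strand = rep(strand, length.out = n),
    length = as.integer(origins$end - origins$start),
    stringsAsFactors = FALSE
  )
  reads$end <- origins$end
  events <- replicate(n, list(sub = integer(0), ins = integer(0),
                              del = integer(0)), simplify = FALSE)
  list(reads = reads, events = events)
}
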