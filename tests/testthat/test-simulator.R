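# Genome simulation, read sampling, idealized alignment and benchmarking.

test_that("planted inverted repeats are reverse complements with the
           requested divergence", {
  set.seed(21)
  cfg <- sim_config(ref_length = 3e5, n_nahr = 3, n_nhej_short = 0,
                    n_nhej_long = 0, ir_length_range = c(600, 600),
                    min_gap = 5000, edge_margin = 10000)
  g <- simulate_reference_with_irs(cfg)
  expect_equal(nrow(g$ir_pairs), 3L)
  for (i in seq_len(3)) {
    left <- Biostrings::subseq(g$reference, g$ir_pairs$left_start[i] + 1,
                               g$ir_pairs$left_end[i])
    right <- Biostrings::subseq(g$reference, g$ir_pairs$right_start[i] + 1,
                                g$ir_pairs$right_end[i])
    id <- mean(strsplit(as.character(Biostrings::reverseComplement(right)),
                        "")[[1]] ==
                 strsplit(as.character(left), "")[[1]])
    expect_equal(id, 1)
  }
  # divergence lowers the identity accordingly
  set.seed(22)
  cfg$ir_divergence <- 0.05
  g2 <- simulate_reference_with_irs(cfg)
  left <- Biostrings::subseq(g2$reference, g2$ir_pairs$left_start[1] + 1,
                             g2$ir_pairs$left_end[1])
  right <- Biostrings::subseq(g2$reference, g2$ir_pairs$right_start[1] + 1,
                              g2$ir_pairs$right_end[1])
  id <- mean(strsplit(as.character(Biostrings::reverseComplement(right)),
                      "")[[1]] ==
               strsplit(as.character(left), "")[[1]])
  expect_equal(id, 0.95, tolerance = 0.02)
  # repeats flank the truth interval
  nahr <- g$truth[g$truth$mechanism == "NAHR", ]
  expect_equal(g$ir_pairs$left_end, nahr$start)
  expect_equal(g$ir_pairs$right_start, nahr$end)
})

test_that("an infeasible packing request errors out", {
  cfg <- sim_config(ref_length = 1e5, n_nahr = 0, n_nhej_short = 0,
                    n_nhej_long = 5, nhej_long_range = c(30000, 40000),
                    edge_margin = 1000)
  set.seed(1)
  expect_error(simulate_reference_with_irs(cfg), "infeasible packing")
})

test_that("apply_inversions respects genotypes and is an involution", {
  set.seed(31)
  ref <- Biostrings::DNAString(paste(
    sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = ""
  ))
  truth <- data.frame(
    chrom = "c", start = c(2000, 9000), end = c(5000, 12000),
    mechanism = "NHEJ", ir_len = 0,
    genotype = c("invinv", "refinv"), het_hap = c(1L, 2L)
  )
  haps <- apply_inversions(ref, truth)
  expect_equal(Biostrings::width(haps), c(20000L, 20000L))
  rc <- function(x, s, e) {
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(x, s + 1, e)
    ))
  }
  # homozygous: both haplotypes inverted
  expect_equal(as.character(Biostrings::subseq(haps[[1]], 2001, 5000)),
               rc(ref, 2000, 5000))
  expect_equal(as.character(Biostrings::subseq(haps[[2]], 2001, 5000)),
               rc(ref, 2000, 5000))
  # heterozygous on haplotype 2 only
  expect_equal(as.character(Biostrings::subseq(haps[[1]], 9001, 12000)),
               as.character(Biostrings::subseq(ref, 9001, 12000)))
  expect_equal(as.character(Biostrings::subseq(haps[[2]], 9001, 12000)),
               rc(ref, 9000, 12000))
  # flanks untouched
  expect_equal(as.character(Biostrings::subseq(haps[[2]], 1, 2000)),
               as.character(Biostrings::subseq(ref, 1, 2000)))
  # applying the same inversions again restores the reference
  truth2 <- truth
  truth2$genotype <- "invinv"
  once <- apply_inversions(ref, truth2)
  twice <- apply_inversions(once[[1]], truth2)
  expect_equal(as.character(twice[[1]]), as.character(ref))
  # overlapping truth records are rejected
  bad <- truth
  bad$end[1] <- 10000
  expect_error(apply_inversions(ref, bad), "overlap")
})

test_that("read sampling hits the requested coverage, length distribution
           and strand balance", {
  set.seed(41)
  cfg <- sim_config(ref_length = 2e6, coverage = 20, mean_read_len = 9000)
  s <- sample_reads(cfg$ref_length, cfg)
  total <- sum(s$reads$length)
  expect_lt(abs(total - 20 * 2e6) / (20 * 2e6), 0.05)
  n <- nrow(s$reads)
  se3 <- 3 * stats::sd(s$reads$length) / sqrt(n)
  expect_lt(abs(mean(s$reads$length) - 9000), se3 + 200)
  expect_gt(min(s$reads$length), 199)
  expect_lt(abs(mean(s$reads$strand == "+") - 0.5), 0.05)
  expect_true(all(s$reads$start >= 0 & s$reads$end <= 2e6))
})

test_that("error-free reads are exact substrings of their haplotype", {
  set.seed(51)
  cfg <- sim_config(ref_length = 50000, n_nahr = 0, n_nhej_short = 1,
                    n_nhej_long = 0, err_sub = 0, err_ins = 0, err_del = 0,
                    coverage = 2, mean_read_len = 3000,
                    min_gap = 2000, edge_margin = 5000)
  g <- simulate_reference_with_irs(cfg)
  haps <- apply_inversions(g$reference, g$truth)
  s <- sample_reads(cfg$ref_length, cfg)
  seqs <- materialize_reads(s, haps)
  for (i in seq_len(min(10, length(seqs)))) {
    r <- s$reads[i, ]
    expected <- Biostrings::subseq(haps[[r$hap]], r$start + 1, r$end)
    if (r$strand == "-") {
      expected <- Biostrings::reverseComplement(expected)
    }
    expect_equal(as.character(seqs[[i]]), as.character(expected))
  }
})

test_that("idealized alignment reproduces the inversion split geometry", {
  set.seed(61)
  # one heterozygous NAHR inversion with a 600 bp repeat
  ref <- Biostrings::DNAString(paste(
    sample(c("A", "C", "G", "T"), 60000, replace = TRUE), collapse = ""
  ))
  genome <- list(
    reference = ref,
    truth = data.frame(chrom = "toy", start = 20000, end = 32000,
                       mechanism = "NAHR", ir_len = 600,
                       genotype = "invinv", het_hap = 1),
    ir_pairs = NULL
  )
  cfg <- sim_config(ref_length = 60000, err_sub = 0, err_ins = 0,
                    err_del = 0, chrom = "toy")
  origins <- data.frame(
    start = c(16000, 22000, 25000),
    end = c(24000, 30000, 35000)
  )
  sampled <- manual_reads(origins)
  bam <- idealized_split_align(sampled, genome, cfg, tempfile("nahr"))
  subs <- collect_subalignments(bam)

  # read m001 crosses the left breakpoint: two sub-alignments of opposite
  # strand whose read intervals overlap by the repeat length
  a <- subs[subs$read_id == "m001", ]
  expect_equal(nrow(a), 2L)
  expect_setequal(a$strand, c("+", "-"))
  expect_equal(min(a$read_end) - max(a$read_start), 600L)
  # the reverse sub-alignment extends through the right repeat
  expect_equal(max(a$ref_end), 32600)

  # read m002 lies inside the inversion: one reverse primary alignment
  b <- subs[subs$read_id == "m002", ]
  expect_equal(nrow(b), 0L)  # single alignment: not a multi-part read
  one <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag", "strand"))
  )[[1]]
  expect_equal(as.character(one$strand[one$qname == "m002"]), "-")

  # signals pin the truth interval within the repeat ambiguity
  sig <- scan_inversion_signals(bam)
  expect_true(all(sig$mechanism == "NAHR"))
  expect_true(all(abs(sig$ref_start - 20000) <= 600))
  expect_true(all(abs(sig$ref_end - 32000) <= 600))
})

test_that("benchmarking scores reciprocal overlap with one-to-one greedy
           matching", {
  truth <- data.frame(
    chrom = "c", start = c(1000, 50000), end = c(11000, 60000),
    genotype = c("refinv", "invinv"), mechanism = c("NAHR", "NHEJ")
  )
  # identical intervals: both true positives
  calls <- data.frame(chrom = "c", start = truth$start, end = truth$end,
                      genotype = truth$genotype)
  bm <- benchmark_calls(calls, truth)
  expect_equal(c(bm$TP, bm$FP, bm$FN), c(2L, 0L, 0L))
  expect_equal(c(bm$PPV, bm$S, bm$GC), c(1, 1, 1))

  # 50% overlap: neither covered at 90%
  half <- data.frame(chrom = "c", start = 6000, end = 16000,
                     genotype = "refinv")
  bm <- benchmark_calls(half, truth)
  expect_equal(c(bm$TP, bm$FP, bm$FN), c(0L, 1L, 2L))

  # no predictions: PPV undefined, sensitivity zero
  bm <- benchmark_calls(calls[0, ], truth)
  expect_true(is.na(bm$PPV))
  expect_equal(bm$S, 0)

  # a genotype mismatch lowers GC only
  wrong <- calls
  wrong$genotype[1] <- "invinv"
  bm <- benchmark_calls(wrong, truth)
  expect_equal(bm$TP, 2L)
  expect_equal(bm$GC, 0.5)
  expect_equal(unname(bm$GC_by_mechanism["NAHR"]), 0)

  # two predictions for one truth: the better overlap wins, the other is
  # a false positive
  dup <- rbind(calls[1, ], data.frame(chrom = "c", start = 1500,
                                      end = 11500, genotype = "refinv"))
  bm <- benchmark_calls(dup, truth[1, ])
  expect_equal(c(bm$TP, bm$FP), c(1L, 1L))
  expect_equal(bm$matches$call, 1L)
})

test_that("the full simulated call set is self-consistent under
           benchmarking", {
  ds <- fixture_sim()
  truth <- ds$genome$truth
  self <- data.frame(chrom = truth$chrom, start = truth$start,
                     end = truth$end, genotype = truth$genotype)
  bm <- benchmark_calls(self, truth)
  expect_equal(c(bm$PPV, bm$S, bm$GC), c(1, 1, 1))
})

test_that("seeded simulations are reproducible", {
  cfg <- sim_config(ref_length = 2e5, n_nahr = 1, n_nhej_short = 1,
                    n_nhej_long = 0, coverage = 5, mean_read_len = 3000,
                    min_gap = 5000, edge_margin = 10000, seed = 99)
  d1 <- simulate_inversion_dataset(cfg, dir = tempfile(),
                                   write_fasta = FALSE)
  d2 <- simulate_inversion_dataset(cfg, dir = tempfile(),
                                   write_fasta = FALSE)
  expect_identical(d1$genome$truth, d2$genome$truth)
  expect_identical(d1$sampled$reads, d2$sampled$reads)
  expect_identical(as.character(d1$genome$reference),
                   as.character(d2$genome$reference))
  s1 <- scan_inversion_signals(d1$bam)
  s2 <- scan_inversion_signals(d2$bam)
  expect_identical(s1, s2)
})
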