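# Sub-alignment filtering and inversion-signal extraction.

test_that("short and contained sub-alignments are filtered, sorted output", {
  cfg <- scan_config()

  # a 400 bp interval falls below the 500 bp minimum
  a <- subalns(
    subaln(ref_start = 0, ref_end = 400, read_start = 0, read_end = 400),
    subaln(ref_start = 5000, ref_end = 8700, read_start = 300,
           read_end = 4000)
  )
  out <- filter_subalignments(a, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_start, 300L)

  # a read interval strictly inside another is removed
  b <- subalns(
    subaln(ref_start = 0, ref_end = 3000, read_start = 0, read_end = 3000),
    subaln(ref_start = 9000, ref_end = 11000, read_start = 500,
           read_end = 2500)
  )
  out <- filter_subalignments(b, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_end, 3000L)

  # a single interval is untouched
  s <- subaln(ref_start = 0, ref_end = 600, read_start = 0, read_end = 600)
  expect_equal(nrow(filter_subalignments(s, cfg)), 1L)

  # output is sorted by read_start
  c2 <- subalns(
    subaln(ref_start = 0, ref_end = 600, read_start = 2000, read_end = 2600),
    subaln(ref_start = 5000, ref_end = 5600, read_start = 0, read_end = 600)
  )
  expect_equal(filter_subalignments(c2, cfg)$read_start, c(0L, 2000L))
})

test_that("equal read intervals collapse to the higher-mapq one", {
  a <- subalns(
    subaln(ref_start = 0, ref_end = 1000, read_start = 0, read_end = 1000,
           mapq = 20),
    subaln(ref_start = 5000, ref_end = 6000, read_start = 0, read_end = 1000,
           mapq = 50)
  )
  out <- filter_subalignments(a, scan_config())
  expect_equal(nrow(out), 1L)
  expect_equal(out$mapq, 50L)

  # tie: the first encountered survives
  b <- subalns(
    subaln(ref_start = 0, ref_end = 1000, read_start = 0, read_end = 1000,
           mapq = 50),
    subaln(ref_start = 5000, ref_end = 6000, read_start = 0, read_end = 1000,
           mapq = 50)
  )
  expect_equal(filter_subalignments(b, scan_config())$ref_start, 0)
})

test_that("filter_subalignments is idempotent on random inputs", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    starts <- sample(0:5000, n)
    lens <- sample(200:4000, n, replace = TRUE)
    a <- do.call(rbind, lapply(seq_len(n), function(i) {
      subaln(ref_start = i * 10000, ref_end = i * 10000 + lens[i],
             read_start = starts[i], read_end = starts[i] + lens[i],
             strand = sample(c("+", "-"), 1))
    }))
    once <- filter_subalignments(a, scan_config())
    twice <- filter_subalignments(once, scan_config())
    expect_identical(once, twice)
  }
})

test_that("opposite-orientation adjacent pairs yield signals with junction
           coordinates, sides, strands and mechanism", {
  cfg <- scan_config()

  # first sub-alignment forward at higher reference position: left signal
  a <- subalns(
    subaln(ref_start = 10000, ref_end = 13000, read_start = 0,
           read_end = 3000, strand = "+"),
    subaln(ref_start = 6000, ref_end = 9500, read_start = 3000,
           read_end = 6500, strand = "-")
  )
  sig <- extract_signals(a, cfg)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$side, "left")
  expect_equal(sig$strand, "+")
  expect_equal(sig$mechanism, "NHEJ")
  # junctions: read-end of the forward first member (ref_end = 13000) and
  # read-start of the reverse second member (ref_end = 9500)
  expect_equal(sig$ref_start, 9500)
  expect_equal(sig$ref_end, 13000)

  # read-interval overlap above 500 bp marks NAHR and is recorded
  b <- subalns(
    subaln(ref_start = 1000, ref_end = 4000, read_start = 0,
           read_end = 3000, strand = "+"),
    subaln(ref_start = 20000, ref_end = 23600, read_start = 2400,
           read_end = 6000, strand = "-")
  )
  sig <- extract_signals(b, cfg)
  expect_equal(sig$mechanism, "NAHR")
  expect_equal(sig$ir_overlap, 600)

  # overlap of 400 bp stays below the threshold
  b$read_start[2] <- 2600L
  expect_equal(extract_signals(b, cfg)$mechanism, "NHEJ")

  # same orientation: no signal
  c2 <- subalns(
    subaln(ref_start = 0, ref_end = 3000, read_start = 0, read_end = 3000),
    subaln(ref_start = 9000, ref_end = 12000, read_start = 3000,
           read_end = 6000)
  )
  expect_equal(nrow(extract_signals(c2, cfg)), 0L)

  # different chromosomes: no signal
  d <- subalns(
    subaln(chrom = "chr1", ref_start = 0, ref_end = 3000, read_start = 0,
           read_end = 3000, strand = "+"),
    subaln(chrom = "chr2", ref_start = 9000, ref_end = 12000,
           read_start = 3000, read_end = 6000, strand = "-")
  )
  expect_equal(nrow(extract_signals(d, cfg)), 0L)
})

test_that("sort_signals orders by chromosome then position", {
  s <- signals_df(
    signal_row(chrom = "chr2", ref_start = 500, ref_end = 1500),
    signal_row(chrom = "chr1", ref_start = 900, ref_end = 1900),
    signal_row(chrom = "chr1", ref_start = 100, ref_end = 1100),
    signal_row(chrom = "chr1", ref_start = 50, ref_end = 1050)
  )
  out <- sort_signals(s)
  expect_equal(out$chrom, c("chr1", "chr1", "chr1", "chr2"))
  expect_equal(out$ref_start, c(50, 100, 900, 500))
  expect_equal(nrow(sort_signals(s[0, ])), 0L)
})

test_that("collect_subalignments keeps only same-chromosome multi-part
           reads and collapses SA-tag duplicates", {
  body <- c(
    # split read: primary + supplementary on chr1, cross-listed in SA tags
    sam_line("split1", 0, "chr1", 1001, "2000M3000S",
             tags = "SA:Z:chr1,6001,-,3000M2000S,60,0;"),
    sam_line("split1", 2064, "chr1", 6001, "3000M2000S",
             tags = "SA:Z:chr1,1001,+,2000M3000S,60,0;"),
    # uniquely aligned read: removed
    sam_line("uniq1", 0, "chr1", 20001, "4000M"),
    # two sub-alignments on different chromosomes: removed
    sam_line("cross1", 0, "chr1", 40001, "1500M1500S",
             tags = "SA:Z:chr2,1001,+,1500S1500M,60,0;"),
    sam_line("cross1", 2048, "chr2", 1001, "1500S1500M",
             tags = "SA:Z:chr1,40001,+,1500M1500S,60,0;")
  )
  bam <- write_test_bam(body)
  subs <- collect_subalignments(bam)
  expect_equal(unique(subs$read_id), "split1")
  expect_equal(nrow(subs), 2L)  # SA entries deduplicated against records
  expect_equal(sort(subs$strand), c("+", "-"))
  # reverse-strand record: clips mirrored onto the original read
  rev <- subs[subs$strand == "-", ]
  expect_equal(rev$read_start, 2000L)
  expect_equal(rev$read_end, 5000L)
  expect_equal(rev$ref_start, 6000)
  expect_equal(rev$ref_end, 9000)
})

test_that("sub-alignments described only by an SA tag are recovered", {
  body <- c(
    sam_line("r1", 0, "chr1", 1001, "1000M2000S",
             tags = "SA:Z:chr1,5001,-,2000M1000S,60,0;")
  )
  bam <- write_test_bam(body)
  subs <- collect_subalignments(bam)
  expect_equal(nrow(subs), 2L)
  sa <- subs[subs$ref_start == 5000, ]
  expect_equal(sa$strand, "-")
  # reverse SA entry: leading 0 trail, read interval mirrored
  expect_equal(sa$read_start, 1000L)
  expect_equal(sa$read_end, 3000L)
})

test_that("simulated junction reads give the expected signal counts and
           labels", {
  # hand-built genome: one homozygous 6 kb NHEJ inversion at [20000, 26000)
  cfg <- sim_config(ref_length = 60000, n_nahr = 0, n_nhej_short = 0,
                    n_nhej_long = 0, err_sub = 0, err_ins = 0, err_del = 0,
                    chrom = "toy")
  set.seed(5)
  genome <- list(
    reference = Biostrings::DNAString(paste(
      sample(c("A", "C", "G", "T"), 60000, replace = TRUE), collapse = ""
    )),
    truth = data.frame(chrom = "toy", start = 20000, end = 26000,
                       mechanism = "NHEJ", ir_len = 0,
                       genotype = "invinv", het_hap = 1),
    ir_pairs = NULL
  )
  origins <- data.frame(start = c(17000, 15000), end = c(23000, 29000))
  sigs <- lapply(c("+", "-"), function(strand) {
    sampled <- manual_reads(origins, strand = strand)
    bam <- idealized_split_align(sampled, genome, cfg, tempfile("geom"))
    subs <- collect_subalignments(bam)
    # read m001 crosses one breakpoint: 2 sub-alignments, 1 signal;
    # read m002 spans both: 3 sub-alignments, 2 signals
    expect_equal(sum(subs$read_id == "m001"), 2L)
    expect_equal(sum(subs$read_id == "m002"), 3L)
    sig <- scan_inversion_signals(bam)
    expect_equal(sum(sig$read_id == "m001"), 1L)
    expect_equal(sum(sig$read_id == "m002"), 2L)
    # every signal pins the true breakpoints
    expect_true(all(sig$ref_start == 20000))
    expect_true(all(sig$ref_end == 26000))
    # the both-breakpoint read supports both strand labels
    expect_setequal(sig$strand[sig$read_id == "m002"], c("+", "-"))
    sig[order(sig$read_id, sig$strand), ]
  })
  # sequencing-strand reversal flips every side label but leaves the
  # strand label (which tracks the junction) unchanged
  expect_equal(sigs[[2]]$strand, sigs[[1]]$strand)
  expect_equal(sigs[[2]]$side,
               ifelse(sigs[[1]]$side == "left", "right", "left"))
})

test_that("signals from the simulated dataset are internally consistent", {
  ds <- fixture_sim()
  sig <- scan_inversion_signals(ds$bam)
  expect_gt(nrow(sig), 50)
  # both labels occur on both axes
  expect_setequal(unique(sig$side), c("left", "right"))
  expect_setequal(unique(sig$strand), c("+", "-"))
  expect_true(all(sig$ref_end >= sig$ref_start))
  # NAHR-classified signals carry an inverted-repeat overlap above the
  # threshold, NHEJ ones do not
  expect_true(all(sig$ir_overlap[sig$mechanism == "NAHR"] > 500))
  expect_true(all(sig$ir_overlap[sig$mechanism == "NHEJ"] <= 500))
})
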