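# VCF 4.2 serialization of inversion calls (symbolic <INV> records).

.GT_STRING <- c(refref = "0/0", refinv = "0/1", invinv = "1/1",
                nocall = "./.")

.vcf_header <- function(contigs, sample_name) {
  c(
    "##fileformat=VCFv4.2",
    paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
    paste0("##source=invcall-", as.character(utils::packageVersion("invcall"))),
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant described in this record\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the inversion\">",
    "##INFO=<ID=MECH,Number=1,Type=String,Description=\"Inferred mechanism (NAHR or NHEJ)\">",
    "##INFO=<ID=IROVL,Number=1,Type=Integer,Description=\"Largest inverted-repeat overlap of supporting sub-alignment pairs on the read (bp)\">",
    "##INFO=<ID=BPLEFT,Number=2,Type=Integer,Description=\"Left breakpoint uncertainty interval (1-based start, end)\">",
    "##INFO=<ID=BPRIGHT,Number=2,Type=Integer,Description=\"Right breakpoint uncertainty interval (1-based start, end)\">",
    "##INFO=<ID=PQ,Number=1,Type=Float,Description=\"Phred genotype quality, full precision\">",
    "##FILTER=<ID=LongInversion,Description=\"Inversion longer than the long-inversion threshold; considered unreliable\">",
    "##FILTER=<ID=LowSupport,Description=\"Fewer supporting reads than required\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality (capped at 99)\">",
    "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"Reads supporting the reference allele (R_ref)\">",
    "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Reads supporting the inversion allele (R_inv)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
}

#' Write inversion calls to VCF
#'
#' Emits one symbolic `<INV>` record per call, converting the internal
#' 0-based half-open coordinates to 1-based inclusive VCF coordinates
#' (`POS = start + 1`, `END = end`). Records are sorted by
#' `(chrom, POS)`. `FILTER` is `PASS` unless the call carries the
#' long-inversion flag (`LongInversion`) or, if present, a `filter`
#' column says otherwise.
#'
#' @param calls Call data.frame (from [detect_inversions()] or
#'   [cluster_signals()] plus genotyping columns `genotype`, `Q`).
#' @param contigs Named integer vector of contig lengths (e.g. from the
#'   BAM header).
#' @param path Output file path.
#' @param sample_name Sample column name. Default `"SAMPLE"`.
#' @param ref_fasta Optional indexed FASTA used to fill the REF base;
#'   `"N"` otherwise.
#' @return Invisibly, `path`.
#' @export
write_inversion_vcf <- function(calls, contigs, path,
                                sample_name = "SAMPLE", ref_fasta = NULL) {
  stopifnot(!is.null(names(contigs)))
  lines <- .vcf_header(contigs, sample_name)
  if (nrow(calls)) {
    bad <- !(calls$chrom %in% names(contigs))
    if (any(bad)) {
      stop("call on unknown contig '", calls$chrom[which(bad)[1L]], "'")
    }
    over <- calls$end > contigs[calls$chrom]
    if (any(over)) {
      i <- which(over)[1L]
      stop("call ", calls$chrom[i], ":", calls$start[i], "-", calls$end[i],
           " extends beyond contig length ", contigs[calls$chrom[i]])
    }
    calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
    pos <- as.integer(calls$start) + 1L
    ref <- rep("N", nrow(calls))
    if (!is.null(ref_fasta)) {
      gr <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(pos, width = 1L))
      ref <- as.character(Rsamtools::scanFa(ref_fasta, gr))
    }
    filter <- if ("filter" %in% names(calls)) {
      calls$filter
    } else {
      ifelse(calls$long_flag, "LongInversion", "PASS")
    }
    gt <- .GT_STRING[calls$genotype]
    q <- ifelse(is.na(calls$Q), 0, calls$Q)
    info <- sprintf(
      "SVTYPE=INV;END=%d;SVLEN=%d;MECH=%s;IROVL=%d;BPLEFT=%d,%d;BPRIGHT=%d,%d;PQ=%.6g",
      as.integer(calls$end), as.integer(calls$end - calls$start),
      calls$mechanism, as.integer(calls$ir_overlap),
      as.integer(calls$left_bp_start) + 1L, as.integer(calls$left_bp_end),
      as.integer(calls$right_bp_start) + 1L, as.integer(calls$right_bp_end),
      q
    )
    fmt <- sprintf("%s:%d:%d:%d", gt, pmin(99L, as.integer(round(q))),
                   as.integer(calls$R_ref), as.integer(calls$R_inv))
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\t%s\t<INV>\t.\t%s\t%s\tGT:GQ:DR:DV\t%s",
      calls$chrom, pos,
      sprintf("inv_%d", seq_len(nrow(calls))),
      ref, filter, info, fmt
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read inversion calls back from a VCF written by [write_inversion_vcf()]
#'
#' A light-weight parser recovering the call table (coordinates back in
#' 0-based half-open convention). Intended for benchmarking call sets and
#' round-trip checks.
#'
#' @param path VCF file path.
#' @return A call data.frame with genotype columns.
#' @export
read_inversion_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(cbind(.empty_calls(),
                 data.frame(genotype = character(), Q = numeric(),
                            filter = character())))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(g) if (length(g) >= 2L) g[2L] else NA_character_, "")
  }
  info <- vapply(f, `[`, "", 8L)
  samp <- strsplit(vapply(f, `[`, "", 10L), ":", fixed = TRUE)
  gt <- vapply(samp, `[`, "", 1L)
  bpl <- strsplit(get_info(info, "BPLEFT"), ",", fixed = TRUE)
  bpr <- strsplit(get_info(info, "BPRIGHT"), ",", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, "", 1L),
    start = as.numeric(vapply(f, `[`, "", 2L)) - 1,
    end = as.numeric(get_info(info, "END")),
    left_bp_start = as.numeric(vapply(bpl, `[`, "", 1L)) - 1,
    left_bp_end = as.numeric(vapply(bpl, `[`, "", 2L)),
    right_bp_start = as.numeric(vapply(bpr, `[`, "", 1L)) - 1,
    right_bp_end = as.numeric(vapply(bpr, `[`, "", 2L)),
    mechanism = get_info(info, "MECH"),
    ir_overlap = as.numeric(get_info(info, "IROVL")),
    R_inv = as.integer(vapply(samp, `[`, "", 4L)),
    R_ref = as.integer(vapply(samp, `[`, "", 3L)),
    genotype = names(.GT_STRING)[match(gt, .GT_STRING)],
    Q = as.numeric(get_info(info, "PQ")),
    filter = vapply(f, `[`, "", 7L),
    stringsAsFactors = FALSE
  )
}
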