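# Idealized split alignment of simulated reads.
#
# Because inversions conserve haplotype length, haplotype coordinates
# equal reference coordinates, with hap[x] = ref[x] outside an inverted
# interval [s, e) and hap[x] = complement(ref[s + e - 1 - x]) inside it.
# A read's sub-alignments are therefore the maximal runs of its template
# interval between inversion boundaries: forward runs map identically,
# inverted runs map through x -> s + e - 1 - x on the reverse strand. At
# an NAHR junction the inverted run's alignment is extended through the
# repeat copy contained in the read (left repeat = revcomp(right repeat),
# so that stretch aligns beyond the opposite breakpoint), producing the
# characteristic read-space overlap of about the repeat length between
# adjacent sub-alignments.

# Build CIGAR core ops and MD tag for one sub-alignment.
#   L       reference span before edge-deletion trimming
#   sub_off mismatch ref offsets (0-based within the span)
#   del_off deleted-base ref offsets
#   ins_g   insertion anchors as "number of ref bases before the insertion"
#   ref_lo  0-based reference start of the span
#   ref_str reference sequence as a single character string
.build_cigar_md <- function(L, sub_off, del_off, ins_g, ref_lo, ref_str) {
  L <- as.integer(L)
  sub_off <- as.integer(sub_off)
  ins_g <- as.integer(ins_g)
  del_off <- sort(as.integer(del_off))
  # deletions at the very edges shift the alignment bounds instead
  k_lead <- 0L
  while (k_lead < length(del_off) && del_off[k_lead + 1L] == k_lead) {
    k_lead <- k_lead + 1L
  }
  k_trail <- 0L
  nd <- length(del_off)
  while (k_trail < nd - k_lead &&
         del_off[nd - k_trail] == L - 1L - k_trail) {
    k_trail <- k_trail + 1L
  }
  if (k_lead || k_trail) {
    del_off <- del_off[del_off >= k_lead & del_off < L - k_trail]
    ref_lo <- ref_lo + k_lead
    L <- L - k_lead - k_trail
    del_off <- del_off - k_lead
    sub_off <- sub_off - k_lead
    ins_g <- pmin(pmax(ins_g - k_lead, 0L), L)
  }
  sub_off <- sort(sub_off)
  ins_g <- sort(ins_g)
  # CIGAR: D and I breakpoints in reference order, M runs between them
  g <- c(del_off, ins_g)
  typ <- rep(c("D", "I"), c(length(del_off), length(ins_g)))
  consume <- rep(c(1L, 0L), c(length(del_off), length(ins_g)))
  o <- order(g, typ == "D")  # at equal g, insertion before deletion
  g <- g[o]
  typ <- typ[o]
  consume <- consume[o]
  cur <- c(0L, cummax(g + consume)[-length(g)])[seq_along(g)]
  ops <- as.vector(rbind(rep("M", length(g)), typ))
  lens <- as.vector(rbind(g - cur, rep(1L, length(g))))
  ops <- c(ops, "M")
  lens <- c(lens, L - if (length(g)) max(g + consume) else 0L)
  keep <- lens > 0L
  ops <- ops[keep]
  lens <- lens[keep]
  if (length(ops) > 1L) {  # merge adjacent identical ops (e.g. D runs)
    grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
    lens <- as.integer(rowsum(lens, grp))
    ops <- ops[!duplicated(grp)]
  }
  # MD: match counts between mismatches and deletion runs
  ev_off <- c(sub_off, del_off)
  ev_typ <- rep(c("S", "D"), c(length(sub_off), length(del_off)))
  o <- order(ev_off)
  ev_off <- ev_off[o]
  ev_typ <- ev_typ[o]
  ne <- length(ev_off)
  if (ne) {
    base <- substring(ref_str, ref_lo + ev_off + 1L, ref_lo + ev_off + 1L)
    gap <- ev_off - c(0L, ev_off[-ne] + 1L)
    contig_del <- ev_typ == "D" & c(FALSE, ev_typ[-ne] == "D") & gap == 0L
    tok <- ifelse(contig_del, base,
                  paste0(gap, ifelse(ev_typ == "D", "^", ""), base))
    md <- paste0(paste(tok, collapse = ""), L - ev_off[ne] - 1L)
  } else {
    md <- as.character(L)
  }
  list(
    ops = ops, lens = lens, md = md, ref_lo = ref_lo, ref_len = L,
    qlen = L - length(del_off) + length(ins_g),
    nm = length(sub_off) + length(del_off) + length(ins_g)
  )
}

# Sub-alignment layout of one read: template runs between inversion
# boundaries, with NAHR repeat extension. `inv` is the per-haplotype
# inversion table (s, e, ir_len), sorted. Returns a data.frame of
# segments in template order.
.read_segments <- function(A, B, inv) {
  ov <- which(inv$s < B & inv$e > A)
  if (!length(ov)) {
    return(data.frame(lo = A, hi = B, rev = FALSE, ref_lo = A, ref_hi = B))
  }
  cuts <- sort(unique(c(A, B, pmax(A, pmin(B, inv$s[ov])),
                        pmax(A, pmin(B, inv$e[ov])))))
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1L]
  seg <- data.frame(lo = lo, hi = hi)
  seg$inv_idx <- vapply(seq_len(nrow(seg)), function(k) {
    hit <- ov[inv$s[ov] <= seg$lo[k] & inv$e[ov] >= seg$hi[k]]
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  seg$rev <- !is.na(seg$inv_idx)
  # NAHR extension through the flanking repeat copies present in the read
  for (k in which(seg$rev)) {
    ii <- seg$inv_idx[k]
    m <- inv$ir_len[ii]
    if (m > 0) {
      if (seg$lo[k] == inv$s[ii] && A < inv$s[ii]) {
        seg$lo[k] <- max(A, inv$s[ii] - m)
      }
      if (seg$hi[k] == inv$e[ii] && B > inv$e[ii]) {
        seg$hi[k] <- min(B, inv$e[ii] + m)
      }
    }
  }
  seg$ref_lo <- ifelse(seg$rev,
                       inv$s[seg$inv_idx] + inv$e[seg$inv_idx] - seg$hi,
                       seg$lo)
  seg$ref_hi <- ifelse(seg$rev,
                       inv$s[seg$inv_idx] + inv$e[seg$inv_idx] - seg$lo,
                       seg$hi)
  seg
}

#' Generate idealized split alignments for simulated reads
#'
#' Derives every read's sub-alignments from its known origin (the
#' geometry a correct long-read aligner recovers), renders them as SAM
#' records with CIGAR, MD, NM and SA tags -- the longest sub-alignment is
#' the primary record, the others supplementary -- and produces a
#' coordinate-sorted, indexed BAM. Record sequences are omitted
#' (`SEQ = *`); the CIGAR and MD tags carry the full error realization.
#'
#' @param sampled A [sample_reads()] result.
#' @param genome A [simulate_reference_with_irs()] result.
#' @param cfg The [sim_config()] used.
#' @param bam_prefix Output path prefix; `<prefix>.bam` and its index are
#'   created.
#' @return The BAM file path.
#' @export
idealized_split_align <- function(sampled, genome, cfg, bam_prefix) {
  reads <- sampled$reads
  events <- sampled$events
  truth <- genome$truth
  ref_str <- as.character(genome$reference)
  inv_by_hap <- lapply(1:2, function(h) {
    on_h <- truth$genotype == "invinv" |
      (truth$genotype == "refinv" & truth$het_hap == h)
    iv <- truth[on_h, , drop = FALSE]
    data.frame(s = iv$start, e = iv$end,
               ir_len = ifelse(iv$mechanism == "NAHR", iv$ir_len, 0))
  })
  n <- nrow(reads)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    A <- reads$start[i]
    B <- reads$end[i]
    ev <- events[[i]]
    seg <- .read_segments(A, B, inv_by_hap[[reads$hap[i]]])
    # read-space offset of a template coordinate (before strand flip)
    readpos <- function(x) {
      (x - A) - sum(ev$del <= x - A) + sum(ev$ins <= x - A)
    }
    read_len <- readpos(B)
    nseg <- nrow(seg)
    recs <- vector("list", nseg)
    for (k in seq_len(nseg)) {
      lo <- seg$lo[k]
      hi <- seg$hi[k]
      # local (1-based) event positions inside this segment
      pick <- function(p) p[p >= lo - A + 1L & p <= hi - A]
      sub_p <- pick(ev$sub)
      del_p <- pick(ev$del)
      ins_p <- pick(ev$ins)
      hap_abs_sub <- A + sub_p - 1L
      hap_abs_del <- A + del_p - 1L
      hap_abs_ins <- A + ins_p - 1L
      if (!seg$rev[k]) {
        sub_off <- hap_abs_sub - lo
        del_off <- hap_abs_del - lo
        ins_g <- hap_abs_ins - lo + 1L
      } else {
        sub_off <- hi - 1L - hap_abs_sub
        del_off <- hi - 1L - hap_abs_del
        ins_g <- hi - 1L - hap_abs_ins
      }
      bc <- .build_cigar_md(hi - lo, sub_off, del_off, ins_g,
                            seg$ref_lo[k], ref_str)
      if (bc$ref_len <= 0L || bc$qlen <= 0L) {
        next  # fully deleted sliver of a segment
      }
      # read-space interval in sequencing orientation
      rs <- readpos(lo)
      re <- rs + bc$qlen
      if (reads$strand[i] == "-") {
        tmp <- rs
        rs <- read_len - re
        re <- read_len - tmp
      }
      fwd <- !xor(seg$rev[k], reads$strand[i] == "-")
      lead <- as.integer(if (fwd) rs else read_len - re)
      trail <- as.integer(read_len - lead - bc$qlen)
      cig <- paste0(
        if (lead > 0L) paste0(lead, "S") else "",
        paste0(as.integer(bc$lens), bc$ops, collapse = ""),
        if (trail > 0L) paste0(trail, "S") else ""
      )
      recs[[k]] <- list(
        pos = as.integer(bc$ref_lo), strand = if (fwd) "+" else "-",
        cigar = cig, md = bc$md, nm = bc$nm, span = bc$ref_len
      )
    }
    recs <- recs[!vapply(recs, is.null, logical(1))]
    nrec <- length(recs)
    if (!nrec) {
      next
    }
    primary <- which.max(vapply(recs, `[[`, numeric(1), "span"))
    sa_items <- vapply(recs, function(r) {
      sprintf("%s,%d,%s,%s,60,%d", cfg$chrom, r$pos + 1L, r$strand,
              r$cigar, r$nm)
    }, "")
    lines <- vapply(seq_len(nrec), function(k) {
      r <- recs[[k]]
      flag <- (if (r$strand == "-") 16L else 0L) +
        (if (k != primary) 2048L else 0L)
      sa <- if (nrec > 1L) {
        paste0("\tSA:Z:", paste0(sa_items[-k], ";", collapse = ""))
      } else {
        ""
      }
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tNM:i:%d\tMD:Z:%s%s",
              reads$read_id[i], flag, cfg$chrom, r$pos + 1L, r$cigar,
              r$nm, r$md, sa)
    }, "")
    out[[i]] <- lines
  }
  sam <- paste0(bam_prefix, ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", cfg$chrom, nchar(ref_str)),
    "@PG\tID:invcall-sim\tPN:invcall-sim",
    unlist(out)
  ), sam)
  bam <- Rsamtools::asBam(sam, bam_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Simulate a complete inversion dataset
#'
#' Seeds the RNG (when `cfg$seed` is set), simulates the reference with
#' planted repeats, the truth set, the reads and their idealized split
#' alignments, and writes reference FASTA, truth table, inverted-repeat
#' database and indexed BAM into `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param write_fasta Write `reference.fa` (+ .fai). Default TRUE.
#' @return A list with the simulation objects (`genome`, `sampled`) and
#'   file paths (`bam`, `truth_tsv`, `ir_tsv`, `fasta` or `NULL`).
#' @export
simulate_inversion_dataset <- function(cfg = sim_config(), dir = tempfile(),
                                       write_fasta = TRUE) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  if (!is.null(cfg$seed)) {
    set.seed(cfg$seed)
  }
  genome <- simulate_reference_with_irs(cfg)
  sampled <- sample_reads(cfg$ref_length, cfg)
  bam <- idealized_split_align(sampled, genome, cfg,
                               file.path(dir, "alignments"))
  truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(genome$truth, truth_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  ir_tsv <- file.path(dir, "ir_pairs.tsv")
  utils::write.table(genome$ir_pairs, ir_tsv, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  fasta <- NULL
  if (write_fasta) {
    fasta <- file.path(dir, "reference.fa")
    refset <- Biostrings::DNAStringSet(genome$reference)
    names(refset) <- cfg$chrom
    Biostrings::writeXStringSet(refset, fasta)
    Rsamtools::indexFa(fasta)
  }
  list(genome = genome, sampled = sampled, bam = bam,
       truth_tsv = truth_tsv, ir_tsv = ir_tsv, fasta = fasta, dir = dir)
}
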