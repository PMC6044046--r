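---
title: "Calling and genotyping inversions from long-read split alignments"
author: "invcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and genotyping inversions from long-read split alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invcall)
```

## The problem

Genomic inversions are copy-neutral: they leave read depth unchanged and,
when mediated by non-allelic homologous recombination (NAHR) between
flanking inverted repeats (IRs), their breakpoints are buried in repeat
sequence that short reads cannot anchor across. Long reads change this:
a single molecule can span a breakpoint, and a split-read-aware aligner
reports it as two sub-alignments of opposite orientation. `invcall`
detects inversions from exactly this signature, classifies their likely
mechanism, and genotypes them from read counts.

## Signal model

For every read with several sub-alignments on one chromosome we sort the
sub-alignments by their left-most position *on the read* (for
reverse-strand records the clip lengths are mirrored so that adjacency is
evaluated on the sequenced molecule). After removing sub-alignments
shorter than `min_subalignment_len` (default 500 bp) on the read, or
whose read interval is strictly contained in another's, every
read-adjacent pair mapping to the same chromosome in opposite
orientations becomes one *inversion signal*.

Two coordinates summarize a signal. The junction between the pair sits
at the read-space end of the first sub-alignment and the read-space
start of the second; mapped to reference space (reference end for a
forward member at its read-space end, reference start for a reverse one,
and vice versa) these two coordinates pin the two breakpoints of the
underlying inversion, regardless of which junction the read crossed and
of its sequencing strand. The outer alignment endpoints, by contrast,
vary with read length by many kilobases and are not used. This is what
makes the later 2 kb clustering radius workable at read lengths of
3–9 kb.

Following the original split-read convention, the signal's *strand*
label is the strand of the first sub-alignment in read order, and its
*side* label is `left` when the first sub-alignment's reference position
exceeds the second's, `right` otherwise. Tracing the geometry through
shows that for a read crossing a single junction the side label equals
the sequencing strand while the strand label identifies the crossed
junction, and that a read spanning both breakpoints (three
sub-alignments) emits two signals carrying both strand labels. The
validation rule below — at least one signal of each side *and* each
strand — is therefore equivalent to requiring both junctions observed
and both sequencing strands present, which is the intended evidence
requirement however the labels are read.

### NAHR classification

The two sub-alignment intervals of a pair are allowed to overlap on the
read. At an NAHR junction they must: the repeat copy contained in the
read aligns once as part of the forward sub-alignment (onto the left
repeat) and once, reverse-complemented, as part of the reverse
sub-alignment (onto the right repeat). The overlap length therefore
estimates the IR length, and a pair overlapping by more than
`nahr_overlap_min` (default 500 bp, the conventional minimum for an
NAHR substrate) is classified `NAHR`, otherwise `NHEJ`. One consequence
is that an NAHR call's breakpoint coordinates are smeared by up to the
repeat length — the true recombination point inside the repeat is
inherently unobservable, since any choice yields the same sequence.

## Clustering and validation

Signals are sorted by `(chrom, ref_start)`. If an IR database is
supplied, each signal whose left breakpoint lies within `X` bp (default
2000) of a pair's left repeat interval and whose right breakpoint lies
within `X` bp of its right repeat is assigned to that pair's bin (the
nearest pair if several qualify) and removed. Remaining signals are
binned by distance: a signal joins a bin when both its start and its end
are within `X` bp of the bin's running mean start and end. The running
mean was chosen as the bin representative because it is deterministic on
sorted input and robust to the order in which members join; with
`X -> 0` every signal is its own bin and with `X -> inf` each chromosome
collapses to one bin (both limits are exercised in the tests).

A bin becomes a call only with `n_left ≥ 1`, `n_right ≥ 1`,
`n_fwd ≥ 1`, `n_rev ≥ 1` and total support `R_inv ≥ min_support`
(default 3; a read supporting both breakpoints counts once per
breakpoint). We do not require more than one signal per side or strand
beyond the total, the most permissive reading consistent with the
validation rule. Call coordinates are the means of the member signals'
breakpoint coordinates; the breakpoint uncertainty intervals are their
min/max. A bin containing any NAHR signal is an NAHR call (alignment
noise can push individual overlaps below threshold), reporting the
largest observed overlap. Calls longer than `long_inversion` (default
1 Mb) are kept but flagged `LongInversion` rather than dropped: NHEJ
inversions of that size are implausible and NAHR ones would need a
repeat too long to span, so they are reported as unreliable.

## Reference support and the error-rate filter

Reads that span a breakpoint uncertainty interval in one piece support
the non-inverted allele — unless the aligner forced a read from an
inverted haplotype straight through, which it betrays by elevated local
error rates. We estimate per-alignment substitution, insertion and
deletion rates (event bases per aligned base) from the first
min(10000, all) primary alignments and keep a spanning alignment only
when all three of its rates inside the inversion region
(`max(left bp start, aln start)` to `min(right bp end, aln end)`) are
below the corresponding mean + 1 SD. Insertion rates may exceed 1 in
short regions containing long insertions. Spanning is read as strict
containment of the uncertainty interval, which also rejects alignments
clipped exactly at a junction (those originate from the inverted
haplotype). When the SD is zero — error-free simulations — the
threshold degenerates to mean + 1e-9 so that perfect reads still pass.
Substitutions come from MD tags when present; otherwise read sequences
are layered onto a supplied reference FASTA.

## Genotyping

With `R_ref` and `R_inv` in hand, each call is genotyped under a
binomial model with misassignment rates ε₁ (inversion read counted as
reference support) and ε₂ (the converse), both 0.01 by default:

$$P(R_{ref},R_{inv}\mid G)=\begin{cases}
(1-\varepsilon_1)^{R_{ref}}\,\varepsilon_2^{R_{inv}} & G=\text{ref/ref}\\[2pt]
\left(\tfrac{1-\varepsilon_1}{2}+\tfrac{\varepsilon_2}{2}\right)^{R_{ref}}
\left(\tfrac{\varepsilon_1}{2}+\tfrac{1-\varepsilon_2}{2}\right)^{R_{inv}} & G=\text{ref/inv}\\[2pt]
\varepsilon_1^{R_{ref}}\,(1-\varepsilon_2)^{R_{inv}} & G=\text{inv/inv}
\end{cases}$$

multiplied by the Hardy–Weinberg prior (¼, ½, ¼) and normalized
explicitly over the three genotypes. The genotype is the posterior
argmax and the quality is $Q=-10\log_{10}(P_{2nd}/P_{1st})$, capped at
1000 when the runner-up underflows. Everything is computed in log space;
the direct-evaluation oracle in the test suite confirms agreement to
within $10^{-10}$ relative error over the count grid $[0,50]^2$, and
with ε₁ = ε₂ the heterozygous branch reduces exactly to
$0.5^{R_{ref}+R_{inv}}$. Two deliberate edge policies: with no data at
all (`R_ref = R_inv = 0`) the genotype is reported missing (`./.`)
rather than as the prior argmax, and posterior ties resolve in the fixed
order ref/ref < ref/inv < inv/inv with the tie visible as `Q = 0`.

## The simulator

`simulate_inversion_dataset()` emulates the published simulation design
at desk scale. The default configuration is a 5 Mb random reference
carrying 10 NAHR inversions and 10 NHEJ inversions (5 short at 1–4 kb,
5 long at 4 kb–1 Mb, log-uniform), genotypes heterozygous or homozygous
with probability ½ each, reads of exponential length (mean 9 kb,
truncated below at 200 bp — untruncated exponentials would make
per-alignment error-rate variances diverge) at 20× diploid coverage, and
per-base substitution/insertion/deletion rates of 5.1/4.9/7.8%. The
deletion probability per template base is $r_d/(1+r_d)$ so that deleted
bases per *aligned* base average exactly $r_d$; substitution and
insertion probabilities equal their target rates directly. Inversion
counts, sizes, rates, read-length means and coverages are all
configurable to reproduce the other study conditions (3/6/9 kb means,
5–40×).

NAHR loci are built from planted IR pairs of 500–3000 bp whose right
copy is the reverse complement of the left (divergence configurable,
default 0), immediately flanking the inverted segment. The distance
between the repeats is sampled log-uniformly at 12–30 times the repeat
length, the regime the empirical IR-length/inversion-size relationship
occupies (a megabase inversion is mediated by a repeat tens of times
shorter). This ratio also keeps the inherent ±IR/2 breakpoint ambiguity
of an NAHR call below the 10% slack of the reciprocal-overlap criterion
($d \ge 12m \Rightarrow d/(d+m) \ge 0.92$); simulating NAHR loci with
repeats comparable to the inverted segment would make the 90% criterion
unattainable for any caller, not because detection fails but because the
breakpoints are genuinely undefined within the repeats.

Instead of running an external aligner, `idealized_split_align()`
derives each read's sub-alignments from its known origin. Because
inversions conserve length, haplotype coordinates equal reference
coordinates, with $hap[x] = ref[x]$ outside an inverted interval
$[s,e)$ and $hap[x] = \overline{ref[s+e-1-x]}$ inside it; a read's
sub-alignments are the maximal runs between inversion boundaries, with
inverted runs mapped through $x \mapsto s+e-1-x$ on the opposite strand.
At an NAHR junction the inverted run is extended through the repeat copy
present in the read (the mapping extends continuously onto the opposite
repeat), reproducing the read-space overlap a real aligner produces.
Records carry full CIGAR, MD, NM and SA tags and omit SEQ — the error
realization lives entirely in CIGAR/MD, which is what the pipeline
consumes; `materialize_reads()`/`write_reads_fastq()` reconstruct
sequences for users who want to run a real aligner.

What the simulator deliberately does not model: aligner-specific
artifacts (one real aligner prefers explaining an inversion as paired
indels, another chops extra breakpoints near junctions), chimeric reads,
reference bias, non-uniform coverage, and repeat-induced mismapping in a
repeat-rich genome (the random reference is repeat-free outside planted
IRs). A clean pass on simulated data therefore demonstrates the
correctness of the signal model, clustering, counting and genotyping —
not robustness to every real-data failure mode.

## Benchmarking

`benchmark_calls()` scores predictions against truth by reciprocal
overlap: a true positive covers, and is covered by, its truth interval
to at least 90%. Matching is greedy by decreasing overlap and
one-to-one (the published criterion does not state a matching
discipline; one-to-one is the conservative choice, counting duplicate
calls of one event as false positives). Reported are
PPV = TP/(TP+FP) (NA when nothing was predicted), sensitivity
S = TP/|truth|, and genotype consistency GC among true positives,
overall and per mechanism.

At the package's default study conditions (5 Mb, ~20 inversions, 9 kb
reads, 20×, fixed seed) the acceptance suite asserts S ≥ 0.80,
PPV ≥ 0.90 and NAHR genotype consistency ≥ 0.90; the problem sizes were
chosen so the whole run — simulation, alignment, detection, genotyping,
scoring — completes in a few minutes on one CPU.

## Inverted-repeat / inversion-size analysis

`fit_loglog_regression()` fits ordinary least squares of
log₁₀(distance between repeats) on log₁₀(mean repeat length) — the
arithmetic mean of the two copies when they differ — with the slope
t-test p-value and residual SD retained.
`prediction_interval_filter()` removes pairs whose distance falls
outside the two-sided 90% OLS prediction interval (t quantile with
n−2 degrees of freedom) at their repeat length; filtering is on the
regression response, the only reading under which a "prediction
interval" applies. Surviving pairs are merged into candidate regions
with `merge_regions()`, which unions overlapping and book-ended
intervals (distance-0 merge, the common BED convention). The module is
validated on synthetic log-linear data; genome-wide repeat discovery is
out of scope and an external repeat annotation is expected as input.

## Numerical and policy choices

* All internal coordinates are 0-based half-open; conversion to VCF's
  1-based inclusive convention happens only at serialization.
* Sub-alignments are taken from both supplementary records and SA tags,
  deduplicated on (read, chromosome, start, strand) — aligners differ in
  which of the two they emit.
* Exactly equal read intervals keep the higher-MAPQ copy (first on
  ties); equal-length mutually overlapping intervals are both kept.
* No cap is imposed on sub-alignments per read; every adjacent pair is
  evaluated independently.
* No MAPQ filter is applied by default (`min_mapq = 0`).
* Genotype quality in the sample column is the rounded Phred value
  capped at 99 (VCF convention); the full-precision value is in the
  `PQ` INFO tag.

## Limitations

Complex events (inversions nested with deletions or duplications,
fork-stalling/template-switching products) are out of scope, as are
translocations and breakend-style representations. Calls rely entirely
on the aligner's split decisions: an aligner that absorbs an inversion
into indels produces no signal. Genotyping assumes the two
misassignment rates are known constants; estimating them from data
would require multi-sample information that a single BAM does not
carry.
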