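---
title: "lncscout: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncscout: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscout)
```

## The problem

Reference annotation is incomplete for long noncoding RNAs, particularly
for transcripts expressed only in disease states or in a minority of
samples of a cohort. Annotation-driven quantification cannot see such
transcripts at all. `lncscout` approaches the problem from the coverage
signal itself: any genomic interval that is robustly expressed in *some*
samples of a cohort, lies outside all annotated genes, and carries
gene-like sequence features is a candidate novel lncRNA worth inspecting.

The package is organized as the staged pipeline its outputs suggest:
scan, filter/merge, structure building, scoring. Each stage is an
exported function with inspectable intermediate output, so a user can
stop after the scan, substitute their own candidate models
(`score_models()`), or run everything with `run_pipeline()`.

## The scan model

Coverage is summarized in RPM (reads per million mapped reads), the
simplest normalization that makes per-base depth comparable across
libraries of different size. The mapped-read denominator counts primary
mapped records; secondary and supplementary alignments are excluded, and
no duplicate removal is performed. Multi-mapped reads are used as they
appear in the BAM.

Windows are 500 bp advanced by 250 bp, so every base is seen by two
windows and a transcript boundary is never more than 250 bp from a window
edge. A trailing window clipped at the chromosome end is kept only when
it is not contained in the window before it — the containment rule keeps
the window list free of fully redundant entries while still covering a
chromosome shorter than one window with a single clipped window.

Selection compares the mean of the highest 20% of samples
(`ceiling(0.2 n)` values, at least one sample, hence the minimum cohort
size of five) and the mean of the lowest 20% against the cohort median.
Using the mean of the quantile tail rather than a single order statistic
keeps the rule well defined for every cohort size and somewhat robust to
one aberrant library. A window fires when **either** extreme differs from
the median by more than 1 RPM **and** by more than one unit of |log2 fold
change|; requiring both an absolute and a relative difference suppresses,
respectively, noise around zero and small shifts on a high shoulder. The
fold change uses a 0.1 RPM pseudocount on both sides so a zero median
(the typical intergenic case) stays finite. The absolute difference is
taken on the linear RPM scale, since RPM is the unit the threshold is
expressed in. All four quantities (thresholds and pseudocount) are
`run_config()` fields.

Known-gene filtering is deliberately coarse: any overlap (one base,
either strand) with any annotated **gene span** — exons *and* introns —
removes a window, because the target class is strictly intergenic
transcripts and anything inside an annotated span is better explained as
a known gene's signal. Merging of surviving windows is plain interval
union, with book-ended windows coalescing, so one transcript covered by a
run of step-spaced windows yields one region.

## Structure building

Merged regions are quantized to the window grid, so boundaries are first
trimmed inward past bases whose pooled mean RPM (cohort average) falls
below `min_rpm` = 0.5, then walked outward base by base: extension
continues while covered bases keep appearing and stops at a run of more
than `max_gap` = 50 consecutive sub-threshold bases, or at the edge of an
annotated gene. The trim is what makes recovered TSS/3'-end coordinates
exact on clean data; the gap tolerance bridges short coverage dips
without fusing separate loci.

Junctions come from CIGAR `N` operations aggregated over all samples;
support of at least 3 reads and intron length of at least 30 bp are
required (shorter skips are treated as deletions, following common
short-read practice). Where junction introns conflict, the
better-supported junction wins, greedily, which yields one representative
exon chain per region — alternative isoforms are intentionally out of
scope. Strand is the majority vote of junction motifs (genomic `GTAG` ⇒
plus, `CTAC` ⇒ minus); with no junctions or a tie, the candidate is
scored in both orientations and the better total reported, flagged as
`strand_ambiguous`.

## Scoring

Nine sub-scores, each in [0, 1], summarize promoter, 3' end, ORF and exon
structure; the ranking score is their sum over the four groups, in
[0, 4]. The piecewise maps use strict inequalities on the outer branches
with the closed middle branch touching 0 and 1 at the breakpoints, so
every map is continuous and non-decreasing (property-tested at the
breakpoints ± 1e−9).

Choices the scheme leaves open, and what this implementation uses:

* **Promoter window**: 200 bp upstream of the TSS plus the first 50
  transcribed bases, on the sense strand (250 nt). Composition scores
  exclude N bases; an all-N window warns and scores 0.
* **Motif consensi and windows**: TATA box `TATAAA` starting between −33
  and −23; Initiator `YYANWYY` (IUPAC) overlapping the TSS; DPE `RGWYV`
  starting between +25 and +35. All configurable; the binary motif score
  asks only for one perfect consensus hit in its window.
* **Poly(A) search**: hexamer `AATAAA` in the last 50 transcript nt plus
  20 nt of downstream genomic sequence; a perfect hit anywhere beats a
  near-perfect (Hamming distance 1) one; ties go leftmost. The T-rich
  window is the 80 bp following the hexamer, continuing into genomic
  sequence past the 3' end.
* **ORF**: longest ATG-to-stop frame over the three forward frames of the
  spliced sequence, stop codon included, leftmost on ties; with no ORF,
  `n_orf = 0` forces the score (not covered by the printed formula) to 0.
* **Exon validity**: an exon counts as junction-supported when every
  internal boundary it owns coincides with a canonical (`GT..AG` in
  transcript orientation) junction.
* **Ranking ties** are broken by mean cohort RPM (descending), then
  genomic coordinate — purely for determinism.

One conceptual note: an *additive* ORF score rewards coding potential,
which may look surprising in a pipeline for noncoding RNAs. It is kept
additive here as part of a "gene-likeness" ranking — the goal is to
surface transcribed units with the full complement of gene features;
classifying coding potential is a separate task and out of scope.

## The synthetic cohort

The generator builds everything from a seed: a uniform-composition
genome, decoy gene spans, planted transcripts, and per-sample alignments.
What it emulates is exactly what the method consumes — cohort coverage
structure and junction-bearing spliced reads: plants are expressed at
~10× depth in 2 of 5 samples over a sparse background (expected 0.05×),
which trips the top-20%-vs-median rule, and decoy genes receive expressed
blocks so the known-gene filter is exercised, not just idle.

Planted sequences are constructed analytically rather than sampled:
promoters are block-arranged base multisets with exact G/C/A/T counts (a
layout that provably contains no TATA/Inr/DPE consensus, so a planted
TATAAA is the only motif), ORFs are `ATG (GGT)ⁿ TAA` (no internal stops
or starts), transcript bodies without ORFs are `CTG` repeats (no ATG, no
stop, Hamming distance ≥ 2 from AATAAA everywhere), and introns are
`GT…AG`. Every expected sub-score is therefore exact; the truth table is
computed by scoring the planted structure directly, independent of the
discovery path, and the flagship plant is designed to reach the maximum
total of 4.0.

The simulator reports a nominal library size of 10⁶ mapped reads per
sample: the 50 kb micro-genome stands for a small slice of a full-size
library, so simulated depth *d* corresponds to *d* RPM and the selection
thresholds keep their real-data meaning. Reads are error-free,
fixed-length (100 nt), deterministically tiled with extra reads piled on
the transcript termini (the sharp-boundary pile-up real TSS/poly(A) sites
show), and unstranded. What the simulation does **not** model — sequence
errors, coverage bias, fragment-length variation, duplicated reads,
antisense signal, overdispersed biological variability — means a passing
recovery test demonstrates correctness of the machinery on clean signal,
not sensitivity or specificity on real tumor cohorts.

Problem sizes used in the shipped validation were chosen to keep the
whole suite interactive: a 50 kb genome, 5 samples, 2 plants and 2
decoys for the end-to-end runs; 1,000 random sequences (≤ 300 nt) against
the brute-force ORF oracle; 10,000 random windows × 10 samples against a
direct transcription of the selection rule.

## Degenerate inputs and numerical notes

* Cohorts under 5 samples are refused (the 20% tail would be empty).
* Regions whose pooled coverage never reaches `min_rpm` are skipped with
  a warning at build time.
* `rpm_normalize` errors on a zero mapped-read count with nonzero signal,
  and returns zero for zero signal regardless of the denominator.
* Empty annotation passes everything; an empty BAM yields zero coverage.
* bedGraph input carries no junction information: candidates from
  bedGraph-only cohorts are single-exon, and the library size must be
  supplied explicitly.
* All outputs are deterministic given inputs and configuration; the only
  randomness in the package sits in the seeded simulator, which saves and
  restores the caller's RNG state.

## Known limitations

* One representative structure per region; no isoforms, no alternative
  TSS/poly(A) sites.
* Strand inference needs junctions; single-exon candidates rely on the
  both-orientation scoring fallback.
* The known-gene filter removes genuinely novel transcripts that happen
  to overlap an annotated span (e.g. intronic lncRNAs) — by design, the
  method only targets intergenic candidates.
* Thresholds are calibrated for bulk RNA-seq RPM scales; very small or
  very unevenly sequenced cohorts may need `run_config()` adjustments.
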