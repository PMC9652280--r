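---
title: "Reference-free strain comparison by canonical k-mer content: methods and design"
author: "strainscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strainscan methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two pig strains have deep shotgun reads but no assembled, annotated
genomes of their own. Mapping-based variant calling against a third
strain's reference conflates mapping artefacts with real divergence,
and assembling each strain is out of proportion to the question
actually asked: *which annotated genes of the reference are intact in
one strain but heavily altered in the other?* strainscan answers this
with an alignment-free representation: a genome is its set of
canonical k-mers, and reference positions are classified by whether
any k-mer window covering them survives in a strain's k-mer set.

## Model and assumptions

**Canonical k-mers.** A window of length k and its reverse complement
are one object; we store the lexicographically smaller string
(A < C < G < T). k is restricted to odd values ≤ 31: odd k makes the
canonical form unique (no self-reverse-complementary k-mers), and
31 bp packs into a 62-bit code in the C++ engine. The default k = 27
balances specificity (most non-repetitive 27-mers are unique in a
mammalian-sized genome) against robustness to sequencing errors (an
error destroys up to k windows).

**Membership threshold T.** A k-mer belongs to an individual when its
read count is at least T. The k-mer histogram — distinct k-mers per
occurrence count c — has an error mode concentrated at c = 1..2 and a
genomic mode at the effective coverage peak. T is the c in
`[2, c_peak]` minimising the histogram, where c_peak is the argmax
over c ≥ 3; ties break toward smaller c (favouring sensitivity), and
counts missing from the histogram are treated as zero only when
occupied counts exist on both sides, otherwise excluded. If the
spectrum is monotone decreasing (no coverage peak — too-shallow or
degenerate data), the fallback T = 3 is returned with a low-confidence
flag rather than an error, so that batch runs surface the problem in
the output instead of dying. Per-sample overrides are accepted
throughout the pipeline for externally fixed thresholds.

**Strain membership.** A k-mer belongs to a strain when at least m of
its N individuals possess it (default m = 3, the "3 of 8 / 3 of 10"
style rule). m > 1 suppresses individual-private variation and residual
error k-mers; m < N tolerates per-individual dropouts at coverage dips.

**Scanning and variant classes.** Sliding along the reference, each
window found in the strain set marks its k covered base pairs present.
Remaining scannable bases are altered base pairs; maximal runs of them
are variants. The signature calculus on isolated events (spacing ≥ 2k)
is exact: a substituted base breaks the k windows covering it but its
neighbours stay covered by flanking windows, leaving exactly 1 altered
bp; an L-bp deletion leaves exactly L; an insertion breaks the k − 1
windows spanning the junction while every reference base stays covered,
leaving 0 altered bp and an absent-run of length k − 1 — reported as a
zero-width junction call carrying the run length. The junction is
placed at the end of the covered span (`run start + k − 1`); the true
insertion point is only localisable to within the run, and this
convention makes the call coincide with the planted coordinate for
isolated events. Absent runs that overlap altered bases are explained
by the altered-run call and are not reported as insertions; we report
whatever qualifying run length is observed rather than requiring
exactly k − 1, since nearby events can merge runs.

**Ambiguous bases.** Windows containing any non-ACGT symbol are skipped
in counting and treated as absent in scanning, but bases covered by no
ambiguity-free window are flagged *unscannable* and excluded from both
altered-bp and insertion calling. Without this category, N-runs and
assembly gaps in a real reference would flood the variant list with
spurious calls; reporting them separately keeps the altered-bp counts
interpretable.

**Coordinates.** The R API returns 1-based closed `GRanges`
(Bioconductor convention); all external interchange (BED calls, truth
tables) is written 0-based half-open. Zero-width insertion junctions
appear in BED as `start == end` records.

## Per-gene aggregation

Gene models come from GFF3: gene span, coding span (first to last
coding base over all transcripts), and exon union (reduced union over
transcripts — counting is per gene, not per transcript, which keeps the
statistic deterministic under annotation redundancy). For each gene ×
region: altered bp inside the region; variant calls intersecting it (a
partially overlapping run counts once; an insertion counts when its
junction lies strictly inside, i.e. both flanking bases are in the
region, and contributes zero altered bp); and per-Mbp rates
count / length × 10⁶. A call spanning two genes is counted in both —
the alternative (assigning to one) would make counts order-dependent.
Differential gene lists select genes with strain-A rate ≥ minRate and
strain-B rate ≤ maxRate for a chosen region and metric, sorted by
strain-A rate; the symmetric contrast is obtained by swapping inputs.

## RFLP genotyping

`inSilicoPCR()` searches both template orientations for exact primer
matches (the assay's primers are long and specific; a mismatch
allowance is deliberately not the default) and returns the smallest
product within `maxProduct`, erroring on equal-length products at
distinct loci. `digestAmplicon()` scans the top strand for the
enzyme's IUPAC site and cuts at `site start + offset`; BsaHI is
GR^CGYC, whose degenerate site is its own reverse complement, so
top-strand scanning finds every site. Fragment lengths always sum to
the amplicon length. Note one deliberate convention: with a staggered
cut (offset 2 in a 6-bp palindromic site), top-strand fragment
boundaries computed on the reverse-complemented amplicon shift by the
2-nt overhang; band sets on a gel cannot resolve this, and the
classifier compares band sets (unique lengths, order-free) with a
configurable tolerance (default 0 for in-silico input).

Because the assay's source record and the exact V199I nucleotide are
not printed in the public description — only the primers, the 545 bp
product and the band patterns 317/119/109 (V/V), 436/109 (I/I) and the
4-band heterozygote — the package ships a *synthetic* template pair
(`rflpReferenceTemplate()`, and the same sequences under
`inst/extdata/prkag3_rflp_templates_synthetic.fa`) constructed to meet
exactly those constraints: primer sites flanking a 545 bp amplicon, a
BsaHI site cutting at offset 317 whose last codon is GTC (valine), a
second site cutting at 436, and an I allele differing by the single
edit GTC→ATC that ablates the first site — the same mechanism as a
codon-199 Val→Ile substitution. The filler sequence is A/T-only, which
provably cannot create additional BsaHI sites or primer matches. These
sequences are labelled synthetic everywhere; they validate the assay
logic, not the PRKAG3 locus itself. Users with the real GenBank record
can supply it directly to `runGenotype()`.

## The synthetic cohort generator

The generator is first-class, tested code; it defines the conditions
under which the pipeline's guarantees are demonstrated.

* **Reference**: i.i.d. bases at a configurable GC fraction (default
  0.41, a mammalian-like value). Contigs of 20–100 kb are used in the
  tests — large enough that 27-mer collisions are vanishingly rare,
  small enough for seconds-scale runs.
* **Planted variants**: substitutions (every substituted base differs
  from the reference), deletions, insertions; positions pairwise
  separated by at least `spacing` (default 2k) and kept away from
  contig ends, so signatures cannot interact. Substituted/inserted
  content is rejection-sampled so that no novel strain k-mer collides
  with a reference k-mer; deletions, whose content is fixed, are
  instead shifted by 0, ±1, ±2, … until the strain junction recreates
  no reference k-mer (boundary-ambiguous deletions — where the deleted
  segment shares a flank with its surroundings — would otherwise
  shorten the observed run, exactly as alignment ambiguity shifts indel
  calls in mapping-based pipelines). The gap and margin budgets absorb
  the worst-case shift, so the spacing guarantee survives. Applying the
  emitted truth table to the reference reproduces the strain genome
  byte-for-byte, and this is property-tested over 100 random
  specifications.
* **Reads**: single-end draws, uniform over placements and strands,
  with i.i.d. substitution errors; read count is
  `ceiling(coverage × genome length / read length)`. Paired-end runs
  are emulated as two independent single-end passes — k-mer content is
  insensitive to pairing. Defaults (30×, 100 bp, error-free or 1%)
  mirror common short-read regimes; the deeper 30–40× and the
  shallower ~15× regimes differ only in where the coverage peak sits.
  Linear-genome sampling produces a coverage ramp over the terminal
  ~read-length of each contig whose k-mers can fall below T; on a real
  multi-gigabase genome this affects a negligible fraction of
  positions, and on the toy fixtures it appears as short altered runs
  at contig ends, which the tests account for explicitly rather than
  hide.
* **What is deliberately not emulated**: quality-dependent or indel
  sequencing errors (threshold inference concerns low-count k-mers
  regardless of error type), structural rearrangements, diploid
  heterozygosity within an individual, and repeat structure. Passing
  tests therefore demonstrate correctness of the k-mer calculus and
  thresholding under clean, non-repetitive conditions — not robustness
  to repeats, which are intrinsically non-unique in k-mer space.
  Within-strain polymorphism can be exercised via `privateRate`
  (expected private substitutions per individual, default 0; real
  rates among cohort individuals are not publicly constrained, so this
  stays a free parameter).

All stages derive their randomness from one master seed; identical
configurations give byte-identical FASTA/FASTQ/GFF3/TSV outputs, and
the pipeline writes MD5 checksums of its outputs into a run manifest so
reruns can be verified.

## Numerical and engineering choices

* k-mers are 2-bit packed into 64-bit codes in C++ (`unordered_map`
  counting, `unordered_set` scanning); the base encoding preserves
  lexicographic order so canonical comparison happens on integers.
  Counting output is sorted by code, making results independent of
  read order and partitioning.
* The brute-force oracles in the test suite (dictionary counting by
  direct window enumeration; presence by substring search against the
  strain genome and its reverse complement) share no code with the
  engine.
* Aggregation is done in R over the union of member strings — at
  fixture scale (≤ ~10⁶ k-mers) this is simpler and fast enough; the
  streaming/partitioned design of the C++ layer is where genome-scale
  counting would go.
* The `(0, 0)` cell of the (i, j) summary is structurally empty: a
  k-mer in no individual is not observable, and the complement of the
  union is unbounded.
* Validation problem sizes: 100 kb references for recovery and noise
  robustness (30 planted events; 30× reads), ≤ 5 kb references × 50
  replicates for oracle equivalence, 60 kb with 4 toy genes for
  per-gene aggregation. These sizes make every guarantee measurable in
  seconds to tens of seconds while keeping k-mer statistics (coverage
  peaks, error tails) in the same regime as real data.

## Known limitations

* Repetitive k-mers are non-unique by construction; presence of a
  repeated window anywhere in the strain genome marks all its
  reference copies present. Divergence inside repeats is invisible.
* Altered-bp runs do not reconstruct the alternate allele; the method
  detects and localises divergence but does not genotype it.
* The valley rule assumes a unimodal genomic mode; contaminated or
  highly heterozygous samples violate this and are flagged only via
  the low-confidence fallback.
* Gene-level counts double-count calls spanning gene boundaries (by
  design, documented above); genome-wide totals are reported separately
  and are not the column sums of the per-gene table.
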