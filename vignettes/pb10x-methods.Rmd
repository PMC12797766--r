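---
title: "Methods: barcoded-TSO design, artifact QC, and benchmarking statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoded-TSO design, artifact QC, and benchmarking statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pb10x)
```

## The protocol this package models

Plate-based 5' scRNA-seq in which the cell identity is carried by the
template-switching oligonucleotide (TSO) rather than by a droplet bead.
Single cells are FACS-sorted into wells; reverse transcription adds, via
template switching, a TSO of the form

```
5'-Biotin - handle(22) - barcode(16) - UMI(9) - TTTCTTATAT - rGrGrG-3'
```

so cDNA from every well of a pool can be amplified and sequenced together
and remains compatible with standard 10X 5' library kits and Cell Ranger.
Sequencing reads 26 nt for read 1 (barcode + UMI + the first, constant
spacer base) and 90 nt for read 2 (the 5' end of the transcript). Pools of
24 wells share one library; 96 wells give 4 pools. The 9-nt UMI (one base
short of the stock 10X design) keeps the oligo at the 60-nt synthesis
limit; downstream tools that read a 10-nt UMI simply absorb the constant
spacer base.

Two artifact classes dominate QC of this chemistry:

* **TSO concatemers** — secondary template switching chains TSO copies
  into reads. At the junction the spacer/riboguanine end of one TSO abuts
  the handle of the next, producing the 11-mer `ATATGGGCTAC` (reverse
  complement `GTAGCCCATAT`). Reads are flagged by exact substring search
  for these literals (`detect_concatemers()`), mirroring a bbduk call with
  `k = 11`, no mismatches, both orientations listed explicitly.
* **Strand invasion** — the TSO hybridises to an internal complementary
  stretch of the first-strand cDNA, truncating reverse transcription. A
  deduplicated 5' UMI-read is flagged when its UMI + spacer + GGG pattern
  matches the reference sequence immediately upstream of its alignment
  start (`strand_invasion_report()`).

## The strand-invasion classifier

For each aligned, deduplicated read the query pattern is built per method
(`method_config()`): `pb10x` 9-nt UMI + `TTTCTTATAT` + `GGG` (22 nt);
`tenx` 10 + 10 + 3 (23 nt); `ss3x` a 10-nt extraction of which the last
two observed bases are the variable WW spacer, so the pattern is the
10-mer + `GGG` (13 nt). The search window is the 23 reference bases
upstream of the alignment start (in read orientation: minus-strand
records take the bases 3' of the alignment end, reverse-complemented),
truncated at contig edges; up to 3 mismatches are allowed.

Numerical choices, made once:

* **Mismatch semantics.** "Mismatch" is a substitution at an anchored
  offset: the full pattern is slid over every position where it fits in
  the window and the minimum Hamming load is taken. This is deterministic
  and matches the convention of the Smart-seq strand-invasion scripts this
  analysis descends from. Because published pipelines sometimes use
  `agrep`, which permits indels, an edit-distance mode
  (`mode = "edit"`: minimum Levenshtein distance of the pattern against
  any window substring) is provided behind a flag; substitution-only is
  the default. On anything but indel-containing contexts the two agree.
* **Degenerate windows.** Windows shorter than the pattern (reads at
  contig starts) are never flagged but stay in the denominator, so the
  reported percentage cannot be inflated by unscorable reads.
* **Tie-breaks.** `best_mismatches` is the minimum over offsets; the
  histogram bins at 0..3 and flags at > 3 mismatches are not tallied.

The classifier is property-tested against exhaustive offset x Hamming
enumeration, and for monotonicity: raising `max_mismatch` never lowers
the flagged fraction, shrinking the window never raises it.

## Barcode selection

Well barcodes are drawn from a vendor whitelist under the constraint that
every pair differs by Levenshtein distance >= 5 (edit distance rather
than Hamming, so synthesis or sequencing indels cannot convert one valid
barcode into another). The selection policy is deliberately simple:
greedy in whitelist order, accepting a candidate iff it is at distance
>= 5 from everything accepted so far. This is deterministic, reproduces
any published set when seeded with it, and needs no optimisation target
the protocol never states. An exhaustive subset search is available for
toy inputs and is used in the tests as an independent oracle for the
achievable set size. Infeasibility is an error carrying the largest set
found.

The 24-barcode set shipped under `inst/extdata/tso_barcodes_synthetic.txt`
is a **synthetic stand-in**: the published supplementary table is not
redistributable here, so the set was generated once (fixed seed) by greedy
selection at d_min = 5 from a synthetic whitelist whose first entry is the
one barcode the protocol prints (`AAAGTAGTCAAGCCTA`). Its realised minimum
pairwise distance is 7.

## What the simulator emulates — and what it does not

`make_transcriptome()`, `simulate_expression()`, `simulate_reads()` and
`simulate_airr()` produce a fully ground-truthed world:

* **Read geometry**: R1 is always barcode + fresh UMI + first spacer
  base (26 nt); R2 is 90 nt. Qualities are constant Q30 — no analysis in
  scope uses them.
* **Expression**: gene x cell counts are negative binomial (defaults
  `mean = 5`, `size = 2`, i.e. variance ≈ mean + mean²/2), the field's
  standard overdispersed model; `size = Inf` is the Poisson limit. The
  protocol states no generative model, so these defaults are a stated
  world, not an estimate.
* **Mitochondrial short transcripts**: 20% of genes are flagged mito by
  default and 80% of those are drawn under 200 nt (uniform 60-199),
  emulating the short, largely tRNA-derived mitochondrial class whose
  preferential loss during bead cleanup lowers mito fractions in pooled
  libraries.
* **Normal reads** start at the transcript 5' end (position 0), as a 5'
  chemistry does to first order; transcripts shorter than 90 nt are
  A-padded (poly-A read-through). The count matrix is the molecule pool:
  a gene with count k contributes k molecules, each given one UMI that
  all of its sequenced duplicates share, so reads resample a finite
  library and saturation/deduplication behave as in real data.
* **Concatemer reads** are 90-nt windows of a three-copy tandem TSO
  template, with the window placement randomised but always covering a
  junction, so `concatemer_rate = 1` implies every read carries the
  literal. Concatemers are absent from the aligned tag table (they do
  not map uniquely in real data).
* **Strand-invasion reads** start at an internal position whose upstream
  22 bases are overwritten with the read's own UMI + spacer + GGG,
  mutated at 0-3 uniformly drawn positions. Loci are non-overlapping
  per-transcript slots so truth is exact by construction; exceeding the
  slot capacity is an error, never silent reuse. Invasion frequency is a
  per-read Bernoulli event, uniform over slots — the protocol gives no
  per-transcript model.
* **UMIs** are uniform over 4^9 with collisions allowed: collisions are
  part of what saturation measures. Artifact reads (concatemer,
  strand-invasion) are one-off molecules with fresh UMIs.

Not emulated: positional priming biases, GC effects, quality-dependent
errors (only uniform substitutions at `error_rate`), multimapping, intron
structure, and real V(D)J sequence assembly (the AIRR generator emits
category-level truth with the Jurkat E6-1 clonotype calls). A green test
therefore establishes correctness of the computational layer against its
own stated world, not protocol performance on real libraries.

## Benchmarking statistics

* **Saturation** = 1 − unique counts / total reads, with "unique counts"
  resolved as distinct (cell, gene, UMI) triples among gene-assigned
  reads — the 10X convention. An all-reads denominator is a flag away
  (`saturation_curve()` operates on whatever tag table it is given).
* **Saturation curves** subsample globally to depth x n_cells reads
  (per-cell targets multiplied by observed cells, not stratified per
  cell), each grid point an independent seeded draw, then deduplicate and
  report means.
* **Dropout ratio** per gene = fraction of cells with zero counts; 1
  means detected nowhere.
* **Per-cell QC**: genes detected, total UMIs, percent mitochondrial
  (NA for all-zero cells).
* **Paired-TCR recovery**: a chain qualifies iff productive with V and J
  identified and a complete CDR3; a cell is "paired" with >= 1 qualifying
  TRA and >= 1 qualifying TRB; denominators are the full assayed cell
  universe; multiple qualifying chains of one locus count once.
  Percentages are rounded half-up to 2 decimals, matching how such rates
  are reported.

## Demultiplexing decisions

Barcode correction is Hamming <= 1 unique-match-or-drop (the vendor
pipeline's behaviour in the common case); ambiguity at the minimal
distance drops the read. The constant 26th base is validated warn-only:
mismatches are counted and reported but reads are kept, since the base
carries no information. The UMI deduplication key is (cell, UMI,
reference, alignment start, strand); without alignment the R2 prefix
would substitute for position, but all in-scope paths carry alignment
facts. Pool assignment is by well order (consecutive blocks of
`pool_size`); whether real plates pool by quadrant or sort order is
unknowable from the protocol and irrelevant to the statistics.

## Limitations

Pure-R string loops bound throughput to roughly 10^5 reads per minute —
ample for the simulation scales in scope, not for real FASTQs. The
exhaustive barcode search is exponential and capped at 16 whitelist
entries. The simulator's single-pool restriction reflects the protocol
(pools are sequenced as separate libraries); multi-pool experiments are
simulated pool by pool.
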