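---
title: "Methods: from crosslink peaks to splicing outcomes"
author: "clipsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from crosslink peaks to splicing outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures behind `clipsplice`, the
choices that were genuinely open when designing them, and what the
synthetic-data tests do and do not demonstrate about real data.

## Coordinates and containers

All internal containers are `GRanges` with the Bioconductor convention of
1-based closed intervals. The conversion burden sits entirely on the I/O
boundary: GTF/GFF3 records (1-based closed) map one-to-one, and BED records
(0-based half-open) are converted by `rtracklayer` on read and write. A
binding-site peak at 0-based genomic position 100 is internally position 101
and is emitted as BED `start 96, end 105`. Keeping a single convention in
one battle-tested container removes the classic off-by-one failure mode;
round-trip identity is property-tested for every reader/writer pair.

Strand `"."` is rejected for peaks and sites throughout: iCLIP signal is
strand-specific and an unstranded record is evidence of an upstream problem,
not a value to guess.

## Binding-site definition

iCLIP reads are collapsed before peak calling: reads with identical mapping
start (per chromosome and strand) *and* identical random barcode are PCR
duplicates, and only the first is kept (`dedupReads`). Crosslink peaks at
immediately adjacent nucleotides (runs i, i+1, i+2, ...) are redundant calls
of one contact: each maximal run is replaced by its highest-scoring member
(`mergeAdjacentPeaks`). A gap of two nucleotides breaks a run. Two
deterministic tie/edge rules were open and are fixed as:

* equal scores within a run keep the 5′-most peak in transcript orientation
  (genomic minimum on `+`, maximum on `-`) — any fixed rule works, but the
  choice must be reproducible;
* a site window that would cross a chromosome boundary is dropped rather
  than clipped, because a binding site is *defined* as 9 nt wide and a
  truncated window would silently break that invariant downstream
  (k-mer windows per site, PFM width, subtraction distances).

Retained peaks are extended by `flank = 4` nt each side into 9-nt sites;
the centre is the binding-site peak. Control subtraction removes a protein
site when a same-strand control site lies within `subtract_dist = 9` nt.
The distance anchor is centre-to-centre between peaks, matching the
peak-centric definition of a site; an interval-gap anchor is available via
`subtractControlSites(anchor = "interval")` because published descriptions
of "within nine nucleotides" do not always say which is meant. Subtraction
is strand-specific for the same reason deduplication is.

## Feature assignment and positional profiles

Only the representative transcript of each gene is used for feature
assignment, to avoid double-counting a site that different isoforms would
label differently. When the annotation does not mark representatives, the
transcript with the longest CDS is chosen, ties broken by lexicographic
transcript ID (CDS-less genes fall back to the longest spliced length). A
site overlapping a feature by at least 1 nt qualifies; if the 9-nt window
spans a boundary the *peak* position decides, keeping per-site assignment
unique. Per-feature gene percentages are computed over the site-bearing
genes and may legitimately sum to more than 100%: a gene can carry sites in
several features.

TSS profiles use the 5′ end of the representative transcript (or a supplied
external TSS table) and count site peaks 0–250 nt downstream,
strand-corrected. 5′ splice-site profiles consider donors of exons at least
`min_exon_len = 50` nt long that are followed by an intron; the signed
distance is negative on the exonic (upstream) side, so a peak 27 nt before
a donor reports −27. Nearest-donor ties prefer the upstream side.

Windows for the upstream sequence matrix are fixed-width (21 nt) and
centred on the peak, so stacking them at the peak anchor *is* the
alignment — a multiple-alignment step would be the identity here. This is a
deliberate simplification relative to workflows that align extracted windows
before building a logo; it trades a cosmetic refinement for exact
reproducibility. The zone of qualifying sites defaults to 25–30 nt upstream
(`zone = c(-30, -25)`) but is exposed as a parameter because reasonable
analyses have used 20–35 nt.

## Hexamer enrichment

Observed hexamer counts are taken over all sliding windows of the 9-nt site
sequences (4 windows per site; windows with ambiguous bases are skipped).
The null model resamples, `n_background = 1000` times, the same number of
9-nt windows uniformly over all valid start positions of the *target
transcript* sequences — the spliced, sense-strand transcripts of the genes
that carry sites — with replacement across resamples. This conditions the
null on local sequence composition: a hexamer is enriched only if it occurs
in sites more often than anywhere in the very transcripts the protein binds.
Uniform-over-positions is the minimal reading of "sampling randomly from
the identical transcripts"; weighting by transcript abundance would need
expression estimates the binding data do not provide.

For each hexamer `z = (observed − bg_mean) / bg_sd`. Because the observed
count is one draw from the same distribution the background estimates, z has
mean 0 and variance 1 under the null *regardless of the count
distribution's shape* — this is what the null-calibration test checks
(mean ≈ 0, SD within [0.8, 1.2] across hexamers at 1000 resamples). A
hexamer never seen in any resample has `bg_sd = 0`; its z is reported
missing and flagged `degenerate` rather than infinite, since an undefined
standardisation should not masquerade as strong enrichment. Counting is
per-window by default; per-site (presence/absence) counting is available
via `per_site = TRUE` because either convention is defensible for short
sites.

Motif scanning is exact-match only (U/T equivalent, overlapping matches all
reported); position-weight-matrix scanning is out of scope. Peak-to-motif
offsets are reported with the motif's first base as position 1 (the C of
CAGA), the display convention for such profiles; internally offset 0 means
"peak on the first motif base". The CU-rich motif class is matched as a
pyrimidine-majority rule (≥ 5 of 9 bases C/U by default, exposed as
`min_pyrimidines`) since a logo, unlike a literal, has no unique string
representation.

## Alternative-splicing events

Events are enumerated from annotation by pairwise transcript comparison
within genes: AA (shared donor, different acceptors), AD (shared acceptor,
different donors), CE (an internal exon whose two flanking junctions are
bridged by a single skipping junction in a sibling transcript), RI (every
distinct annotated intron, quantified against the gene-span "pre-mRNA" so
retention of any intron is measurable), and EI. An exitron is an intron
both of whose boundaries lie *strictly* inside one CDS exon of a sibling
transcript — a 1-nt margin on both sides, so an intron sharing a boundary
with the host exon is an ordinary alternative splice site, not an exitron.
The reading-frame effect (length mod 3) is recorded. Junctions absent from
all transcripts (purely novel junctions) are out of scope: the event space
is annotation-driven.

PSI is `inclusion / (inclusion + exclusion)`, undefined at 0/0. For RI and
EI, inclusion is retention support and exclusion the spliced junction, so
wild-type exitrons sit near PSI 1 (rarely spliced) and wild-type retained
introns near PSI 0 — the synthetic generator encodes exactly this (EI
baselines ≥ 0.9, RI ≤ 0.1).

ΔPSI and its supporting probability come from a deliberately simple,
fully-specified posterior rather than a re-implementation of a splice-graph
EM: counts are pooled within condition, given a Jeffreys Beta(½, ½) prior,
ΔPSI is the difference of posterior means (test − control), and the
probability is the Monte-Carlo posterior mass on the estimated sign
(`n_draws = 2000` paired Beta draws, seeded per event). Identical conditions
give probability ≈ 0.5; a clean shift gives ≈ 1. The published scores this
replaces are used only as a ≥ 0.9 gate, and any calibrated posterior
supports the same gate; numerical equality with other tools' scores is not
claimed. Replicates enter in two ways: the min-samples rule (≥ 3 replicates
with defined PSI per condition, or the event is excluded) and the
read-support filter; the posterior itself pools counts, which is declared
rather than inferred from any reference implementation.

Significance requires probability ≥ `min_prob = 0.9` and
|ΔPSI| ≥ `min_dpsi = 0.1`, after two structural filters: AA/AD events need
both alternative junctions observed at least once overall (the "detected in
either condition" variant is a matter of totals and can be recovered from
the per-condition columns), and RI events need intron support in *every*
control sample or *every* test sample. Strong shifts are |ΔPSI| ≥ 0.3.
Direction summaries report per-type up/down and strong-shift fractions and
test the RI-vs-EI direction contrast with a two-sided Fisher exact test.
DE classification is |L2FC| ≥ 1 (inclusive) with adjusted p < 0.05, with a
CPM ≥ 1 in ≥ 3 samples expression filter available; both operate on
supplied per-gene statistics, since model fitting is out of scope.

## Overlap statistics

For sets of sizes n1, n2 in a universe of size N, the expected overlap is
n1·n2/N, the representation factor is observed/expected, and the p-value is
the hypergeometric upper tail P(X ≥ observed) (one-sided enrichment;
depletion behind a flag). The universe must be supplied explicitly — an
"all annotated genes" default would silently inflate enrichment whenever
the analysis is restricted to expressed genes. The normal approximation
(continuity-corrected) activates only above `approx_threshold = 1e6`,
i.e. effectively never at desk scale, but is implemented and tested to
|Δp| ≤ 0.01 against the exact tail at N = 5000 because the upstream tool
this mirrors documents it.

## The synthetic-data generator

The generator is the package's study condition, not a tuning knob. It
emulates: compact plant-like gene models (5′ UTR, 2–4 CDS exons, 3′ UTR;
introns ≥ 60 nt, matching a standard minimum-intron alignment setting, with
GT…AG boundaries written into the genome); exitron-bearing isoform pairs in
25% of genes; AA/AD/CE isoforms in 60%; binding sites biased to 5′ UTRs and
to 25–30 nt upstream of donor sites; embedded motifs (literal CAGA placed
with its first base on the peak, or CU-rich 9-mers); control crosslinking
partly co-located with protein sites (default 60% of control peaks within
9 nt, exercising the subtraction path); PCR duplicates as exact
(start, barcode) copies with barcode length 9; and binomial junction counts
around condition PSIs. Background base composition is uniform 25% per base
(configurable GC) so hexamer-null expectations are analytic.

It does **not** emulate: sequencing errors or read-level FASTQ structure,
alignment artefacts, crosslinking sequence bias (UV crosslinking prefers
uridines in real data), overdispersed biological replicate variation
(binomial, not beta-binomial, is the default count noise — the minimal model
consistent with count data; an overdispersed variant would only widen
posterior intervals), expression-weighted transcript abundance, overlapping
genes, or noncoding-gene feature taxonomies. Passing recovery tests
therefore demonstrates the *computational* correctness of each stage under
known truth, not robustness to every artefact of real libraries. The
control-rate default is a free parameter: published descriptions state only
that control crosslinking is weak, not how weak.

Problem sizes in tests and in `scripts/acceptance.R` (20–60 genes, 100–250
sites, 100–500 events at depth 1000, 150–1000 background resamples, 20 seed
replicates for rank stability) were chosen as the smallest scales at which
the binomial/Monte-Carlo error bands in the checks are decisively narrower
than the effects being recovered.

## Numerical and degenerate-input choices

* Percentages round half-up at a fixed number of decimals (`percentage`),
  matching how such tables are conventionally printed; banker's rounding
  would flip displayed 42.5-type values.
* `deltaPSI` at identical inputs returns probability ≈ 0.5 by construction
  (symmetric posterior), not NA.
* Empty inputs propagate as empty outputs without error for readers,
  deduplication, merging, subtraction and Venn counts; zero-information
  cases that cannot be represented (PSI at 0/0, splicing index at zero
  total, z at zero background SD) are NA, never a sentinel number.
* Hypergeometric p-values are clamped into (0, 1] only against floating
  underflow; the exact tail itself is computed by `phyper`.
* All stochastic operations take explicit seeds (from `clipConfig`), and
  per-event seeds are derived as `seed + event index`, so event-level
  results are independent of event order and the whole pipeline is
  bit-reproducible.

## Known limitations

* The event space is annotation-driven; junctions absent from the supplied
  transcript models are invisible.
* The ΔPSI probability is a pooled-count posterior, not a splice-graph EM;
  absolute probability values are not comparable across tools, only the
  ≥ 0.9 gating behaviour is.
* Feature assignment uses one representative transcript per gene; sites in
  isoform-specific regions of non-representative transcripts inherit the
  representative model's labels.
* Exact-match motif scanning cannot express degenerate consensus positions
  other than the built-in CU-rich rule.
* The generator's independence assumptions (sites placed independently,
  binomial counts) make recovery tests necessary but not sufficient
  evidence for performance on real libraries.
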