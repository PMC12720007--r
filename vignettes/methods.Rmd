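---
title: "Methods: overlap significance and telomeric repeat content of peak sets"
author: "telopeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap significance and telomeric repeat content of peak sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telopeaks)
```

## Scope and model

telopeaks analyses two peak sets — in the motivating application, a
lncRNA's chromatin occupancy map (TERRA CHIRT-seq) and an R-loop map
(DRIP-seq) — and asks whether they co-locate beyond chance and whether the
co-located peaks are distinguished by tandem telomeric repeat content, the
sequence feature that would permit RNA–DNA hybridisation by
complementarity. The package takes *called peaks* as its input boundary:
read processing, alignment and peak calling live upstream, and plot
rendering lives downstream; the numbers behind the figures are the
deliverable.

All coordinates are 0-based half-open (the BED convention). The paper
trail of every analysis step is a plain-text file: BED3/BED6/narrowPeak
peaks, two-column `chrom.sizes`, FASTA genomes, BED12 gene models,
one-id-per-line gene lists, and TSV/JSON outputs.

## Shared/unique partition

A peak of set A is **shared** when it intersects at least one peak of set
B by at least `min_overlap` bp (default 1); otherwise it is **unique**.
The overlap of `[s1, e1)` and `[s2, e2)` is `max(0, min(e1, e2) -
max(s1, s2))`, so adjacent intervals do not overlap. A peak with several
partners counts once in the shared set — the partition is over peaks, not
pairs — but every qualifying pair is enumerated with its overlap length.
Shared/unique status is deliberately asymmetric in interpretation
(shared-A vs shared-B are different sets) and `intersect_peaks` returns
all four partitions.

Exclusion filtering (ENCODE-style blacklists, subtelomeric margins)
removes whole peaks on any 1-bp contact with a mask, mirroring how
region-drop filters behave in coverage tools; peaks are never trimmed,
since a trimmed peak would no longer be the unit the caller reported.
Subtelomeres are defined operationally as the terminal 500 kb of each
chromosome. Because published genome-scale shared/unique counts do not
state whether exclusion preceded the partition, the pipeline treats
exclusion as an optional pre-filter and, when masks are supplied, reports
the partition both before and after it.

## Telomeric repeat scanning and peak types

Scanning is exact-hexamer matching of `TTAGGG` and its reverse complement
`CCCTAA`, case-insensitive by default. Degenerate units (`TTAGG`,
`TGAGGG`, ...) are not matched: the biological rationale (R-loop formation
by complementarity to the RNA's own repeat) concerns the canonical unit,
and exact counting keeps every downstream number reproducible from first
principles. `N` never matches. Soft-masked (lowercase) sequence *is*
scanned by default — repeat arrays are exactly what maskers mask, and no
masking policy is assumed — with `respect_softmask = TRUE` available to
flip that choice.

A **tandem run** is a maximal series of occurrences of the *same* motif at
exactly unit-length spacing. Two design rules follow from what a genomic
telomeric array is: a single intervening base breaks a run (tandemness
means zero gap), and runs never mix `TTAGGG` with `CCCTAA` (an array is
strand-uniform; a `TTAGGGCCCTAA` junction is two runs of one unit, not one
run of two). Both motifs' counts are summed per peak without strand
deduplication; the two counts are also reported separately.

Peaks are typed by their run multiset: **I** no repeats, **II** a single
repeat, **III** multiple but scattered repeats (no run reaching the tandem
threshold), **IV** exactly one run at or above the threshold, **V** two or
more such runs. The classes are exhaustive and mutually exclusive by
construction, and the test suite proves it by enumerating every run
multiset up to total 12. The threshold defaults to 4 units — the stable
in-cell R-loop criterion, chosen because in-vitro work puts the minimum at
3 — and is a parameter (`min_tandem`) everywhere it is used, so the
3-unit variant is one argument away. The tandem filter (longest run ≥
threshold) is provably the same partition as type ∈ {IV, V}, and the suite
cross-checks the two definitions against each other.

## Permutation test of overlap

The null model re-places every peak uniformly at random on its own
chromosome (start drawn from `[0, L - length]`), preserving each set's
peak number, length multiset and chromosome distribution; both sets are
re-randomized independently each permutation (one-set randomization is
available for sensitivity analysis). Randomized peaks may overlap each
other, as nothing in the null forbids it. The statistic is the shared-A
count under the same intersection criteria as the observed analysis (the
pair count is available as an alternative). With `r` of `n` permutations
reaching the observed statistic, the raw empirical p is `r / n` — the
published definition — and because that can be 0, `(r + 1) / (n + 1)` is
reported alongside, together with the null mean, SD and a z-score.

"Mappable genome" is approximated by the full chromosome lengths, the
plain reading of the published procedure; an optional placement mask
(blacklist + subtelomeres) restricts placement by rejection sampling with
a 1000-retry bound per round, after which an infeasible mask is an error —
detecting infeasibility is preferred over silently biasing placement.

Calibration at desk scale is a test-design question: the shared count is
integer-valued, so with tiny expected overlap the p-value distribution is
too discrete for a meaningful uniformity check. The acceptance suite
therefore calibrates at 200 peaks of 500–1500 bp per set on a 2-Mb
two-chromosome genome (null expectation ≈ 35 shared peaks, wide support),
where 200 replicate p-values pass a Kolmogorov–Smirnov uniformity check at
α = 0.01, and verifies power by planting 100 of 200 A peaks onto B peaks
(observed ≈ 3× the null expectation), which drives p ≤ 0.01 in ≥ 95% of
replicates — the same qualitative outcome as the published test, where the
observed overlap exceeded all 1000 randomized datasets.

## Genomic annotation

Each peak's midpoint `(start + end) / 2` decides its category with the
precedence promoter–TSS > TTS > exon > intron > intergenic, approximating
HOMER's behaviour with explicit windows: promoter −1000..+100 bp around
the TSS and TTS −100..+1000 bp around the transcript end, both
strand-oriented and closed. 5′/3′ UTR sub-categories are folded into
"exon": BED12 blocks do not carry reliable CDS-independent UTR structure,
and the simplification is documented rather than guessed around. The
nearest gene minimises |midpoint − TSS| among genes on the peak's
chromosome (lexicographically smaller id on ties); distances are signed,
positive downstream of the TSS, and zero exactly at it regardless of
strand. Peaks on gene-free chromosomes stay intergenic with no nearest
gene rather than matching across chromosomes. Gene association for
external-list overlap uses nearest-TSS of the tandem-passing shared peaks,
with an optional cap on |TSS distance| (off by default, since the
published association did not state one).

## Summary statistics

`repeat_content_summary` contrasts the A-side shared and unique
partitions: counts and percentages of peaks with ≥ 1 repeat; within the
repeat-bearing subpopulations, the more-than-one and exactly-one splits
and medians (that conditioning matches the published denominators, e.g.
212/260); each partition's share of all repeat occurrences (occurrences,
not tandem units — consistent with counting "single telomeric repeats");
and tandem-filter pass counts. When no repeat exists anywhere the shares
are undefined and flagged rather than forced to a number. Group means are
compared with Welch's unequal-variance two-sided t-test — the safer
default when one group is an order of magnitude larger than the other, as
the shared/unique split typically is — with the pooled-variance variant
behind a flag.

## Synthetic fixtures

The generator emulates the statistical structure the analysis assumes, at
desk scale:

* **Genome.** Five chromosomes of 2 Mb by default (10 Mb total — large
  enough for stable permutation nulls, small enough that the whole suite
  runs in minutes); i.i.d. background at GC 0.42 (mouse-like). Any
  accidental `TTAGGG`/`CCCTAA` occurrence is re-rolled locally (keeping
  generation linear in genome length) until the background is certifiably
  motif-free, so planted counts are unambiguous.
* **Arrays.** 40 planted tandem arrays, uniform 1–12 units, strand mix
  0.5, pairwise separated by at least the maximum peak length and kept out
  of the 500-kb subtelomeric margins so exclusion tests never silently
  change planted-truth accounting (a flag places them *inside* the margins
  to exercise the exclusion path). After planting, the scanner is run over
  every chromosome and generation fails unless the realized runs equal the
  planted arrays exactly.
* **Peaks.** 500 per set of 150–1000 bp; 3% of A peaks are forced onto B
  peaks (the published shared fraction), a quarter of those centred on
  arrays with both pair members fully containing the array. All other
  peaks avoid arrays and the designed pairs, so off-array peaks are
  provably repeat-free. Chance A–B collisions are permitted and recorded
  by default; `exact_bookkeeping = TRUE` rejects them so `truth.json`
  predicts the shared count exactly. At desk-scale densities the chance
  collision rate exceeds 3%, so one fixture cannot simultaneously show the
  published ~3% shared fraction *and* permutation significance; the truth
  -recovery fixture and the planted-enrichment significance configuration
  are therefore separate, each documented where used.
* **Genes.** 60 non-overlapping multi-exon genes (5–30 kb, 2–6 exons,
  both strands, every exon/intron segment ≥ 20 bp). Ground-truth peak
  categories are computed by an independent matrix-form implementation of
  the same window definitions, so annotation recovery is a genuine
  dual-route check.

The fixture is a pure function of its configuration (one seed; byte
-identical files on re-run). What passing tests on fixtures do *not* show:
real peak-length and GC heterogeneity, degenerate repeat units, mappability
structure, or peak-caller artefacts — the fixtures validate the machinery,
not the biology.

## Numerical choices and degenerate inputs

* Canonical peak order is (chrom, start, end, name) with radix sorting;
  all outputs are deterministic given inputs, with no timestamps.
* narrowPeak float columns are carried verbatim as text so round-trips are
  byte-faithful; coordinates are validated as non-negative integers with
  line-numbered errors.
* Duplicate records are kept with a warning (replicated summits can be
  real); duplicate names are suffixed to preserve uniqueness. Unknown
  chromosomes are an error whenever chromosome sizes are available
  (fail fast when validation is possible), and accepted otherwise.
* Empty peak sets, empty files, zero-margin subtelomeres, gene-free
  chromosomes and repeat-free universes all have defined, tested
  behaviour; a degenerate permutation null (SD 0) reports an undefined
  z-score rather than dividing by zero.
* Welch's test refuses groups with fewer than two values or zero combined
  variance.

## Known limitations

Exact-hexamer scanning undercounts diverged repeats; midpoint annotation
assigns long peaks to a single category; the permutation null ignores
mappability and chromatin-accessibility structure unless a mask is
supplied; nearest-TSS association is a heuristic for peak–gene linkage;
and the five-class typing depends on the tandem threshold, which is why
the threshold stays a visible parameter everywhere.
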