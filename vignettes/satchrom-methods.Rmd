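---
title: "Models and methods behind satchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind satchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`satchrom` analyses occupancy-style ChIP-seq — a linker histone rather than a
punctate transcription factor — together with repeat-element enrichment and
nucleosome-spacing measurements. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Coverage model and normalization

Reads are reduced to fragment midpoints and counted in non-overlapping
`w`-bp windows tiling each chromosome `[0, L)` (default `w` = 100 bp).
Midpoint counting is unbiased for the simulator's fixed fragment length, and
no artificial read extension is applied. Counts are normalized to 10 million
mapped reads (`value × 10⁷ / N`), and occupancy is reported as the
difference track IP−IN, the normalized ChIP signal minus the normalized
input control per window. Two exact conservation properties anchor the
implementation: window counting preserves the read total, and rebinning by
summation preserves the track total. IP−IN of a track against itself is
identically zero and the operation is antisymmetric.

The window scheme is *tiled*, not sliding. A sliding interpretation would
multiply-count reads and break conservation; tiling keeps every downstream
sum exact, and the window width is a parameter wherever it matters.

GC% is computed from sequence on the same grid as
`100·(G+C)/(A+C+G+T)`, with `N` excluded from the denominator and all-`N`
windows set to missing; missing windows are dropped pairwise before
correlation rather than imputed, which would bias R toward the imputed
value.

## Repeat-class assignment

The unit of repeat quantification is the consensus entry, grouped into
classes. A read is matched by its **first 35 bases** (no quality trimming)
against every entry with up to 2 mismatches. Three contract details:

* Each consensus is **doubled** (two concatenated copies) before scanning,
  so a seed crossing a tandem-monomer junction — common for satellite
  reads — still matches.
* Both strands are scanned (reverse complement of the doubled consensus);
  sequencing is strand-symmetric.
* `N` never matches, on either side.

A read hitting one entry at many offsets counts once for that entry; a read
hitting several entries is a multiread and is placed uniformly at random
among the tied entries with a seeded generator. Random single placement is
the right behaviour for class-level percentages: it keeps the class totals
unbiased while avoiding fractional counts. Per class, percent mapped is
`100 × reads-in-class / total library reads` (the denominator is the whole
library), fold enrichment is `%ChIP / %input`, and significance is a
two-sided Fisher exact test on the in/out-of-class 2×2 table. A class with
zero input percent but nonzero ChIP percent has undefined fold and is
reported as `NA` with a warning, never as infinity.

Under the generator's sampling model, a class covering genomic fraction `s`
with ChIP weight `f` has expected fold enrichment `f / (1 + s(f − 1))` —
less than `f`, because enriching the class dilutes everything else in a
fixed-size library. Seed detection is incomplete on divergent arrays
(at 5% divergence, a 35-bp seed stays within 2 mismatches of the consensus
about 75% of the time), but the detection probability multiplies numerator
and denominator alike and cancels from the fold estimate. A small residual
bias (≈ 1–2% low) remains from array edges, where flanking positions carry
input-level weight in both libraries but are renormalized differently;
the Monte Carlo checks run at 3-SE tolerance, which absorbs it.

The inner mismatch scan is compiled C++ with early exit (a position is
abandoned at the third mismatch, an entry at its first qualifying offset);
Biostrings pattern matching serves as an independent oracle in the tests.

## Island calling

Enriched domains are called SICER-style on 200-bp windows:

1. background rate λ = `N·w / (0.8·genome length)` — the 0.8 is the
   effective (mappable) genome fraction;
2. a window is *eligible* when its count's upper-tail Poisson p-value at λ
   is ≤ `p0` = 0.2 (the published SICER default; the calling parameters
   themselves are window 200, gap 600, E-value 1000, q ≤ 0.001);
3. eligible windows separated by at most `gap` bp of ineligible space merge
   into maximal islands (gap ∈ {0, 1, 2, 3} × window);
4. an island's score is Σ −ln p over its eligible windows;
5. the E-value is realized by a **seeded Monte Carlo**: the same number of
   reads is placed uniformly over the effective genome, islands are called
   identically, and the score threshold is the smallest value whose expected
   exceedance count is ≤ E. This replaces SICER's analytic recursion with a
   brute-force-checkable contract at mini-genome scale; it is a
   simplification, not a reimplementation, of that algorithm.
6. with an input library, each ChIP island receives the empirical tail
   probability of its score among islands called identically on the input,
   Benjamini–Hochberg adjusted; islands with q ≤ 0.001 are kept. When the
   input produces no islands at all, the empirical tail probability is 0 —
   any ChIP island exceeds an empty background.

Gap-size optimization calls islands at each candidate gap and keeps the gap
maximizing the aggregate (summed) island score, ties to the smallest gap.
Aggregate score is monotone non-decreasing in the gap on clean signal, so
the tie rule matters exactly when gaps are interchangeable. Region
annotation assigns each region by its midpoint — inside a TSS–TTS span,
within 5 kb of a gene boundary (proximal), or distal — by-midpoint rather
than bp-apportioned, so the three fractions sum to one; the 5-kb proximal
flank is a parameter, as no standard width exists for "proximal regulatory
region".

## Metagene profiles

Profiles are built in gene-relative, edge-aligned bins of the track window
width: bin `j` covers `[anchor + j·w, anchor + (j+1)·w)` on the plus strand
and its mirror on the minus strand, so offsets always run 5′→3′ and the
anchor sits on the boundary between the two central bins (offsets `−w` and
`0`). A bin's value is the overlap-weighted mean of the at most two track
windows it straddles; bins beyond a chromosome end are dropped from that
offset's mean rather than zero-filled. With a symmetric depletion centered
on the TSS, the two central bins are equal in expectation — "the minimum is
at the TSS" therefore means the minimum falls in that central pair.

Gene groups: expression deciles-extremes (top 10%, bottom 10%, all — note
"all" overlaps the extremes, so this scheme is deliberately not a
partition), expression quintiles, promoter-mark quantiles (mean mark over
TSS ± 2 kb; k equal groups), and bivalency classes (K4/K27 presence within
TSS ± 1 kb, half-open overlap). The 2-kb scoring and 1-kb bivalency
half-widths match the visible extent of promoter mark peaks and are
parameters. All rank splits break ties by stable gene id, so groupings are
deterministic; group sizes differ by at most one.

The distance-decay analysis collects the single window value at TSS ± D for
each distance D and drops points lying within an exclusion radius of any
*other* TSS, so distal values are not contaminated by neighbouring
promoters. The radius has no defensible default and is a required argument.

## Correlation

Tracks are rebinned to 1-kb windows by summation and correlated with
Pearson's R over all windows pooled across chromosomes (per-chromosome
variants report each chromosome separately; pooled and per-chromosome R can
legitimately disagree). Windows missing in either track are dropped
pairwise. Zero-signal windows are **kept** by default — dropping them
conditions on the joint signal and shifts R — with a documented flag to
drop. Zero-variance inputs yield an explicit `NA` rather than an error or a
spurious value.

## Quantification estimators

**NRL.** For each MNase timepoint, the apparent nucleosome repeat length is
the OLS slope of polynucleosome band size on band number — the intercept is
left free because end-trimming shifts all bands by a constant, which moves
the intercept only. Apparent NRLs shrink as digestion proceeds, so the
zero-time NRL is the intercept of a second OLS line of apparent NRL on
digestion time, reported with its standard error. Both stages are plain
unweighted OLS: the band noise is homoscedastic in the generator, and the
extrapolation is deliberately linear ("extrapolating the curve to time 0"
with three timepoints does not support anything richer). On noise-free
ladders the estimator recovers the generating NRL to machine precision; at
5-bp band noise with bands 1–8 and timepoints 2.5/5/10 min its standard
deviation is ≈ 0.94 bp, so a ±3 bp per-replicate recovery band is a ≈ 3.2σ
event per replicate — expect a rare excursion in runs of hundreds of
replicates.

**Ratios.** H1 per nucleosome divides the peptide-bond-adjusted sum of H1
peak areas by half the adjusted H2B area (two H2B per nucleosome); it is
invariant to a common scale on all areas. qRT-PCR relative expression
subtracts mock-RT signals before normalizing to the housekeeping reference;
the subtraction is performed on *linear* quantities (post standard-curve or
2^−Ct), since subtraction on the Ct scale is meaningless — negative
adjusted targets are clamped to zero with a warning. qChIP enrichment is
signal over IgG. Percent methylated CpG excludes unscored calls from the
denominator.

## The synthetic-data generator

The generator emulates the study design at desk scale: a mini-genome with a
divergent tandem satellite array and expressed genes; a ChIP library whose
fragment midpoints are sampled proportional to
`w(m) = class_weight(m) × Π_g (1 − d_g·exp(−(m − TSS_g)²/2σ²))`,
against a uniform input. Fragments land on either strand with probability
1/2; the dip is strand-agnostic because occupancy, not transcription, is
modelled.

Design choices worth stating:

* **Weights are evaluated at the fragment midpoint**, the same coordinate
  that is recorded as the true origin and counted by the coverage module.
  Evaluating the dip at the fragment start would shift the apparent
  depletion by half a fragment length in midpoint-counted coverage and
  off-center every TSS profile.
* **Dip shape and width.** No quantitative dip model exists to copy; the
  multiplicative Gaussian is a modelling choice. The default width
  σ = 250 bp gives a promoter-scale footprint (FWHM ≈ 600 bp), sharp at
  100-bp window resolution, and — because the dip is TSS-centered rather
  than spread over the transcription unit — keeps gene bodies net-depleted
  after per-10M renormalization at realistic gene densities. The dip depth
  scales with expression rank (`d_g = d·rank_g/n`), so highly expressed
  genes carry the deepest dips.
* **Multi-mapping is emergent.** The simulator never labels a read as a
  multiread; tandem-array reads simply match many offsets and, via the
  doubled-consensus scan, are rediscovered as multireads downstream.
* Coordinates are 0-based half-open everywhere internally, matching BED
  emission natively.
* MNase ladders are generated directly in band-size space,
  `S(n,t) = n·(NRL₀ − r·t) + b + ε`, with independent Gaussian band noise.
  Specs whose largest timepoint would drive the apparent NRL to zero or
  below are rejected.

What the generator does **not** emulate: sequencing errors, PCR duplicates,
GC amplification bias, paired-end reads, mappability structure, chromatin
fragmentation bias, or indel divergence in repeats. Passing tests on this
generator demonstrate that the estimators recover known parameters under
the stated sampling model — not that they are robust to the full error
structure of real libraries.

## Problem sizes and determinism

The test suite and the acceptance script run on mini-genomes of 0.2–1 Mb
with 2×10⁵–4×10⁵ reads per library, 100-replicate ladder experiments, and
exhaustive or 100-seed brute-force oracles for the exact test and the
island caller; the full suite completes in about two minutes on one CPU.
Every stochastic step takes an explicit integer seed, simulation is a pure
function of (spec, seed), and the demo pipeline writes an MD5 manifest that
is byte-identical across reruns of the same config.

## Known limitations

* The island caller's E-value contract is Monte Carlo, so the retained set
  near the score threshold can change with the background seed; at the
  default E = 1000 on mini-genomes the threshold is usually vacuous.
* Fold enrichment near array edges carries the small renormalization bias
  described above; it vanishes as array length grows relative to fragment
  length.
* The Gaussian TSS dip does not model gene-body-wide depletion; profiles
  over long genes will under-state depletion relative to real occupancy
  data.
* `deciles_extremes` grouping is intentionally not a partition; downstream
  code must not assume disjoint groups for that scheme.
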