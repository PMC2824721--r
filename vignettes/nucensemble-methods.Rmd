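---
title: "Methods: consensus integration of nucleosome positioning maps"
author: "nucensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus integration of nucleosome positioning maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model behind `nucensemble`, the
choices made where the design was genuinely open, and what the
synthetic-data validation does and does not establish.

## The integration model

Each input is a set of nucleosome position calls from one platform. All
analyses operate on the *binary restructuring* of a call set: a
per-chromosome 0/1 vector in which 1 marks a base inside a nucleosome
footprint (dyad ± 73 bp by default; reported call intervals can be used
instead) and 0 marks linker DNA. Coordinates are 0-based half-open
throughout; BED and bedGraph files are read and written in their native
conventions via `rtracklayer`.

Given N binary tracks, three site-wise summaries are computed:

* **Stable consensus (logical AND).** `S(i) = 1` iff every dataset calls
  site i occupied. Under a model where each dataset independently
  detects a well-positioned nucleosome with high probability, AND-runs
  mark the intersection of N footprints and their midpoints estimate the
  consensus dyad.
* **Dynamic disagreement (mean pairwise XOR).** With k(i) of N datasets
  calling site i occupied, the number of discordant pairs is k(N−k), so
  the mean over all C(N,2) pairs is `D(i) = k(i)(N−k(i))/C(N,2)`. This
  is computed in closed form; the test suite verifies it against an
  explicit all-pairs enumeration. D is maximal where the per-dataset
  occupancy probability is 1/2, i.e. where measurement outcomes are
  maximally inconsistent.
* **Binomial decomposition (BDID).** Treating the N datasets as i.i.d.
  Bernoulli observations of a per-site occupancy probability, estimated
  by the frequency `p(i) = k(i)/N`, the decomposition produces N+1
  probability tracks `P{X(i)=k} = C(N,k) p(i)^k (1−p(i))^{N−k}`. The
  tracks are grouped as NFR (k = 0), dynamic (1 ≤ k ≤ N−2) and stable
  (k ≥ N−1). The stable threshold `stableMinK = N−1` is exposed as a
  parameter because the grouping of intermediate k values is a judgement
  call; with six datasets the default assigns k = 5, 6 to the stable
  group. The stable *probability* map `P{X ≥ N−1}` degrades gracefully
  when a single platform drops a call (p = 5/6 still yields a high
  stable probability), which is why per-gene analyses that need
  per-nucleosome resolution — promoter-pattern clustering and +1-dyad
  assignment — are run on the thresholded BDID stable map rather than on
  the strict AND track, whose runs vanish whenever one platform misses.

Two further comparison tools mirror standard practice: region-wise
Pearson correlation matrices between datasets (whole genome, promoter,
and 400-bp gene segments, strand-oriented; zero-variance pairs are
reported as NA and excluded from means, never zero-filled), and a 2 × 2
PCA split of two continuous occupancy tracks into a common component
(projection on the same-sign eigenvector of the standardised pair's
covariance) and an independent component (the mixed-sign axis). The
same-sign labelling rather than strict eigenvalue order makes the
decomposition behave sensibly for anti-correlated inputs, where the
"common" signal is the part that cancels.

## Composite profiles and equilibrium points

Signals are aligned to TSS (or TTS) anchors, strand-oriented so negative
offsets are upstream, over a ±800 bp window by default; genes whose
window leaves the chromosome are dropped and counted. Column means give
the composite profile.

Peak detection on composites needed care because binary-consensus
profiles do not have smooth unimodal peaks: an AND-run composite is a
train of flat-topped, slightly double-humped plateaus (the intersection
of jittered footprints, with coverage highest near footprint edges that
face a neighbouring nucleosome). The detector therefore:

1. smooths with a centred moving average (default 31 bp);
2. collects strict local maxima and merges neighbours separated only by
   a shallow dip (valley above 80% of the lower maximum, measured from
   the profile minimum) — the two humps of one plateau must not count
   twice;
3. discards maxima with prominence below 12% of the profile range
   (prominence = height above the higher flanking valley). The default
   is deliberately above the amplitude of genuine low-amplitude
   structure in consensus tracks, such as residual counterphase bumps in
   an AND profile;
4. locates each surviving peak shape-aware: flat-topped peaks (top
   region within 15% of prominence at least 50 bp wide) are placed at
   the midpoint of their two flank half-height crossings, each flank
   measured against its own valley — for a footprint-shaped peak the
   crossings sit at the support edges symmetrically about the dyad
   regardless of how unequal the valleys are; narrow rounded peaks are
   placed at the midpoint of the region above valley + 50% prominence,
   which is unbiased for a symmetric bump between unequal valleys;
5. greedily suppresses peaks within 100 bp of a higher one, ties broken
   toward the smaller |offset|.

Peak spacing is the sequence of successive differences; gaps above
200 bp (the NFR-spanning gap between the −1 and +1 peaks) are excluded
from the mean and reported separately. The same gap rule delimits the
*phased array* when the dynamic profile is compared with stable-peak
midpoints: counterphase is a statement about adjacent nucleosomes within
the array, so dynamic peaks inside the NFR gap or beyond the outermost
stable peaks (which flank no pair of adjacent stable peaks) are reported
but not matched to midpoints.

## Measurability and positioning SNR

Per-gene measurability is the mean Pearson correlation over all C(N,2)
dataset pairs in the ±800 bp TSS window; zero-variance pairs are
excluded and the pair count reported. The positioning SNR is
`10·log10(S/D)` dB where S and D are the mean squared stable and dynamic
signals ("average energies") in a window — 200 bp sliding for the
promoter curve, the full window for per-gene values. Energy ratios make
the statistic scale-invariant; windows with zero dynamic energy yield
+Inf sentinels (−Inf for zero stable energy), serialised as empty TSV
cells.

## Regulation analyses

* **Clustering**: Euclidean k-means (k = 4, 10 restarts, seeded) on the
  per-gene stable-map rows in a 1600 bp TSS window. Clusters are
  relabelled by decreasing mean +1-region occupancy so labels are stable
  across runs.
* **Group frequency curves**: genes sorted by a property and scanned
  with a sliding window of `ceiling(N/23)` consecutive genes (209 for
  4,792 genes); per window, each cluster's percentage against the
  window's mean property.
* **Group density tests**: Welch two-sample t-tests on per-gene promoter
  occupancy density for every cluster pair.
* **LRC maps**: for every window width (100–600 bp) and centre inside
  ±800 bp, the Pearson correlation across genes between window-mean
  occupancy and a property. The width step defaults to 10 bp and the
  position step to 1 bp; the validation suite uses 50/8 bp steps, which
  sample the same map 400× faster without changing its half-maximum
  geometry.
* **+1 nucleosome**: the stable call with the smallest non-negative
  strand-oriented dyad offset in [0, 120]. The upper bound is chosen to
  end before the first counterphase midpoint (~+140) and far before the
  +2 position (~+225): with a wider window, a gene whose +1 is missing
  from the consensus map is silently assigned its +2 (or a destabilised
  call), which both biases and inflates the variance of dyad–TSS
  statistics. With the tight window such genes are excluded and counted
  instead. Reported distance is TSS − dyad (a dyad 60 bp downstream
  gives −60).
* **TATA contrast**: class-wise +1 offset means, their difference, and
  property means, all with seeded percentile bootstrap intervals.

## The synthetic genome

The generator is the package's test bed: it plants a known architecture
and the analyses must get it back.

* **Geometry.** One chromosome; TSSs every 2,400 bp (±200 bp jitter),
  which keeps all ±800 bp windows disjoint; 50/50 strands; gene length
  1,200 bp. Defaults place 2,000 genes.
* **Stable array.** Eight equilibrium offsets (−559, −393, −228, +60,
  +225, +392, +559, +725 bp from the TSS; configuration, not constants)
  with per-gene Gaussian jitter (SD 8 bp). The +1 mean switches to 58 bp
  on TATA-containing promoters (20% of genes) and 64 bp on TATA-free
  ones. No stable dyad is planted inside the promoter NFR (−180..0).
* **Archetypes.** Each gene carries one of four occupancy archetypes —
  full array, downstream-only, upstream-only, none — in equal
  proportions, emulating the promoter pattern classes that k-means is
  asked to recover.
* **Dynamic nucleosomes** occupy the counterphase midpoints between
  adjacent equilibrium offsets, but only where *both* flanking stable
  positions are absent for that gene: a 147 bp particle cannot sit
  between two present neighbours only ~166 bp apart, so fuzzy
  nucleosomes live where the stable array locally is not. Each platform
  re-draws their positions (SD 25 bp) and presence (probability 0.55
  with mild per-gene lognormal variation). The presence default sits
  near 1/2 deliberately — pairwise disagreement k(N−k) is maximal at
  occupancy 1/2 — and the jitter keeps each bump inside its inter-stable
  cage so the dynamic signal stays phase-opposed to the stable one.
* **Platforms.** Six specifications with positional noise 8–18 bp,
  detection 0.95, 0.05 false calls per kb. The noise scale is set by
  cross-study positional discordance, which in practice far exceeds any
  single study's nominal resolution; it is also what blurs footprint
  boundaries enough that linker bases become coin flips, producing the
  counterphase disagreement peaks the XOR analysis measures.
* **Properties.** Five gene properties share one linear model:
  `beta_dyn · z(dynamic occupancy in 0..+640) + beta_stab · z(stable
  occupancy in −240..+560) + noise`, defaults +0.5/−0.5/SD 1. The
  windows define the planted LRC regions; the exact correlations implied
  by the realised occupancy vectors are stored as metadata so recovery
  can be checked without re-deriving them.
* **Heat shock.** Activated promoters (15%) slide away from their
  equilibrium points, outward from the TSS, by `cap·|index|/5` with
  cap = 350 bp, so displacement grows with nucleosome index up to the
  cap; repressed promoters (15%) move toward equilibrium (deviation
  × 0.3); basal genes get small symmetric jitter (SD 5 bp). A zero cap
  gates all movement and returns the layout unchanged. The sliding
  analysis observes dedicated stable-class call sets (noise 2 bp,
  detection 0.98) for both conditions, since ordinal indexing tracks
  positioned nucleosomes.

What the generator does **not** emulate: DNA sequence and MNase
digestion chemistry, sequence-dependent positioning signals, replicate
correlation structure between platforms, chromosome-scale heterogeneity,
overlapping or nested transcripts, and real distributions of gene
properties. Passing recovery tests therefore shows that the estimators
are correct and well-calibrated for a genome whose ground truth matches
the model's assumptions — not that the six published datasets would
yield the published figures.

## Numerical choices and degenerate inputs

Seeds: every stochastic operation takes a seed and derives
sub-stream seeds deterministically; RNG state of the caller is restored.
Undefined correlations (zero variance) are NA and excluded from means.
An empty peak set, a gene without a +1 call, a single-observation
bootstrap cell, and a contingency table with a zero margin are all
explicit, named outcomes rather than silent numbers. Bootstrap intervals
are percentile-based. Even footprints place the dyad left of centre
(`start + footprint %/% 2`); BED dyads are `floor((start+end)/2)`.

## Problem sizes

The recovery analyses (test suite and `scripts/acceptance.R`) use the
generator's default study: 2,000 genes, six platforms, one ~4.8 Mb
chromosome, 500–1,000 bootstrap resamples, LRC on 50/8 bp steps. The
pipeline smoke test runs the full stage graph on 500 genes. These sizes
put every planted effect several standard errors away from its
acceptance threshold while keeping a full run in tens of seconds.

## Known limitations

* The AND consensus requires unanimity, so its per-gene runs disappear
  at a rate of `1 − detection^N` per nucleosome; analyses needing
  per-gene calls should use the BDID stable map (the package does).
* Ordinal nucleosome indexing assumes conditions share the gene's
  nucleosome count near the TSS; large insertions/evictions between
  conditions would shift indices rather than match particles.
* The +1 window [0, 120] assumes promoter-proximal spacing near 165 bp;
  genomes with much shorter repeats need a narrower window.
* LRC maps report raw correlations; no multiplicity correction is
  applied across the (width × centre) grid, as the map is interpreted
  geometrically (sign regions), not as a hypothesis field.
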