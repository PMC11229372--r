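---
title: "Promoter colocalization of architectural proteins: models and methods"
author: "peakcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter colocalization of architectural proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcoloc)
```

## Scope and data model

`peakcoloc` covers the downstream, coordinate-level part of a ChIP-seq
study of a promoter-binding architectural protein: everything after peaks
have been called. Peaks, gene models, promoter windows and
heterochromatin blocks are tibbles in a single internal convention —
0-based, half-open intervals (the BED convention). GTF input (1-based,
inclusive) is converted on read; coordinates are written back out as BED.
Adjacent half-open intervals share no base and never overlap.

Each peak has an *anchor*: its summit when one is available (the
point-source estimate peak callers emit) and its midpoint otherwise. All
point-wise decisions — promoter membership, compartment, feature label —
are made at the anchor, so a broad peak whose summit sits in a promoter
is a promoter peak regardless of how far its tails reach.

## Annotation around the TSS

The promoter is the symmetric, strand-independent window of ±200 bp
around the TSS (401 positions; `halfwidth` is tunable and in bases).
Feature priority is promoter > gene body > intergenic: an anchor inside
any promoter window is a promoter peak even if it also lies inside
another gene's span. When windows of neighbouring genes overlap, the
anchor goes to the nearest TSS, with ties broken toward the
lexicographically smaller gene id so output never depends on input order.
For multi-TSS genes the package uses whatever gene-level TSS the
annotation supplies; isoform-level TSS selection is out of scope.

The euchromatin/heterochromatin partition is a fixed coordinate map. For
the fly genome, `dm6_heterochromatin()` carries the pericentromeric
blocks of dm6 (2L:22000975–23513712, 2R:1–5398184, 3L:22962476–28110227,
3R:1–4174178, X:22628490–23542271, read as 1-based inclusive and stored
half-open); block starts are inclusive. Any map with the same shape can
be substituted. No chromatin-state inference is attempted beyond this
partition.

Multi-set peak unions (`merge_union()`) are connected components of the
overlap graph: linkage is transitive, so two peaks that never directly
overlap can share a region through a chain. This matters when counting
combination memberships — a merged region lists every contributing set
once, and `combination_counts()` can count either merged regions
(default) or original contributing peaks, since published summaries are
ambiguous between the two.

## Motif model

A motif is a position weight matrix over A, C, G, T; probabilities come
from counts with an additive pseudocount (default 1), and scores are
log2-odds against a background (default uniform — scanning tools rarely
state their background, so it is a parameter). A site is a window whose
score reaches the threshold for a target p-value, default 1e-4: the
minimal t with P(score ≥ t) ≤ p for a random background word.

The threshold is computed by dynamic programming over a discretized score
lattice: per-position scores are rounded once to 1e-4 log2-odds units and
the exact distribution of the lattice word score is built by convolution.
The scanner makes its pass/fail decision with the same lattice scores, so
the threshold, the scanner and exhaustive enumeration of all words agree
exactly — including for words with exactly tied raw scores, which no
refine-until-stable scheme can split consistently (an earlier design
halved the step until the passing set stabilized; tied words made that
unreachable, so the fixed shared lattice replaced it). The only
approximation left is the initial rounding, bounded by L·step/2 (3.75e-4
score units for a 15-mer), orders of magnitude below typical gaps between
distinct word scores. Zero-probability letters (possible only with
pseudocount 0) carry a −1000 sentinel score; inside the DP they are
clipped to 16 log2-odds units below their column maximum to keep the
lattice bounded, which can only affect thresholds at impractically large
p.

Windows containing `N` are skipped rather than scored as background —
scoring them would inflate hits in masked regions. Both strands are
scanned by default; minus-strand hits are reported at the plus-strand
window start. When several PWMs are supplied (e.g. motif variants
discovered from different peak subsets), a peak is motif-positive if any
of them has a hit within the peak span at its own threshold — a logical
OR, matching the practice of accepting a site if at least one discovered
motif variant matches.

## The colocalization test

For two proteins with bound housekeeping-promoter sets A and B inside a
universe U, the observed statistic is Fo = |A∩B| / |A∪B|. The null
draws 5000 pairs of uniform random subsets of sizes |A| and |B| from U —
each subset without replacement, the two subsets independent of each
other — and records the same fraction; the p-value is the proportion of
null fractions strictly exceeding Fo, and BH correction is applied across
all pairs. Three deliberate choices:

* **Denominator.** "Shared over all included ids" could mean |A∪B| or
  |A|+|B|. Both are strictly increasing in k = |A∩B| at fixed set sizes,
  so p-values are identical; the package defaults to the Jaccard form and
  exposes `denominator = "sum"` for the other reading. Only the reported
  Fo value differs.
* **Tie rule.** The default is the strict "exceeds" count. On a discrete
  statistic this is anti-conservative: the test rejects at nominal 0.05
  with true probability ≈ 0.07 at a universe of 1000 and set sizes ≈ 100
  (computable exactly from the hypergeometric tail). The
  `greater_equal` tie rule is the conservative standard for permutation
  p-values and brings the rate to ≈ 0.036; `smoothing = "add_one"`
  additionally avoids reporting exactly zero. Both are off by default to
  match the strict definition, and the calibration study below reports
  the consequence honestly.
* **Universe.** U is always an explicit input (the housekeeping promoter
  list); no default size is assumed, and whether to restrict U to
  promoters bound by at least one protein in the panel is the caller's
  decision.

Because Fo is monotone in k, the test statistic could equally be the raw
intersection count — `sample_null(..., stat = "count")` exists precisely
so the equivalence is testable, and the closed-form oracle
`hypergeom_tail()` gives the exact large-sample limit of the empirical
p-value.

Reproducibility: each protein pair's null draws come from an RNG
substream seeded by a deterministic hash of the two protein names mixed
with the master seed, so adding or removing a protein from the panel
never changes the other pairs' p-values. The null sampler itself is
compiled (a partial Fisher–Yates shuffle using R's RNG), which keeps the
calibration and power studies below fast enough to run routinely.

## The synthetic-data generator

The generator emulates exactly the statistical structure the test
assumes: binary binding per housekeeping promoter with controlled
marginals and controlled pairwise association.

* Gene models sit in equal non-overlapping slots along each chromosome
  (TSSs near-uniform, spans never overlapping), with random strand and an
  exact housekeeping count. Default geometry: 2 chromosomes of 1 Mb, 1000
  genes, half of them housekeeping — promoter windows of neighbouring
  genes then never collide, so annotation is unambiguous.
* Binding indicators come from a bivariate Bernoulli: the first protein
  is the reference; each other protein is drawn conditionally on it so
  the pair attains marginals (p1, p2) and odds ratio θ, using the
  closed-form joint p11 = (S − √(S² − 4θ(θ−1)p1p2)) / (2(θ−1)) with
  S = 1 + (p1+p2)(θ−1). θ = 1 gives independence. With more than two
  proteins, pairs are generated against the reference only — pairwise
  dependence is sufficient to exercise a pairwise test, and higher-order
  structure is a documented non-goal. Default marginal: 0.1.
* Peaks are materialised at bound TSSs (default width 100, summit jitter
  0); with the summit anchor, annotation recovers the bound sets exactly
  whenever jitter ≤ the promoter half-width, and the generator warns
  when that guarantee is lost.
* Genome sequence is i.i.d. from the PWM background, with one
  PWM-sampled word implanted per selected peak at a recorded position and
  strand.

What the synthetic data does *not* emulate — read-level noise, peak-width
variability, GC structure, copy number, co-binding driven by shared
motifs rather than by statistical association — bounds what green tests
mean: they verify the *inference machinery* (coordinates, recovery,
calibration, power, exactness), not robustness to upstream artefacts of
real ChIP-seq.

## Calibration, power and problem sizes

The statistical studies the suite and `scripts/acceptance.R` run, at the
sizes they use:

* **Oracle agreement** — empirical p versus `hypergeom_tail()` on a 24-cell
  grid of (|U|, N1, N2, k), 5000 draws per cell, within three binomial
  standard errors.
* **Type-I error** — 1000 independent θ = 1 pairs on a universe of 1000
  housekeeping promoters at marginal 0.1 (the calibration studies set the
  housekeeping fraction to 1 so the universe size equals the gene
  count). Under the default strict tie rule the measured rate is ≈ 0.08
  against a nominal 0.05 — the discreteness effect computed exactly
  above, reported as-is; the `greater_equal` rule measures ≈ 0.033 and is
  covered by its own test.
* **Power** — 200 paired-seed replicates at θ ∈ {1, 2, 4, 8}: rejection
  rates rise monotonically and reach ~1 by θ = 4 at these sizes.
* **Exactness** — 20 random PWMs of length ≤ 8 against exhaustive
  enumeration of all 4^L words; 1000 random interval instances against
  brute-force overlap and connected-component oracles.

These sizes were chosen so each study carries real statistical weight
(binomial noise on 1000 replicates is ±0.7 percentage points) while the
whole suite stays something a developer runs on every change.

## Known limitations

* The test is pairwise; conditional or three-way colocalization is out of
  scope.
* The empirical p-value's floor is 1/n_samples; pairs far beyond that
  floor all report 0 (or 1/(n+1) with add-one smoothing) and are
  distinguished only by Fo.
* Heterochromatin is a fixed coordinate map, not an inferred state.
* The DE module consumes a finished differential-expression table;
  count modelling, normalisation and dispersion estimation belong to the
  upstream tools that produce it.
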