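---
title: "MS/MS-seeded peak grouping and spectral library matching: methods"
author: "lcmsmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MS/MS-seeded peak grouping and spectral library matching: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmsmatch)
```

# The problem

Untargeted metabolomics and lipidomics experiments acquired in
data-dependent mode (DDA) produce MS1 survey scans interleaved with MS2
fragmentation scans of selected precursors. Annotating such a run means
(i) deciding which regions of (m/z, retention time) space contain real
chromatographic peaks, (ii) collecting the MS2 scans that belong to each
peak, and (iii) comparing the resulting fragmentation spectra against
spectral libraries. `lcmsmatch` implements this pipeline headlessly, with a
deterministic synthetic-data generator so every stage can be validated
against known ground truth without downloading any raw data.

# MS2-seeded slicing

Rather than scanning the full MS1 plane, the pipeline only looks where the
instrument itself decided something was worth fragmenting: every MS2 scan
seeds a rectangular *slice* centered on its precursor m/z and retention
time. Requiring each final peak group to carry at least one MS2 scan both
improves annotation quality and shrinks the search space.

Slices are merged whenever they overlap in *both* m/z and retention time,
regardless of the sample they came from, and merging repeats until no two
slices overlap. Three numerical choices matter here:

* **Half-widths.** Defaults are 20 ppm in m/z and 0.5 min in RT
  (`slicing` arguments `mz_half_width_ppm`, `rt_half_width_min`). The ppm
  width is converted to Th at the seed precursor and frozen; merged slices
  union their Th bounds and are never re-centered, so the merge has a
  well-defined fixed point.
* **Closed intervals.** A shared endpoint counts as overlap. This makes
  endpoint ties merge deterministically instead of depending on float
  comparison order.
* **Fixed-point iteration.** Unioning two slices can create a new overlap,
  so merging iterates (connected components of the overlap graph, then
  bound unions, repeated to stability). Correctness is defined by a
  brute-force oracle — repeatedly union any overlapping pair until stable —
  and the test suite checks agreement on 1,000 random slices under input
  shuffles, plus idempotence and seed conservation.

# EIC extraction, peak detection, grouping

For each merged slice, each sample contributes an extracted ion
chromatogram (EIC): at every MS1 scan inside the slice RT range, the sum of
centroid intensities inside the slice m/z window. Per-sample EICs are
summed on the union of their RT grids with no interpolation — a sample
with no scan at a grid point contributes zero, so no signal is invented.

Peak detection on an EIC is deliberately simple and fully specified:
moving-average smoothing (default window 5 scans), apexes at local maxima
of the smoothed trace above `min_height` (default 1e4), boundaries
extending to the nearest local minimum or zero on each side. Peak groups
are the peaks of the *merged* EIC; each sample's own peaks join the group
whose RT window contains their apex. MS2 scans are then assigned to the
group with the nearest apex, within a tolerance (default 0.5 min), each
scan to at most one group. Groups that end with no MS2 scan are discarded
by default, or retained as explicitly unannotated.

# Consensus spectra

All MS2 spectra assigned to a group are combined: fragments pooled across
scans are clustered greedily in descending intensity order with a ppm
window (default 20 ppm), each cluster becoming one consensus peak at the
intensity-weighted mean m/z with the mean member intensity. The default
`min_presence_fraction = 0` keeps every fragment, including ones seen in a
single scan. This is intentional: the hypergeometric score tolerates
chimeric contamination, so discarding genuine low-presence fragments costs
more than keeping noise. Users who rely on intensity-based scores can
raise the presence threshold.

# Similarity scores

Matching is greedy and one-to-one: reference fragments in descending
intensity order each claim the nearest unmatched observed fragment within
the ppm tolerance, ties resolving to the lower m/z. One-to-one matching is
what makes the matched count k well defined. Five scores are computed from
a match:

* **Hypergeometric score (HGS).** With m observed fragments, n reference
  fragments, k matches, and N non-overlapping m/z buckets,

  $$\mathrm{Score} = -\ln \frac{\binom{m}{k}\binom{N-m}{n-k}}{\binom{N}{n}}.$$

  N models the number of places a fragment could land by chance and scales
  with resolving power; for high-resolution data (>50,000 RP) it should be
  on the order of 1e5 (the default) or higher. The score uses no
  intensities, which makes it usable with intensity-free in-silico
  libraries and robust to chimeric spectra: contaminant fragments enter
  only through m, costing $\ln\binom{m}{k}$ rather than collapsing the
  score the way unmatched intensity collapses a cosine. Implementation
  note: the log-probability is evaluated as a product of bounded ratios
  with `log1p`, not as a difference of two large log-binomials, so
  near-zero scores retain full relative precision (the suite checks
  agreement with an exact big-integer oracle to 1e-9 relative over a
  ~3,000-tuple grid). Invalid tuples (e.g. n − k > N − m from a
  too-small N) raise an error rather than being clamped: silent clamping
  would hide a misconfigured N.
* **MVH (intensity-class weighted).** Reference fragments are split into
  three intensity classes by rank; the score is the negative log of the
  multivariate hypergeometric probability
  $\prod_c \binom{n_c}{k_c}\binom{N-n}{m-k}/\binom{N}{m}$.
  With a single class this reduces *exactly* to the HGS by the symmetry of
  the hypergeometric probability in m and n — that reduction, and an exact
  three-class oracle value, are tested. The three-class split is this
  package's declared interpretation of the intensity-weighted variant.
* **Dot product (cosine).** Cosine of intensity-power-weighted spectra
  (default power 0.5; 1.0 recovers the plain cosine); matched pairs feed
  the inner product, all fragments feed the norms.
* **Fraction of reference fragments matched** (k/n) and **fraction of
  reference TIC matched** (matched reference intensity / total reference
  intensity).

# Library search

Candidates are library entries whose precursor m/z lies within
`precursor_tol_ppm` (default 20) of the group's seed-precursor mean — the
slice is precursor-centered, so the seed mean is the natural query, not
the peak apex m/z. Results rank by score, ties broken by higher k and then
compound name. The name tie-break is arbitrary and documented as such:
isomers with identical spectra (common in lipidomics) are *not*
disambiguated. `min_score` defaults to 0 (accept everything); choosing a
threshold is the Retention Balance Point's job, below.

# Cross-library concordance and the Retention Balance Point

When two libraries annotate the same features, each feature is either an
agreement (same annotation) or a disagreement. Lacking a practical false
discovery rate for small-molecule annotation, the package computes, per
library, the score threshold maximizing

$$\frac{\#\{\text{agreements} \ge t\}}{\#\text{agreements}} -
  \frac{\#\{\text{disagreements} \ge t\}}{\#\text{disagreements}},$$

the Retention Balance Point (RBP). The objective is a step function
changing only at observed scores, so candidates are exactly the observed
values; ties resolve to the lowest threshold, which retains the most
annotations at equal objective. Annotations scoring below their own
library's RBP are discarded; a feature annotated by both libraries but
passing only one threshold counts as annotated by that library alone.
Agreement between surviving pairs is classified on a hierarchy — same
class, + same adduct, + same summed composition (e.g. PC 34:1), + same
chain composition (e.g. PC 16:0/18:1) — with adducts compared by strict
string equality. Compound-level counts collapse adduct forms, treating a
compound as (class, chain or summed composition).

# In-silico lipid fragmentation libraries

The generator enumerates species per class over a chain space
(default: even carbons 12–22, 0–6 double bonds; chains are unordered, so
PC 16:0/18:1 and PC 18:1/16:0 are one species) and evaluates per-class,
per-adduct fragment rules from a plain YAML file
(`system.file("extdata", "lipid_rules.yaml", package = "lcmsmatch")`).
Shipped classes: PC, PE, PG, TG, SM (d18:1 base), CE — a representative
subset chosen so every rule kind (head-group ions, fixed neutral losses,
per-chain acyl losses, carboxylate anions) is exercised; the engine is
class-agnostic and new classes are added by editing the data file, not the
code. Chain validity is enforced as double bonds ≤ carbons/2, which keeps
the enumeration a clean product space (6 × 7 = 42 chain types, hence
`choose(43, 2) = 903` diacyl-PC species by the multiset formula).

Elemental bookkeeping is closed form: species formula = backbone + Σ fatty
acids − one water per chain; monoisotopic masses come from a single atomic
mass table (1e-6 Da), audited in the tests against an independent mass
oracle and literature precursor values (e.g. PC 16:0/18:1 [M+H]+ at
760.5851, the 184.0733 phosphocholine head-group ion). Adducts without
their own template *borrow* one ([M+NH4]+ borrows [M+Na]+;
[M+FA−H]− donates to [M+Cl]−-style adducts), shifting
charge-carrier-retaining fragments by the difference of adduct deltas and
leaving charge-carrier-independent ions (e.g. the CE 369.3516
cholestadienyl cation) fixed. This encodes the working assumption that
these adducts fragment alike; it is an approximation, flagged per rule.

Relative intensities are nominal template values on a 0–100 scale — they
are package defaults meant to be edited, not measurements; fragment *mass*
identities follow standard lipid fragmentation chemistry. A class may be
declared `mass_only`, emitting uniform intensities, for classes whose
fragment masses are predictable but whose intensities are unknown. Every
spectrum is normalized to base peak 100 and peaks below 0.2% of the base
peak are removed (the PC [M+H]+ template deliberately contains a
sub-cutoff peak to pin this behavior in tests).

# The synthetic-run generator

`generate_run()` plants library compounds into a multi-sample DDA run:
Gaussian elution profiles (default sigma 0.05 min) on a fixed MS1 grid
(default 1 s), uniform random retention times, per-sample heights
(1e5–1e6) with log-normal intensity noise (CV 0.1), 3 ppm m/z jitter, a
flat baseline of random centroids, and DDA-style MS2 triggering: top-k per
cycle above a trigger height, with a 15 s dynamic-exclusion window. A
configurable *chimerism rate* merges a co-eluting compound's fragments
into an MS2 scan, emulating co-isolation. All draws derive from one seed
through R's default Mersenne-Twister generator, so a seed fixes the run
byte-for-byte across platforms.

Two generator choices deserve explanation:

* **Precursor separation floor.** Planted compounds are picked with
  pairwise precursor separation of at least 50 ppm, emulating a spike-in
  panel of distinct standards. Lipid libraries contain exact-mass isomer
  sets that no spectral method can separate; without the floor, an
  identification benchmark measures isomer name collisions rather than
  pipeline correctness.
* **What the generator does not emulate:** isotope envelopes, adduct
  co-detection, RT drift between samples, detector saturation, and
  profile-mode peak shape. Passing the end-to-end benchmark therefore
  demonstrates the pipeline's internal consistency on idealized
  chromatography, not performance on real instrument data.

# Validation scale and known limitations

The test suite validates: the HGS against an exact big-integer oracle
(~3,000 tuples, ≤1e-9 relative); slice merging against a brute-force
fixed-point oracle (1,000 random slices, 10 shuffles); the RBP against an
exhaustive sweep (1,000 random score sets) and its recovery of a planted
3-sigma separation (threshold within (15, 25) across 1,000 seeds);
end-to-end identification of 20 planted compounds in 3 samples (100%
grouped with MS2, 100% correct rank-1 in the shipped configuration); and
format round-trips (msp, SQLite, mzML) at 1e-6 relative. These problem
sizes were chosen to exercise every code path while keeping the default
suite in the low minutes.

Known limitations: no RT alignment across samples; no centroiding
(vendor-centroided input is assumed, profile data is accepted with a
warning); no isotope-pattern grouping; no decoy-based FDR; isomer
tie-breaks are lexicographic; the shipped lipid classes are a subset and
their intensity templates are nominal. On chimeric data the dot product
degrades by design of the statistic, not by a flaw in its implementation —
the package's benchmark shows the hypergeometric score's precision is at
least the dot product's at matched recall, which is the motivation for
making HGS the default score.
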