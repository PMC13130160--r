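---
title: "Detecting tire-wear particles in tissue: simulation and classification methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tire-wear particles in tissue: simulation and classification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`twpscan` reimplements, on fully synthetic data, a workflow for detecting
tire-wear particles (TWPs) in zebrafish gut sections from laterally
resolved LA-ICP-MS elemental images. This vignette documents the
measurement model behind the simulator, the parameters that matter, the
numerical conventions, and the design decisions taken where more than one
reasonable choice existed — together with what the synthetic data can and
cannot demonstrate about real measurements.

## The measurement model

A focused laser (7 µm spot) rasters the section in parallel lines at
70 µm/s while an ICP-MS quadrupole cycles through eight isotopes —
^13^C, ^64^Zn, ^48^Ti, ^92^Mo, ^121^Sb, ^142^Nd, ^197^Au, ^208^Pb — in a
100 ms cycle. Because the stage moves exactly one pixel pitch (7 µm) per
cycle, one cycle maps to one pixel; `raster_params()` enforces this
"no-bleeding" identity `scan_speed × cycle_time = pitch` as an invariant.
The simulated per-cycle expectation is

* the material level under the spot footprint (a circle of diameter
  `spot_um` centered on the pixel center, area-averaged over the level map;
  with spot ≤ pitch the footprint stays inside its own pixel and averaging
  is the identity),
* convolved along the scan direction with a normalized single-exponential
  washout kernel (time constant `0.1/ln(100)` s ≈ 21.7 ms, so 99 % of the
  aerosol arrives within one cycle, consistent with a washout time below
  100 ms; truncated at five constants and renormalized so total expected
  counts are conserved),
* plus a per-isotope gas-blank background rate,
* then Poisson-sampled (counting statistics dominate at trace levels;
  detector dead time and flicker noise are not modeled).

Au spikes are injected at the first and last cycle of every line — the
instrument-side line markers used to synchronize the transient signal with
the laser log. Cycles between lines carry only washout tail and background
and are discarded during reconstruction rather than folded into edge
pixels, since residual tail is an instrument artifact, not sample signal.

Bracketing NIST612 standard runs model day-to-day sensitivity changes as a
per-isotope multiplicative drift. The normalization step uses the
arithmetic mean of the before/after standard means as the sensitivity (the
alternative, time interpolation, changes nothing for the constant-drift
runs simulated here and is deliberately not the default); the relative
variation between the standards is recorded and flagged above 20 %,
matching the acceptance level of the acquisition protocol, with processing
continuing under a warning.

## Phantoms and the fingerprint registry

`default_fingerprints()` defines lognormal expected-signal models (median
counts/cycle, lognormal spread, marker-presence probability) for the 13
bulk materials. Absolute concentrations of the marker elements in tire
rubber are not available (Zn is reported only at the g/kg level, Pb at
mg/kg), so the absolute scale is a free simulator parameter; what the
registry fixes is the qualitative multielement ordering: TWP dominated by
Zn; lake sediment by Ti; river sediment by Nd; road dust by Pb and Mo; PET
by its Sb catalyst; paraffin a near-blank; gut tissue carrying biogenic
levels that overlap TWPs element by element. Zn, Ti and Pb are present in
every TWP (Zn as the ubiquitous vulcanization activator, with a tight 5 %
lognormal spread; Ti and Pb as systematic rubber/road constituents with
10 % spreads), while Mo, Sb and Nd are carried by only half of the
particles (50 % presence, 35 % spread) — individual particles from
different tires carry different additive packages, which is what makes the
panel multivariate.

Phantom scenes place non-overlapping circular particles (diameters from a
truncated normal, 80 ± 39 µm on [14, 355] µm — the administered TWP size
distribution) uniformly in the allowed region, largest first so that big
particles are not crowded out; placement failing 1000 attempts raises an
error rather than silently under-filling. Default scene sizes are chosen so
the full train-and-apply pipeline runs in seconds per seed: the
TWP-in-paraffin training/test scene is 150 × 150 px (1.05 × 1.05 mm, 60
particles, ≈ 30 % coverage, which leaves several thousand pixels above the
Zn training threshold), blank guts are 100 × 100 px and TWP-in-gut scenes
120 × 120 px.

Gut tissue is not homogeneous. Three structural features of the synthetic
tissue are load-bearing for the classification problem and deserve
explicit statement:

* **Element-specific biogenic hotspots.** Separate Gaussian hotspot fields
  for Zn (epithelial Zn-rich regions), ^48^Ti (Ca-rich calcified spots seen
  through the ^48^Ca interference on this channel) and Pb drive each single
  element to TWP-like levels somewhere in blank tissue. This is what makes
  every univariate classifier fail — the Zn-only threshold baseline
  false-fires on every blank gut — while leaving the joint pattern
  separable. The fields of different elements are spatially disjoint
  (distinct tissue structures; centers at least 12 px apart), so no gut
  pixel carries a TWP-like multielement co-elevation.
* **Bracketing supports.** The gut hotspot amplitudes for Zn and Ti are set
  so the blank-tissue distribution spans and exceeds the corresponding TWP
  band (hotspot Zn peaks at ≈ 26× base versus the TWP band at ≈ 20× ; Ti
  peaks at 7× base). A classifier trained on one gut therefore sees
  class-2 examples on *both* sides of the TWP band, and no "just above the
  training maximum" region exists in which a new tissue pixel could only be
  explained as a particle. Pb hotspots overlap the TWP Pb band for the same
  reason.
* **Confounder particles.** Blank and exposed guts contain feed-like
  particles (a compositionally uniform pellet product with mineral-premix
  Ti and Pb inside the TWP bands but low Zn). They play the role of the
  natural particles visible in real blank guts and force the classifier to
  learn the full multielement rule rather than any single-marker shortcut.
* Gut trace levels of Mo, Sb and Nd are set at the gas-blank level —
  indistinguishable from a marker-absent TWP pixel — so that one-count
  Poisson fluctuations in these channels carry no class information.

A smooth low-amplitude (± 8 %) modulation field adds biological
level variation across each section.

## Reconstruction

Line boundaries are the intensity-weighted centers of Au-spike groups
(cycles above `blank mean + 10 · blank sd`, merged when consecutive); the
per-line clock offset against the laser log is summarized by its median,
and each line receives exactly `floor(line_length/pitch)` cycles. Offsets
spreading over more than two cycles, or a spike count inconsistent with the
log, abort reconstruction — these indicate desynchronization that no
median offset can repair. Rasters are unidirectional by default ("parallel
line scans"); serpentine acquisition is supported behind a flag and flips
even lines to a common orientation. With noise disabled the
simulate-reconstruct round trip reproduces the footprint-averaged phantom
to machine precision; with washout enabled the deviation is bounded by the
kernel tail mass (≈ 1 %).

## Bulk chemometrics

Bulk runs are twenty 5 mm line scans per material at 70 µm spot and
700 µm/s (≈ 7 s and 71 cycles per line). Levels are drawn per line —
with marker-presence draws per line for the particulate TWP material — and
each line is averaged after background correction and normalization,
giving a 260 × 6 feature table. The analysis conventions:

* columns are standardized (sample sd, n−1 denominator) before PCA and
  clustering;
* PCA signs are fixed so each component's largest-magnitude loading is
  positive, making biplots reproducible; biplots scale loadings by the
  component standard deviations (correlation-biplot convention,
  configurable);
* hierarchical clustering uses Euclidean distances with Ward's linkage in
  the **Ward.D2** convention (squared-distance Lance–Williams update,
  heights on the distance scale). The variant is not dictated by the
  method description, so it is fixed here and verified in tests against an
  explicit brute-force agglomeration using
  `d(A,B) = sqrt(2|A||B|/(|A|+|B|)) · ‖μ_A − μ_B‖`.

Under the default registry the dendrogram root separates the
inorganic-rich materials (lake sediment, river sediment, road dust — which
share a strong lithogenic Ti/Nd/Pb profile on top of their individual
maxima) from the organic-rich remainder, and the TWP replicates form a
pure subcluster inside the organic branch, driven by their Zn signal.

## The pixel classifier

Training data follow the study design exactly: class 1 is 4000 pixels
drawn uniformly without replacement from the pixels of a TWP-in-paraffin
image whose Zn signal exceeds `0.75 · P95(Zn)` of that image; class 2 is
4000 pixels drawn uniformly from a blank-gut image. The percentile uses
linear interpolation between closest ranks (R's type-7 quantile; the
convention is stated because the originating software is unspecified), and
the mask rule is *strictly greater than* the threshold. Features are the
six marker elements, standardized with center/scale fitted once on the
pooled 8000-pixel set and frozen; predictions on any later image reuse the
training parameters, the only self-consistent choice when the training
standardization is never refit.

The forest draws `round(r · n)` rows per tree — without replacement, the
natural reading of a subsampled "percentage of the training set"; a
bootstrap flag is available — with all six features available at every
split (Gini, unbounded depth): the forest's randomness is row subsampling
only, matching a description in which the tuned quantities are the tree
count and the subsample fraction. The defaults are the tuned values
`n_trees = 65`, `r = 0.58`. Out-of-bag (OOB) error is balanced across
classes, averaged over five seeds during tuning; the error surface over the
default grid (trees 5–200 by 5, r 0.10–0.90 by 0.04) is computed from the
cumulative error trace of one maximal forest per (r, seed), which is exact
and two orders of magnitude cheaper than refitting per grid point. Tied
pixel votes go to class 2 — the workflow prioritizes avoiding false
positives. A deliberately univariate baseline, `classify_zn_threshold()`,
calls TWP wherever Zn alone exceeds the stored training threshold and
exists to demonstrate that no single marker suffices.

## Particle analysis and the detection limit

Classified masks are grouped into particles by connected components
(8-connectivity by default; 4 available — the grouping rule is a package
choice, since pixel clusters do not define particles by themselves), sized
by the equivalent circular diameter of their pixel area. Truth matching
uses maximal pixel overlap, with a truth particle counted as detected when
at least one predicted pixel lies inside it (an overlap-fraction criterion
is configurable).

The geometric detection limit asks for the smallest disk diameter that
guarantees, for *every* raster alignment, at least one laser shot fully
contained in the particle — the condition for at least one pure training
-like pixel. At the imaging settings the laser fires every 0.7 µm along a
line (100 Hz at 70 µm/s), quasi-continuously relative to the 7 µm spot, so
the binding constraint is the across-scan line spacing: the disk center
lies within `pitch/2` of some line, and the spot at the closest point of
that line is contained iff `diameter ≥ spot + pitch`. This yields 14 µm at
7 µm spot and pitch — twice the spot size — and is verified in tests by a
brute-force sweep over random raster offsets with exact containment
geometry. Registration onto reference micrographs uses least-squares
affine fits to 3–8 control-point pairs, with the residual RMSE defined per
coordinate (so that with 8 points and isotropic noise σ it concentrates at
`σ·sqrt(1 − 6/16)`).

## What the synthetic data do and do not show

The simulator reproduces the statistical structure the analysis relies on:
Poisson counting noise at realistic count rates, washout smearing,
sensitivity drift, single-element overlap between tissue and particles,
per-particle additive heterogeneity, and natural confounder particles. It
does **not** reproduce: irregular particle morphology (particles are
disks; real TWPs are irregular with complex surface texture), beam-profile
and ablation-depth physics (information depth differences between SEM and
LA-ICP-MS are out of scope), spectral interferences beyond a lumped
elevated gut ^48^Ti channel, detector dead time, or within-image drift.
Consequently, passing tests demonstrate that the *pipeline logic* is
correct and that the classifier achieves zero false positives and
near-complete interior recall under the stated noise model — not that any
particular instrument will achieve those error rates on real tissue, where
margins depend on true additive concentrations and matrix effects.

Test problem sizes are chosen for fast, stable statistics: unit tests use
40–60 px scenes; the end-to-end classification checks run the default
150 × 150 / 100 × 100 px scenes over 20 seeds; clustering checks use the
full 13 × 20 bulk design per seed. The detection-probability study uses
fixed-diameter scenes over the grid {7, 10, 14, 21, 35, 80} µm, bracketing
the 14 µm limit.
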