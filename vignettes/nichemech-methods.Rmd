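---
title: "Quantifying adhesion mechanics and migration in the neural stem cell niche"
author: "nichemech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adhesion mechanics and migration in the neural stem cell niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemech)
```

## Scope and motivation

Aging changes how neural stem cells (NSCs) of the subventricular zone (SVZ)
adhere to and move through their niche: quiescent NSCs and niche astrocytes
drift away from the ventricle wall, while activated NSCs and progenitors
become more adhesive, produce more traction force, and migrate less. This
package implements the quantitative readouts used to measure those
phenotypes — molecular tension-sensor force mapping, detachment and
dispersion assays, time-lapse migration tracking, section geometry, and
single-cell adhesion-signature scoring — together with exact nonparametric
tests and a synthetic-data generator, so every stage can be exercised and
validated against known ground truth without any raw microscopy data.

## FRET tension-sensor force mapping

A molecular tension sensor is a surface-bound peptide presenting an
integrin-binding RGD motif, with a donor/acceptor fluorophore pair flanking
an elastic domain. Unloaded, the fluorophores are close and FRET efficiency
is high; when a cell pulls on the ligand the sensor extends and efficiency
drops, so *low efficiency means high force*.

`computeEfficiency()` uses the sensitized-emission proximity ratio

$$E = \frac{A'}{A' + \gamma D'}, \qquad
  D' = D - b_D,\quad A' = A - b_A - \beta D',$$

with per-channel backgrounds $b_D, b_A$, donor-to-acceptor bleed-through
$\beta$ (default 0) and detection-ratio $\gamma$ (default 1). Pixels whose
total corrected signal falls below an explicit intensity floor carry no
usable sensor signal and are masked invalid rather than given a meaningless
ratio. Efficiencies are clamped to $[0,1]$.

Forces come from a monotone calibration curve (force up, efficiency down)
inverted piecewise-linearly by `forceFromEfficiency()`; efficiencies above
the zero-force node clamp to 0 pN and below the terminal node to the
maximal calibrated force. Calibration curves are sensor-construct specific
and must be supplied by the user (`readCalibration()`); the packaged
`defaultCalibration()` — six nodes from 0 pN/E = 0.90 to 10 pN/E = 0.15 —
is a synthetic curve with the right qualitative shape, used only for
examples and tests.

Adhesion segmentation (`segmentAdhesions()`) thresholds the force map
inside the cell mask, groups candidate pixels with 8-connectivity, and
drops components below a minimum area (default 0.5 µm², the conventional
"analyze particles, size 0.5–infinity" floor for focal adhesions). Touching
adhesions can be divided by a watershed of the force landscape seeded at
local force maxima; the seed tolerance (minimum force drop between two
maxima, default 10% of the supra-threshold range) controls how aggressively
plateaus are split. Because thresholding the force map at $F_t$ is
identical to thresholding the efficiency map at $\mathrm{cal}(F_t)$, a
force threshold can equivalently be stated as an efficiency cutoff; the
default corresponds to an efficiency 0.1 below the resting level.

Per-cell summaries (`profileCell()`) call a cell *force-producing* when at
least one adhesion survives segmentation. Whether a cell's average adhesion
force should weight adhesions by pixel count or equally is genuinely open;
the pixel-weighted mean is the default and the unweighted per-adhesion mean
is available (`weighting = "adhesion"`). A cell with no adhesions reports
its average force as absent (`NA`), never as 0, so group means are not
diluted. `compareGroupsForce()` compares per-animal mean forces with a
two-tailed Mann–Whitney test and force-producing prevalence with a
two-sided Fisher exact test on the pooled cell table.

## Assay quantifications

* **Detachment** (`percentRemaining()`): 100 × cells after / cells before
  enzyme treatment, counted by `countParticles()` inside
  `restrictMargin()` (a border exclusion, conventionally 250 px, against
  well-edge debris).
* **Centrifugation** (`areaFraction()`, `percentAreaRemaining()`): percent
  well area covered by cells inside a centered `cropCircle()` ROI
  (conventionally radius 700 px), before vs after spinning. The remaining
  fraction is computed as after/before, consistent with the detachment
  convention; the same ratio has circulated printed with the operands
  reversed, which the function documentation flags explicitly.
* **Matrigel dispersion** (`dispersionDistance()`): the maximum Euclidean
  distance from the initial spot perimeter to any cell pixel outside it.
  The perimeter is the set of foreground pixels 4-adjacent to background;
  distances are between pixel centers, via an exact Euclidean distance
  transform. Nested masks give monotone non-decreasing distances over time.
* **Masked intensity** (`maskedIntensity()`): summed intensity inside each
  cell mask divided by the cell's area, so the value is invariant to cell
  size; `normalizeToReferenceMean()` then expresses values relative to the
  reference group's mean within each experiment block.

Thresholds are always explicit arguments. `otsuThreshold()` is provided as
a convenience but is never applied silently, mirroring the practice of
fixing one threshold per experiment.

## Migration tracking

`linkDetections()` links per-frame detections by mutual nearest neighbors:
a link forms only when the track and the detection are each other's
closest candidate and the step is within `maxDisplacement` per elapsed
frame; tracks may bridge up to `maxGap` missing frames, and ties resolve
to the lowest detection index so linking is deterministic. Track *velocity*
is defined as mean instantaneous path speed — total path length over
elapsed time (`trackSpeed()`); this is the usual "track velocity"
semantics of commercial trackers, and net-displacement speed is available
as an option since the two differ for meandering cells. Tracks with fewer
than 5 detections are excluded as transient. Group comparisons average
track speeds per animal first (`summarizeByAnimal()`), so each animal
contributes one value to the Mann–Whitney test.

## Niche geometry

`distanceToBorder()` is the exact minimum point-to-segment distance from a
nucleus centroid to the traced ventricle-border polyline; the analysis is
2-D, on z-projected sections, and the polyline is taken as given (tracing
is manual upstream). Analyses are restricted to a 200 µm band from the
ventricle wall (`filterBand()`) to exclude striatal astrocytes; the filter
is boundary-inclusive and idempotent. Marker panels are closed decision
tables (`classifyCells()`): GFAP+/Ki67− → qNSC/astrocyte, GFAP+/Ki67+ →
aNSC (similarly for S100a6), and in the EdU panel EdU+/DCX+ cells are
neuroblasts regardless of Ki67 while EdU+/Ki67+/DCX− cells are aNSC/NPCs.
Vessel-adjacent cells are censored through an input flag — the adjacency
call is made by the experimenter, not computed. Region counts
(`countInRegions()`) use the even-odd rule with boundary points counted
inside, a deterministic edge convention; `labelingEfficiency()` divides
EdU+ by Ki67+ cells within the SVZ region.

## Single-cell signatures

`logNormalizeCP10K()` maps counts to $\ln(1 + 10^4 c/\text{total})$ —
natural log, matching the convention of the standard single-cell toolkits;
the base and scale are recorded in the result's metadata.
`signatureScore()` sums a cell's log-normalized values over a gene set
(e.g. GO:0007155 "cell adhesion"); genes absent from the matrix are
dropped with a reported count rather than silently, and an empty
intersection is an error. Before comparing cumulative score distributions,
the larger (young) population is downsampled to the size of its old
counterpart (`downsampleGroup()`, seeded, without replacement) so the
distributions are size-matched. `decileAssociation()` bins genes into ten
equal-count bins of promoter accessibility (stable tie order, bin sizes
differing by at most one) and summarizes expression per decile. Clustering,
cell-cycle scoring and differential expression are deliberately out of
scope; group labels arrive from upstream tools.

## Exact nonparametric tests

All group comparisons route through three tests. The Mann–Whitney U and
Wilcoxon signed-rank tests compute exact two-sided p-values
($\min(1, 2\cdot\text{one-sided})$) whenever the labeling/sign space is
small enough — at most $2 \times 10^5$ labelings, or 20 non-zero pairs —
and otherwise use normal approximations with tie and continuity
corrections; the branch taken is always reported. The exact branch counts
the full distribution of the (doubled, so ties give integers) rank sum
with a subset-sum dynamic program that is mathematically identical to
exhaustive enumeration but polynomial in cost, and handles ties exactly
through mid-ranks — the reason these are implemented here rather than
delegated to `stats::wilcox.test`, which abandons exactness under ties.
The Fisher exact test sums hypergeometric probabilities of all tables no
more probable than the observed one (relative tolerance $10^{-7}$ on the
comparison). The test suite checks all three against literal
`combn`/`expand.grid` enumeration oracles and `stats::fisher.test`.

## The synthetic-data generator

Each generator takes an explicit integer seed (Mersenne–Twister, restored
afterwards, recorded in outputs) and returns exact ground truth:

* **Tension-sensor images**: cells are disk footprints on a jittered grid;
  adhesions are ellipses rasterized at pixel centers (no anti-aliasing, so
  truth masks are exact), rejected and resampled if they leave the cell
  footprint, and kept two pixels apart so adhesions are spatially distinct,
  as focal adhesions are. True efficiency is the resting level outside
  adhesions and the calibration at the drawn force inside; expected
  intensities are $D = S(1-E)+B$, $A = SE+B$ and observed counts are
  Poisson. Defaults — 0.16 µm/px (typical ×100 TIRF), 2,000 signal and 100
  background photons per pixel, resting efficiency 0.90, forces uniform on
  2–8 pN, adhesion areas ≈ 0.6–1.9 µm² — are conventional imaging choices,
  not measured values; no optical PSF, drift, read noise or photobleaching
  is simulated, so robustness to *those* artifacts is untested.
* **Tracks**: a discrete 2-D Ornstein–Uhlenbeck velocity process with
  stationary Rayleigh speed of mean `meanSpeed` and persistence time 1 h
  by default, sampled every 0.5 h for 20 h (41 frames) to match the
  standard live-imaging protocol.
* **Detachment**: independent Bernoulli retention of each plated cell.
* **Sections**: per-group distance draws placed by perpendicular offset
  from a uniformly chosen point on the border; the recorded true distance
  is recomputed against the full polyline so it stays exact for curved
  borders.
* **Counts**: negative-binomial with log-normal baseline means
  (dispersion 0.3); gene-set genes in non-reference groups have means
  scaled by $e^{\text{effect}}$.

Because all of this is synthetic, passing tests demonstrate correctness of
the *computations* under the stated noise models — not performance on real
micrographs, which add segmentation, registration and staining variability
the generator deliberately omits.

## Numerical and design choices

* Coordinates are 0-based pixel centers, physical units via `pixelSize`;
  column index maps to x and row index to y.
* 8-connectivity for adhesion components (4-connected labeling plus a
  union-find merge of diagonal adjacencies); particle counting splits
  touching objects by a distance-map watershed.
* Efficiency maps clamp to $[0,1]$; force maps clamp to the calibrated
  range; invalid pixels propagate from efficiency to force to
  segmentation.
* Configuration files are YAML; `runPipeline()` executes the demo chain
  (synthetic images → efficiency → force → adhesions → profiles; tracks →
  linking → speeds; detachment → percent remaining) and its report is
  byte-deterministic under a fixed config. `validateConfig()` aggregates
  range errors and suggests the nearest valid key for typos.
* Problem sizes in the validation suite — 20 cells × 2 adhesions on a
  448 px field, 500 simulated tracks, 100-run power checks, 10,000-run
  size checks, 1,000 random point/polyline pairs — were chosen so the full
  suite completes in about two minutes while keeping Monte-Carlo error
  well inside the asserted tolerances.

## Known limitations

* The efficiency formula is a configurable proximity ratio; instrument-
  specific corrections (registration, flat-field, acceptor photobleaching)
  are out of scope and must be applied upstream.
* Exact adhesion thresholds and the FRET→force calibration are
  acquisition-specific inputs; published figures cannot be reproduced
  without them.
* The watershed split keys on force relief; two touching adhesions at
  indistinguishable force plateaus will merge (the generator therefore
  keeps synthetic adhesions separated).
* Tracking has no mitosis or merge/split handling and is quadratic per
  frame in the number of coincident detections.
* The centrifugation "percent remaining" operand order is ambiguous in
  circulation; this package fixes after/before and documents the choice.
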