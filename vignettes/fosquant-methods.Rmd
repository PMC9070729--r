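---
title: "Methods: semi-automated c-Fos quantitation with fosquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated c-Fos quantitation with fosquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosquant)
```

## The problem

Counting c-Fos-immunoreactive nuclei across many brain regions and many
animals by hand is slow enough that it limits study designs. `fosquant`
implements a semi-automated alternative for DAB-stained brightfield
sections, where c-Fos-positive nuclei appear as small dark blobs on a
light background. The pipeline has three stages:

1. **Detection** — on a cropped region image, estimate and remove the
   smooth illumination background, smooth, suppress specks, extract
   connected dark components, and keep those passing an area gate and a
   darkness gate.
2. **Registration and quantitation** — map named atlas region outlines
   onto the section with a fitted 3x3 projective transform (homography),
   count the accepted signals whose centroids fall inside each outline,
   and divide by the region's physical area to get signals/mm^2.
3. **Statistics and scoring** — Pearson correlation matrices between
   regional densities, autoscaling plus Ward hierarchical clustering for
   the two-way heatmap, and the social-interaction-test (SIT) scoring
   rules that define the behavioral subpopulations the densities are
   stratified by.

Everything runs on a `subjects x regions` density table at the end, so
each stage can also be used on its own.

## The detection model

A section crop is a `gray_image`: an 8-bit raster with a physical
resolution (default 0.000908 mm/px, a slide-scanner pixel size). The
filter chain, in fixed order, is:

* **Rolling-ball background subtraction** (radius 50 px). The smooth
  light background is estimated as the grayscale *closing* of the image
  by a flat disk of the given radius — the morphological formulation of
  the rolling-ball idea for dark-signal-on-light-background images — and
  removed as `img - background + 255`, clipped to [0, 255]. Background
  pixels map to ~255; a blob of depth *d* below its local background
  keeps value ~`255 - d`. The disk is discretized as
  `dx^2 + dy^2 <= r^2`.
* **Mean filter** (5x5) and **Gaussian filter** (sigma 1.3, 5x5,
  truncated and renormalized so constants are fixed points). Borders are
  edge-replicated for both.
* **Morphological opening** (5x5). Signals are dark, so a plain opening
  would erase them; the opening is therefore applied in the inverted
  (signal-bright) representation, which equals a grayscale *closing* in
  the original polarity. Small dark specks vanish; dark blobs wider than
  the structuring element survive. The operation is idempotent.
* **Candidate extraction.** The filtered image is binarized at intensity
  `< candidate_threshold` (default 200) and 8-connected components are
  labelled. The binarization cut is deliberately *looser* than the
  darkness gate below, so that classification — not binarization — is
  the binding filter; it is exposed as a parameter because reasonable
  values between the two gates give identical results on well-stained
  material.
* **Classification.** A candidate is a c-Fos signal iff its area lies in
  the closed interval [10, 550] px *and* its minimum intensity is
  strictly below 170. The area bounds are read as inclusive
  ("between"), the intensity cut as strict ("less than"). Minimum
  intensity is measured on the background-subtracted image *before*
  smoothing (smoothing biases extrema towards the background); a
  `intensity_source = "filtered"` switch measures it on the fully
  filtered image instead.

### Border handling

Mean and Gaussian filters replicate edges. For morphology the
neighborhood is clipped at the image border, which for disk and square
elements is identical to edge replication. An alternative — padding with
white (255) — was considered and rejected: it breaks the basic
invariants that a constant image is unchanged by opening and maps to
uniform 255 under background subtraction (corners would be distorted by
the pad value).

### What the filter order implies for small blobs

Because the opening runs with a 5x5 element *after* smoothing, dark
components whose core is at or below ~5 px across are strongly
attenuated and can fall out of the candidate set even when their raw
area passes the 10 px gate. This is a property of the published filter
order, not a bug: the 10 px gate removes debris from the candidate list,
while the opening sets the effective minimum size of a detectable
nucleus slightly higher. At the default scanner resolution a real
c-Fos-positive nucleus is comfortably above this limit; the synthetic
generator's default blob radii (3–6 px semi-axes, see below) deliberately
include the borderline so the behavior is visible in testing.

## Registration and quantitation

The original workflow warped atlas diagrams onto each section by hand.
`fosquant` keeps the geometry and replaces the hand-warping with its
computational content: the user supplies >= 4 point correspondences per
section and `estimate_homography()` fits the projective map by the
normalized direct linear transform (both point sets centered and scaled
to mean distance sqrt(2), 2n x 9 system solved by SVD, denormalized).
With consistent correspondences the fit is exact to machine precision;
with redundant noisy ones it is the algebraic least-squares solution.
One homography is fitted per section (per atlas plate); per-region
refinement is out of scope.

Region outlines are simple polygons in `(x, y) = (col, row)` 0-based
pixel coordinates; simplicity and nonzero area are enforced at
construction and re-checked after transformation (a projective map can
fold a polygon across its horizon — this raises an error rather than
silently producing nonsense areas).

Signal membership uses the even-odd rule on the signal *centroid*, with
the polygon boundary counting as inside (tolerance 1e-9). Centroid
membership is unambiguous for blobs straddling a border, which mask
overlap would not be. Region area comes from the shoelace formula;
`area_mm2 = area_px2 * resolution^2` and
`density = count / area_mm2`. With the default resolution a
1,000 x 1,000 px region is 0.824464 mm^2, so 100 signals give
~121.29 signals/mm^2.

## Validation metrics

Automatic output is compared to manual annotation at two levels, both
summarized as

* sensitivity (%) = 100 * TP / (TP + FN)
* precision (%) = 100 * TP / (TP + FP)

**Counts.** Manual clicks and automatic centroids are matched one-to-one
by *mutual nearest neighbors* within `max_dist_px` (default 10 px, about
a blob radius at the upper area gate). Matched pairs are TP, unmatched
manual clicks FN, unmatched automatic signals FP. The matching rule is a
design decision — how "the same signal" is decided is otherwise
unspecified — and is prominently configurable because it changes TP
counts; `max_dist_px = Inf` emulates a totals-only comparison. The rule
is symmetric, so swapping the two point sets exactly swaps sensitivity
and precision.

**Areas.** For region outlines, TP is the intersection area, FN the
manual-only area, FP the auto-only area. The exact intersection is
computed by Sutherland–Hodgman clipping, which requires one of the two
polygons to be convex (no polygon-clipping dependency is used); for two
non-convex outlines a dense point-sampling estimate
(`method = "grid"`) is provided and documented as approximate.

## Statistics

* **Correlations.** Pairwise-complete Pearson r between region columns;
  two-sided p from `t = r sqrt((n-2)/(1-r^2))` on n-2 df. No
  multiple-testing correction is applied (raw per-pair p values); the
  choice is intentional and should be corrected downstream if desired.
  Zero-variance regions produce missing entries with a warning.
* **Autoscaling.** Each region column is standardized to mean 0 and
  *sample* SD 1 (n-1 denominator, the convention of the statistical
  environments this mirrors). Constant columns are an error naming the
  region.
* **Clustering.** Agglomerative Ward on *squared* Euclidean distances:
  `hclust(dist(x)^2, method = "ward.D")`, the classical Ward
  formulation whose Lance–Williams update operates on squared
  distances (equivalent to `ward.D2` on unsquared distances up to a
  squaring of the merge heights). Heights are monotone non-decreasing.
  Determinism on ties follows `hclust`'s minimum-index convention; ties
  are measure-zero for continuous data. Rows with missing entries are
  dropped from clustering with a warning (correlations, by contrast,
  use pairwise deletion). The published procedure autoscales, averages
  within experimental group, then clusters group means; `autoscale()`,
  `group_means()` and `two_way_cluster()` compose in that order, and
  the reordered autoscaled matrix is what a heatmap should display.

## Behavioral scoring

The SIT arena is 40 x 40 cm with a caged stimulus mouse at one wall.
The interaction zone is the full-width band covering exactly 1/3 of the
arena area nearest the stimulus wall; the avoidance zone the band
covering exactly 1/4 farthest from it. Bands are the simplest geometry
satisfying the stated area fractions; the text does not draw the zones,
so corner-based variants are conceivable — the geometry is configurable
in principle but bands are the package default and the documented
choice. A position exactly on a zone boundary resolves towards the
stimulus side (deterministic tie-break). Occupancy integrates
sample-and-hold dwell times over the 150 s session, matching frame-based
tracking exports; time before the first sample is assigned to no zone.

A mouse is **avoidant** iff it spent strictly more than 50% of the
session in the avoidance zone. The four subpopulations follow from the
avoidant flags at the two test timepoints: `Av_both`, `Av_0W`, `Av_2W`,
`Non-Av` — a bijection over the four flag combinations. The
body-weight-change index is `(day8 - day1)/day1 * 100` (%).

## The synthetic-data generator

Every stage is testable without microscopy data:

* `make_section()` renders light-background crops: a tilted-plane
  illumination gradient (background 200 +/- 20 by default), dark
  elliptical blobs, and additive Gaussian speckle (SD 3). Blobs are
  hard-edged filled ellipses so the ground-truth masks and centroids are
  exact; the pipeline's own smoothing provides the soft edges. Default
  blob semi-axes are 3–6 px (areas ~29–113 px, inside the [10, 550]
  gate) and depths 110–150 gray levels — deep enough that
  `255 - depth < 170` holds with margin after subtraction, as for real
  near-black DAB nuclei; centers sit on a jittered grid with >= 36 px
  separation (>= 3 maximal blob diameters). Overlapping masks are
  permitted but flagged.
* `make_outline_pair()` plants a star-shaped simple polygon, a
  well-conditioned random homography (near-similarity with mild
  projective terms), and its image — the fixture for round-trip tests.
* `make_density_table()` draws multivariate-normal densities per group
  with a target inter-region correlation matrix (PSD-checked), truncated
  at 0. With the default means (~100) and SDs (~10) the truncation is
  essentially never active; planted correlations of 0.9 are recovered
  within 0.05 at n = 10,000.
* `make_trajectory()` builds piecewise-stationary paths spending
  scheduled times in each zone, sampled at 10 Hz.

What the generator does *not* emulate: hematoxylin counterstain,
out-of-focus planes, stitching artifacts, anisotropic staining, and
realistic nucleus texture. Passing the synthetic suite therefore
demonstrates algorithmic correctness against ground truth, not
performance on any particular slide scanner's output; on real material
the binding uncertainties are staining quality and the manual
correspondence points.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 100 random images up to
32 x 32 for exact filter-vs-oracle equality; 20 sections of 220 x 220 px
with 20 planted blobs plus 8 distractors each for detection recovery;
100 random planted homographies (recovery < 1e-6 px, polygon round
trips < 1e-9); 100 random 6 x 4 tables for merge-history equality
against an independent Lance–Williams implementation; 100 seeded
12-subject tables with a 4 SD offset in 6 of 8 regions for k = 2
partition recovery (4 SD places single-subject misassignment
probability below 1e-6, i.e. recovery is in the deterministic regime);
and one n = 10,000 draw for correlation convergence. These sizes were
chosen so each property is tested in a regime where its expected outcome
is unambiguous.

Tolerances: filter equality is exact for morphology and 1e-12 for
convolutions (summation order); homography fitting is validated at
1e-6 (fit) and 1e-9 (round trip); correlation/autoscaling at 1e-12;
polygon-boundary membership at 1e-9 px.

## Known limitations

* The rolling-ball estimate is the disk-closing formulation; it matches
  the classic sliding-paraboloid variants only approximately on strongly
  curved backgrounds.
* Exact polygon intersection requires one convex outline; two non-convex
  outlines fall back to grid sampling.
* Region polygons with holes are unsupported.
* The candidate binarization threshold, opening polarity, and the image
  on which minimum intensity is measured are configurable decisions, not
  inferred from any authoritative description; defaults are documented
  above.
* Group-difference inference (t tests, ANOVA, post hoc corrections) is
  deliberately left to standard tools on the exported density tables.
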