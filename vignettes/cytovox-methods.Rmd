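---
title: "Detect-then-segment 3D cytometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detect-then-segment 3D cytometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cytovox implements a two-step strategy for in vivo cytometry from 3D
confocal stacks of densely packed nuclei: candidate cell centres are first
*detected* by a sliding-window classifier, and each detection then *seeds* a
level-set active contour that grows against a preprocessed guide image until
it reaches a boundary or collides with a neighbouring contour. Per-cell
masks feed position and fluorescence quantification (DNA content, EdU
incorporation, cell-cycle phase indices) and nuclear-morphology phase
classification. Everything is exercised end to end on synthetic phantoms
with known ground truth.

This vignette documents the models, the tunable parameters and their units,
the numerical choices, and which design decisions were genuinely open.

## The synthetic phantom

`phantom_spec()` / `generate_phantom()` emulate a tube of densely packed,
roughly spherical nuclei, imaged at 0.25 um isotropic voxels:

* **Geometry.** Nuclei of mean radius 2 um (8 % radius jitter) are packed
  into a tube whose length is set so nuclei occupy ~55 % of the tube volume.
  Centres are placed by growth-based rejection sampling: at least
  `min_separation_um` (default 3.2 um) from every existing centre and within
  1.85 radii of the growing cluster, so the tissue is contiguous and the
  touching-masks graph connected, as in a real germ line. No two centres are
  ever closer than 1.5 um.
* **Truth masks.** Each cell's mask is the ball of its nuclear radius plus a
  quarter of the membrane thickness, with overlaps resolved by the
  nearest-centre rule. The extra quarter-thickness places the mask boundary
  halfway into the cytoplasmic gap between the nuclear surface and the
  membrane ridge: segmentation targets *cell* boundaries (as hand-drawn
  reference masks do), while the DNA signal stays strictly inside the mask.
* **DNA channel.** Chromatin is concentrated in a shell near the nuclear
  periphery, with phase-dependent texture: G1 nuclei carry 5-6 bright
  puncta in a thin shell, S nuclei are smooth with a thicker shell, G2
  nuclei carry 8-12 puncta in the thickest shell (the spatial extent
  ordering G1 < S < G2 observed in real data is therefore geometric, not
  just a brightness effect), and M nuclei are condensed compact cores.
  Per-cell summed DNA is scaled to the true content (2C for G1, 4C for
  G2/M, uniform between 2C and 4C for S) before any degradation, so content
  recovery can be tested exactly.
* **Membrane channel.** Walls are analytic Gaussian shells (sd =
  half-thickness, default 0.25 um) centred half a thickness outside each
  nuclear surface, plus explicit walls on the bisector plane of every
  overlapping pair. Building walls analytically (rather than by thresholding
  a discretised mask) makes them smooth and hole-free by construction.
* **Degradations.** Optional z-attenuation `exp(-lambda z)`, an arbitrary
  axial gain profile `g(d)` along the tube, a small optical blur
  (sd 0.15 um), Gaussian noise (sd 0.08 against shell intensities near 1,
  a signal-to-noise ratio of roughly 8-12) and optional Poisson resampling.

What the phantom does *not* emulate: a realistic point-spread function
(anisotropic, depth-dependent), autofluorescent background structure,
meiotic/crescent nuclear morphologies, or segmentation-relevant texture
*inside* the cytoplasm. Passing the phantom benchmarks therefore
demonstrates that the algorithms are implemented correctly and behave as
designed under controlled degradations - not that the default parameters
transfer to any particular real stain.

## Guide images

The membrane route (`make_guide_worm()`) chains four steps: sliding-window
sharpening (each voxel divided by the mean over a 2D square of one cell
diameter in its xy-plane, which cancels slowly varying gain including
z-attenuation), Hessian sheet enhancement at the membrane-thickness scale,
and a final blur. Sheetness uses the ordered eigenvalues d1 <= d2 <= d3 of
the spacing-aware Hessian and responds with
`-d1 * exp(-(d2/2d1)^2) * exp(-(d3/2d1)^2)` where d1 < 0; ordering
ascending makes d1 the most negative eigenvalue so bright sheets on a dark
background give positive responses.

Two numerical guards matter in practice:

* the local sharpening mean is floored at half the *global* mean intensity
  (besides the tiny 1e-6 x max guard). Without this, signal-free background
  is divided by a near-zero mean and its noise is amplified into spurious
  sheet responses that stall or leak active contours. The floor scales with
  the image, so invariance to global gain is preserved exactly; the
  z-gain-cancellation identity holds exactly only where local means exceed
  the floor.
* the final guide is rescaled so that boundary responses *saturate* at 1:
  the rescale threshold is the Otsu split between background and sheet
  responses, and values above it clip to 1. Well-stained guides look like
  this (boundaries saturate the intensity range), and both the degradation
  benchmark and the active-contour speed image assume it.

The DNA route (`make_guide_embryo()`) fits the multiplicative gain model
`m(x,y,z) = exp(c1 z)(c2 x + c3 y + c4)` to local means around detections.
The model is multiplicative in z but additive in x and y, so a pure
log-linearisation is invalid; the fit is nonlinear least squares seeded from
a log-linearised estimate, with a constant-model fallback for degenerate
inputs. The stack is thresholded at `k` times the model (k = 1/3 works well
in practice), median-filtered, inverted and blurred.

## Detection

Windows are two 2D patches (xy and xz planes) through the candidate centre,
each twice the cell diameter wide. Features are the mean xy brightness plus
one histogram-of-oriented-gradients block per plane: a 4 x 4 grid of
non-overlapping sub-windows, 18 unsigned orientation bins each,
L2-normalised per sub-window with the normalisation factor appended. The
grid size and the exact normalisation layout are package conventions
(documented configuration, not an inference about any particular prior
implementation).

A linear SVM scores windows as `w^T v`; the detection threshold tau is
applied post hoc so precision-recall sweeps need no retraining. Training
mines hard negatives iteratively (train, scan, add the highest-scoring
false positives farther than one cell radius from every positive, retrain)
until no negative scores inside the margin - which is mathematically
equivalent to training on all negatives at once, a property the test suite
asserts (cosine similarity > 0.999 against full-pool training). Positives
are augmented with left-right and top-bottom mirrored windows, and two
latent passes re-estimate each positive centre as the response maximum
within half a cell radius. Scanning runs at five geometric scale steps over
[0.7, 1.5] (implemented by scaling the window sampling), and detections
overlapping a higher-scoring detection within one cell radius are
suppressed greedily.

## Active contours

Masks are the negative region of per-cell embeddings phi evolved by

    dphi/dt = -g |grad phi| (1 - c1 k) + c2 grad g . grad phi

with `g` the inverted guide (low at boundaries), `k` the mean curvature
`div(grad phi / |grad phi|)`, c1 = 0.1, and the two-step schedule: 650
steps of dt = 0.15 with c2 = -1 (conservative: the advection term pushes
the front back from edge slopes, so masks stop short of boundaries), then
300 steps with c2 = +1 (refinement: the front is pulled onto boundaries and
pushed back past them). With the inside-negative convention the propagation
term carries a minus sign so that positive speed grows the mask. Voxels
claimed by two cells are frozen for both, and ownership stays with the
first claimant, so masks are disjoint by construction.

Numerics: Godunov upwinding for the propagation term, per-component upwind
differences for the advection term with each advection velocity clamped to
the CFL-stable magnitude, central differences for curvature, per-cell
cropped sub-windows, and a narrow band. The band is deliberately split:
only voxels within 0.6 um of the zero level set are updated, while values
are clamped at 2.5 x that and refreshed by signed-distance
reinitialisation every 150 steps. This split is load-bearing. The eikonal
term decreases phi *everywhere* the speed is positive, so if far voxels are
allowed to move, a new negative region eventually nucleates beyond a g = 0
barrier ("tunnelling") after reinitialisation pulls those voxels into
range; with the tight active band, the front advances roughly one band
width per reinitialisation cycle and cannot tunnel. The same mechanism
bounds how far a contour can stray through defects in a degraded guide,
which is what makes the active contours visibly more robust to guide
degradation than marker-controlled watershed in the benchmark.

The speed image saturates like the guide: `g = 1 - guide` after the guide
is clipped at its boundary-response level (for guides built by
`make_guide_worm()` this is already done; `saturation = "otsu"` does it
inside `active_contours()` for raw guides). A structureless (constant)
guide yields full speed everywhere.

## Baseline segmenters

Truncated Voronoi assigns a voxel to cell i iff seed i is the nearest seed
(micrometre metric, exactly equidistant voxels to the lower index) and
within radius r; it uses no guide at all. Marker-controlled watershed
imposes minima at the seed voxels and priority-floods the guide with
6-connectivity, deterministically (ties broken by insertion order); the
eight stack corners seed a background basin so empty space is not forced
into cell segments, and segments outside 5 %-500 % of the median volume
can be filtered out. The benchmark grid evaluates watershed without the
size filter so the metric sees raw segmentation quality.

## Evaluation

A detection is a true positive iff it lies within 1.5 um of an annotated
centre and no other detection is closer to that centre; annotated centres
with no detection within 1.5 um are false negatives. Average precision is
the un-interpolated area under the precision-recall curve over all distinct
score thresholds. Segmentations are compared by the Jaccard index under the
maximum-weight one-to-one matching between predicted and reference segments
(bipartite matching on the positive-overlap pairs); AO is the mean Jaccard
over matched pairs, unmatched segments appear in segment-level precision
and recall (a matched pair counts as a segment-level true positive at
Jaccard >= 0.5, a configurable convention).

## Quantification

* **Top-layeredness** theta is the fraction of a cell's z-projection
  footprint in which it is the first nonzero label along z; theta > 0.1
  selects the "top layer" with minimal optical attenuation. The direction
  of "first" is a configuration flag.
* **Geodesic position** projects centres onto a simplified principal curve
  (centres ordered by their first principal component, smoothed by a
  running mean, joined as a polyline) and reports arc length from the
  distal end. On straight or gently curved clouds this reproduces analytic
  arc lengths to a few percent.
* **Cell rows** are 1 + the unweighted shortest-path distance from the
  distal cell on the touching-masks graph (face adjacency, 6-connectivity);
  unreachable cells are flagged. Convenience wrappers pick the distal
  reference inside the largest connected component.
* **Worm DNA recipe**: keep top-layer cells; divide raw content (sum over
  the mask) by a spline of the per-cell 95th-percentile pixel value against
  geodesic distance; per bin of four cell rows, map the 10th and 85th
  percentiles of the result to exactly 2C and 4C. The spline is fitted to
  the *log* percentile (staining gain is multiplicative) and the
  generalised cross-validation smoothness is capped at 5 degrees of
  freedom: left free, GCV occasionally chases per-cell content fluctuations
  (tens of effective degrees of freedom) and the "gain" estimate absorbs
  biology. Bins with fewer than 5 cells merge with their neighbour; fewer
  than 4 support points falls back to a linear fit.
* **OE DNA recipe**: second-order polynomial gain along x fitted to the
  90th-percentile intensity of each x-slice, first-order along z on the
  middle 25 slices, contents scaled so the median annotated M-phase cell
  is exactly 4C. Slice percentiles are computed over tissue voxels (above
  1 % of the stack maximum) and only slices with enough tissue constrain
  the fit; with few cells the slice statistic still carries some
  composition noise, so the correction is near-identity rather than exact
  on uniform-gain inputs.
* **EdU**: median filter, clamp to [t1, t2], rescale to [0, 1], sum per
  mask, map the 10th/85th percentiles of cellular contents to 0/1, then
  threshold. The default positive threshold (0.15) sits between the
  negative mode near 0 and the positive mode, where one would place a
  manual cut on the content histogram.
* **Phase calls**: EdU-positive cells are S; EdU-negative cells below
  C = 3 are G1, above are G2/M (the split is the 2C/4C midpoint and a
  configuration knob); manual M annotations override. Indices are per-bin
  proportions; `phase_indices()` also exposes a categorical chi-square
  comparison between bins.

## Morphology classifiers

Each cell contributes a 2D patch at the median-z slice of its mask, clipped
to 34 x 34 pixels and masked. Features: the number of connected components
(8-connectivity) and pixel count of the Otsu-thresholded foreground
(thresholds are computed over in-mask pixels by exhaustive search over 256
histogram levels), plus all center-surround Haar-like responses. The Haar
family is frozen as: outer squares of side 3..8 at every position in the
34 x 34 frame, inner square exactly centred with side = outer - 2 (a
one-pixel surround ring); that enumeration has exactly 5239 members, and
the response is the inner mean minus the surround mean, computed for all
features at once via an integral image.

One-vs-rest linear SVMs are trained per phase with per-phase
hyperparameters (box constraints 1e-5 / 1e-3 / 1e-2 / 1e-3 and tolerances
1e-7 / 1e-8 / 1e-8 / 1e-8 for G1 / S / G2 / M). Two conventions matter:
box constraints are scaled per class as N/(2 N_k) (the class-weighting
convention of the toolchain those values originate from), and features are
used on an acquisition-range intensity scale (the stack maximum maps to
4095, a 12-bit range) *without* re-standardisation - those tiny box
constraints are scale-coupled, and with standardised O(1) features the G1
classifier at C = 1e-5 degenerates to a majority vote. The underlying SVM
library exposes no iteration cap, so a maximum-iteration setting has no
equivalent here. Performance is reported as mean sensitivity and
specificity over 25 random equally-sized, non-intersecting train/test
splits.

## Benchmark protocol and problem sizes

`run_segmenter_grid()` builds one 30-cell phantom, its guide, and evaluates
the three segmenters under: clean guide with seed jitter 0 / 0.5 / 1 um
(jitter is an exact uniform draw from the ball, by rejection sampling), and
a degraded guide (kernel = crop of the guide, inverted, clamped at 0.85,
rescaled to [0, 1], tiled from the origin and multiplied in; the crop for
phantom-sized stacks defaults to 32 x 16 x 14 voxels, the full-stack recipe
value being 108 x 108 x 40). The active contours use a sub-window margin of
1.2 x the mean cell radius here, which caps how far a contour can stray
through degradation holes while accommodating the largest cells.
`run_detector_learning_curve()` trains on resampled subsets of up to eight
phantoms and reports AP on held-out phantoms.

The problem sizes used throughout the tests and the acceptance script -
30-cell tubes (roughly 240 x 44 x 44 voxels) for detection and
segmentation, 120 cells for the DNA/EdU/phase recovery experiment, 160
cells with an enriched M fraction (15 %) for the morphology classifiers,
and 64-cell grids for the OE recipe - were chosen as the smallest sizes at
which the statistics of interest (rank correlations, per-phase
sensitivities, per-bin percentiles) are stable.

## Known limitations

* The level-set front advances at most about one narrow-band width per
  reinitialisation cycle; pathological schedules (very few steps with very
  infrequent reinitialisation) under-grow. The defaults are matched.
* Active-contour accuracy degrades where walls are thin relative to the
  voxel size (under about two voxels of Gaussian support the lattice never
  samples the wall interior and contours leak); the phantom uses realistic
  wall widths.
* The OE gain recipe assumes slices average over many cells; on sparse
  stacks the slice percentile is composition-noise-limited.
* The morphology hyperparameters are tied to the 12-bit feature-scale
  convention; rescaled inputs require rescaled box constraints.
* `geodesic_positions()` assumes the centre cloud is monotone along its
  first principal component (true for tube-like tissues bent less than
  about a quarter turn); strongly coiled organs would need a proper
  principal-curve fit.
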