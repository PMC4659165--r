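# cytovox

Detect-then-segment 3D spatial cytometry for confocal stacks of densely
packed nuclei — for biologists and image analysts who want per-cell
measurements (position, DNA/EdU content, cell-cycle phase) from intact
tissue rather than dissociated cells.

The pipeline follows a two-step strategy. Candidate cell centres are
detected by a sliding-window linear SVM over HOG features
(a window scores as a centre when `w^T v > tau`), trained with iterative
hard-negative mining — mathematically equivalent to training on every
negative window — and latent re-estimation of the annotated centres. Each
detection then seeds a level-set active contour evolved against a guide
image `g` (the inverted, sheet-enhanced membrane channel):

    dphi/dt = -g |grad phi| (1 - c1 k) + c2 grad g . grad phi

with mean curvature `k`, curvature weight `c1 = 0.1`, and a two-step
schedule (`c2 = -1` for 650 steps of 0.15: conservative growth stopping
short of boundaries; `c2 = +1` for 300 steps: refinement onto boundaries).
Contours that collide are frozen, so masks never overlap. Truncated
Voronoi and marker-controlled watershed are included as baselines, along
with the full evaluation harness: detections match annotated centres within
1.5 um (nearest-in-radius rule), detectors are summarised by the
un-interpolated average precision (AP), and segmentations by the mean
Jaccard index over an optimal one-to-one segment matching (AO).

Per-cell quantification covers top-layeredness, geodesic and cell-row
position (Dijkstra on the touching-masks graph), DNA-content normalisation
onto the 2C/4C scale (spline-detrended, percentile-anchored), EdU content
and status, phase indices per spatial bin, and nuclear-morphology phase
classifiers (Otsu spot count/area plus 5239 center-surround Haar features
feeding per-phase linear SVMs).

Everything runs end to end on synthetic phantoms — tubes of densely packed
spherical nuclei with peripheral chromatin texture, membrane shells,
attenuation and noise — whose complete ground truth (centres, masks, DNA
contents, phases, EdU status) makes every stage testable without any
external data.

## Worked example

```r
library(cytovox)

spec <- phantom_spec(n_cells = 30)          # 2 um nuclei, 0.25 um voxels
ph <- generate_phantom(spec, seed = 7)      # dna / membrane / edu + truth

guide <- make_guide_worm(ph$membrane, cell_diameter_um = 4,
                         membrane_um = 0.25)
labels <- active_contours(guide, ph$truth$centers_um,
                          contour_params(margin_um = 2.4))
ev <- segmentation_ao(labels, ph$truth$labels)
round(c(ao = ev$ao, precision = ev$precision, recall = ev$recall), 3)
#>        ao precision    recall
#>      0.83      1.00      1.00
```

AO = 0.83 means the recovered masks overlap the true cell masks with an
average Jaccard index of 0.83 under the optimal one-to-one matching;
precision and recall of 1 mean every predicted segment matched a true cell
(at Jaccard >= 0.5) and vice versa. From the same phantom, per-cell records
and cell-cycle calls follow:

```r
rec  <- cell_records(ph$dna, ph$truth$labels)   # positions, contents, theta
norm <- normalize_dna_worm(rec)                 # C-values on the 2C/4C scale
edu  <- quantify_edu(ph$edu, ph$truth$labels, t1 = 0.05, t2 = 0.8)
phases <- phase_indices(merge(norm, edu, by = "cell"), bins = "row")
head(phases$indices, 3)
#> # A tibble: 3 x 6
#>     bin     n    G1     S   G2M     M
#>   <dbl> <int> <dbl> <dbl> <dbl> <dbl>
#> 1     1     1 0     1         0     0
#> 2     2     2 0     1         0     0
#> 3     3     6 0.333 0.667     0     0
```

`run_segmenter_grid()` and `run_detector_learning_curve()` reproduce the
robustness benchmarks (guide degradation, seed jitter, AP versus
training-set size), and `plot_segmenter_grid()` / `plot_dna_histogram()` /
`plot_phase_indices()` display the results. A thin command-line front end
over the same functions is installed at `inst/cli/cytovox`.

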