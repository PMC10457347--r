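---
title: "Single-cell MALDI-MSI analysis with scmsi: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell MALDI-MSI analysis with scmsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`scmsi` implements a desk-side analysis pipeline for single-cell lipidomics
by high-spatial-resolution MALDI mass spectrometry imaging (MSI): automated
cell detection from pixel spectra, per-cell spectrum extraction and
averaging, ppm- and ion-mobility-gated ion images, merging of serial
positive- and negative-mode acquisition runs of the same cells,
formula-based lipid annotation, and a statistical layer (UMAP, supervised
classification, group comparison, reproducibility metrics). Because raw
single-cell imaging datasets are large and instrument-bound, the package
ships a synthetic-scene generator with complete ground truth; every stage
is specified, tested and exercised against it.

# The data model

An acquisition is a rectangular pixel grid (default 10 µm raster). Each
acquired pixel carries one centroided spectrum: ascending m/z values (Da),
non-negative ion counts, and optionally one inverse reduced mobility value
1/K0 (V·s/cm²) per peak from trapped ion mobility separation. Polarity is a
property of the whole run; typical scan ranges are 400–1000 Da (positive)
and 200–1000 Da (negative), and the mobility scan range is 0.90–1.60
V·s/cm². Internally all coordinates are 0-based `(col, row)`; the imzML
standard is 1-based, and the conversion happens only at the I/O boundary so
off-by-one errors cannot propagate.

imzML files are written in processed mode (per-pixel m/z axis, 64-bit
little-endian floats, external `.ibd` arrays); both processed and
continuous files are read. Core imzML has no per-peak mobility slot, so
1/K0 values are stored in a plain-text sidecar
(`<file>.imzML.mobility.csv`, keyed by `col,row,index`) and restored
transparently on read — the main file stays standard-conformant and
readable by any imzML tool. The writer is deterministic: the file UUID is
derived from the binary payload, so a fixed simulation seed yields
byte-identical output.

# Cell detection

Detection follows a channel-sum thresholding scheme. The user designates 8
*foreground* m/z values (lipids expected where cells sit) and 8
*background* m/z values (matrix-derived ions dominating cell-free area).
For each pixel both channel sets are summed inside ±`tol_ppm` windows
(default 10 ppm, closed intervals), the background sum is subtracted from
the foreground sum, and a pixel is assigned to a cell when the subtracted
value is **greater than or equal to** `threshold_factor` (default 6) times
the average background pixel intensity. A median filter (default 3×3)
removes non-cellular single-pixel artifacts, connected components under
8-connectivity become cells, and cells outside `[area_min, area_max]`
(defaults 4 and 2000 px at 10 µm — roughly 400 µm² to 0.2 mm²) are
eliminated. ROIs carry pixel lists, areas and arithmetic centroids.

Choices worth making explicit:

* **What is thresholded.** The subtracted sum `fg − bg` is compared against
  `6 × mean(bg)`; comparing the raw foreground sum instead is available via
  `subtract_background = FALSE`. The subtraction reading follows directly
  from performing background subtraction immediately before thresholding.
* **"Average background pixel intensity"** is the mean of the
  background-channel sum over *all* acquired pixels — a single-pass,
  order-independent definition that needs no iteration or prior cell mask.
* **Border handling.** The median filter pads with 0: outside the
  acquisition region is background. For binary input the median equals a
  majority vote, which is how the box-filter implementation computes it;
  it is tested bit-for-bit against a naive neighborhood loop.
* **Determinism.** Labels are renumbered in raster-scan order of each
  component's first pixel, so results are independent of pixel iteration
  order and platform.
* Negative subtracted sums are kept, not clipped; they simply sit below
  any positive threshold.

# Per-cell spectra and features

The spectrum of a cell is the arithmetic mean over *all* its pixels:
peaks of the member pixels are aligned by single-linkage grouping at the
extraction tolerance, and a pixel lacking a peak contributes 0 to that
peak's mean (area-weighted averaging, not mean-of-detected — otherwise
sparse peaks would be inflated). Consensus m/z is the intensity-weighted
mean of the grouped peaks.

Peak picking (for profile-mode spectra) centroids local maxima by
intensity-weighted mean over a window of width m/`resolution`; `resolution`
(default 7000) is interpreted as the full width at half maximum of the
centroiding window, and apexes below `intensity_threshold` (default 2000
counts, inclusive boundary) are discarded.

Ion images sum, per pixel, the intensities within ±`tol_ppm` of a center
mass and, when requested, inside a closed 1/K0 interval — this is how
isobaric lipids ~51 ppm apart with distinct mobilities (e.g. 1.4178 vs
1.4416 V·s/cm²) are imaged separately. Gating happens directly in 1/K0
space; conversion to collision cross-section would need instrument
calibration constants and is an extension point. Unacquired grid positions
are *missing* (NA), never zero, and no normalization or denoising is
applied to images.

Feature matrices for statistics cluster peak m/z across cells per polarity
(single-linkage at `align_tol_ppm`, default 10 ppm), split clusters at
1/K0 gaps larger than `mobility_bin` (default 0.02 V·s/cm²) when mobility
is present, drop features seen in fewer than `min_frequency` (default 10%)
of cells, and fill missing values with 0.

# Dual-polarity merging

Serial runs on the same cells are registered through a least-squares
similarity transform (scale, rotation, translation — the closed-form
Procrustes solution) fitted to control-point pairs such as pen marks; a
slide is rigid and control points are few, which is why the model is
similarity rather than full affine (affine is available behind a flag).
ROIs of the two runs are then paired by greedy nearest-centroid matching
under a `max_dist` cap, ties broken by distance then cell id; each cell is
used at most once, unmatched cells are kept as single-polarity profiles
with a flag, and a match-rate summary is always attached. Greedy matching
is deterministic and explainable; for cells separated by at least twice
`max_dist` it coincides with optimal assignment.

# Annotation

Monoisotopic masses are summed from a bundled most-abundant-isotope table
(≥ 6 decimals per element). Adducts supported: `[M+H]+`, `[M−H]−`,
`[M+H−H2O]+`, using the **proton** mass 1.007276 Da rather than the
hydrogen atom mass — the electron matters at the fourth decimal for
lipid-sized ions (e.g. C44H84NO8P + H⁺ = 786.6007). Peaks are matched
against a library within `tol_ppm` (ppm computed relative to the
theoretical mass), optionally co-gated by mobility, with multiple hits
ranked by absolute ppm error.

The bundled library covers ~30 lipid species (PC, ether-PC, PE, PS, PI,
LPC, LPE, FA, Cer classes) commonly observed in cultured human cells, with
elemental formulas and, where available, measured m/z values from imaging
experiments. Curation notes: several fatty-acid entries and one ether-PC
entry carry measured values deviating from their formula-derived masses by
more than 10 ppm; these rows are flagged (`verified = FALSE`) and excluded
from parity testing, since the measured values cannot be reproduced from
composition. One PE entry is named by the composition its measured mass
actually corresponds to (36:1) rather than the label it sometimes appears
under (34:1); ceramide shorthand in the library states the hydroxylation
count consistent with the formula shipped.

# Statistics

* **Split:** plain random 60/40 partition (training size
  `floor(0.6 × n)`, so 104 cells give 62/42); stratification is off by
  default and available behind a flag.
* **Models:** SVM (radial kernel), random forest and a single-hidden-layer
  MLP (softmax, size 8, decay 0.01, inputs standardized by training-set
  statistics), all with the pinned defaults of their standard R
  implementations (e1071, randomForest, nnet); hyperparameters are echoed
  into every classify report.
* **Metrics:** accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
  specificity = TN/(TN+FP), computed on the held-out set; ratios with zero
  denominators are reported as missing, never as 0.
* **UMAP** is delegated to the uwot implementation of the published
  algorithm, run single-threaded under a fixed seed. The contract is shape
  and per-seed determinism; coordinate values are not comparable across
  library versions, so tests assert class separation (silhouette) rather
  than coordinates.
* **Group comparison:** per-feature equal-variance two-tailed Student's
  t-test (Welch behind a flag) on base-peak-normalized intensities
  (negative-mode base peak m/z 313.1428, matrix-derived), log2 fold change
  of group means, and Benjamini–Hochberg q-values emitted alongside raw
  p-values; threshold-style reporting uses the raw p-values.
  Zero-variance features with equal means yield missing p-values.
* **Reproducibility:** relative standard deviation of replicate-ROI means,
  sample standard deviation (n−1) over mean × 100.

# The synthetic-scene generator

The generator emulates the reference acquisition conditions used
throughout testing: a 160×160 px grid at 10 µm, two cell classes of 52
cells each (104 total), disk-shaped cells of radius 2–3 px placed by
rejection sampling at ≥ 3 px edge-to-edge separation (with a 4 px slide
margin), per-class lipid panels of 8 peaks, 8 matrix-derived background
ions, log-normal cell-to-cell variability at 20% CV (mean-1 scaling per
cell and feature), additive Gaussian pixel noise (σ = 50 counts, clipped
at zero with the clipping rate reported), and uniform ±3 ppm m/z jitter —
inside the 10 ppm gates but large enough to exercise tolerance logic.
The class contrast mirrors a pancreatic cancer/stellate two-population
experiment: one class-exclusive ether-PC marker plus three two-fold-shifted
features; the negative-mode panel (FA/LPE/PE/PS) carries the DAN matrix
base peak at m/z 313.1428 as a background ion. Mean peak intensities are
chosen so that cell foreground sums clear the 6× background threshold by a
comfortable factor, as they do in well-prepared single-cell slides.
Background-ion masses in the positive panel are synthetic placeholders
inside the scan range.

What the generator deliberately does **not** model: realistic cell
morphologies (disks keep ground truth analytic), isotope envelopes, matrix
crystal heterogeneity, ion suppression gradients, profile-mode peak
shapes, or overlapping/touching cells. Passing tests on these scenes
therefore demonstrate the correctness of the operators and the end-to-end
plumbing — not that the pipeline's biological conclusions transfer to any
particular instrument dataset.

Dual-run simulation renders the same cell geometry a second time in
negative mode, mapped through a planted similarity transform and with
planted means scaled by an attenuation factor in (0, 1], mirroring the
slight signal loss of a second serial acquisition; ground truth records
the cell pairing.

# Numerical choices and degenerate inputs

* ppm distances are always computed relative to the reference
  (center/theoretical) mass; all interval boundaries are closed.
* Single-linkage m/z grouping breaks chains at consecutive gaps larger
  than the tolerance — deterministic and order-independent after sorting.
* An all-zero background channel makes the 6× threshold degenerate (every
  non-negative pixel passes); this is allowed but warned about.
* Registration requires ≥ 2 non-coincident control points (3 for affine);
  scale is constrained positive.
* Empty datasets, empty ROIs, absent base peaks, single-class training
  partitions and too-small UMAP inputs raise explicit errors naming the
  offending quantity rather than propagating NaN.
* Problem sizes in the test-suite and acceptance benchmarks (160×160 px,
  104 cells, 10 replicate seeds) were chosen as the smallest scenes that
  preserve the reference study's cell count and class balance.

# Known limitations

* The SVM with default hyperparameters occasionally misclassifies one
  borderline cell (a low draw of the marker under 20% CV) on some random
  splits; the forest and MLP are robust across all tested seeds. Reports
  therefore show per-model metrics side by side.
* Touching cells are not split (no watershed); they merge into one ROI and
  are usually removed by the area cap.
* Shorthand lipid names are opaque labels; formulas ship in the library
  and no shorthand parser is provided.
* Mobility gating operates on per-peak 1/K0 scalars, not full mobility
  traces.

# A minimal run

```{r example}
library(scmsi)

sim <- simulate_scene(scene_spec(seed = 1))
seg <- segment_cells(sim$dataset, default_channels("positive"))
length(seg$rois)                      # detected cells

profiles <- lapply(seg$rois, function(r)
  extract_cell_spectrum(sim$dataset, r))
fm <- build_feature_matrix(profiles)
labels <- match_rois_to_truth(seg$rois, sim$truth$cells)$class
res <- train_and_evaluate(fm, labels, split_spec(0.6, seed = 1))
res$svm
```

The same chain is exposed as subcommands (`simulate`, `segment`,
`extract`, `ionimage`, `merge`, `annotate`, `classify`, `compare`) through
`run_subcommand()` / `run_pipeline()` and the thin `exec/scmsi` wrapper,
each writing a JSON run report with the configuration echo, its hash, the
expanded stage seed and input checksums.
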