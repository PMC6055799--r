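---
title: "Quantifying cortical ER architecture and dynamics with ernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical ER architecture and dynamics with ernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernet)
```

## The measurement problem

The cortical endoplasmic reticulum of a plant epidermal cell is, to a
good approximation, a planar network: membrane tubules meet at three-way
junctions and enclose polygonal lacunae; flat cisternal sheets sit
embedded in the network. Three per-cell quantities summarize its
architecture and respond to perturbations of network-shaping proteins:

1. the distribution of **enclosed polygonal-region areas** (µm²), a
   "looseness" measure of the network;
2. the **percentage of the cell surface classified as cisternae**;
3. the **number of three-way junctions per unit cell area** (µm⁻²).

For time-lapse data, two further readouts quantify motion: the
**persistency composite** (which pixels stay occupied across sampled
frames) and the **cumulative fluorescence intensity (CFI)**
distribution, plus tracking of bright labelled puncta with
merge/absorption events and a stationary/directed/mobile classification.

All of these depend on image-processing choices — segmentation,
structuring-element sizes, junction definitions — that published work
typically leaves to an interactive tool. `ernet` makes every choice an
explicit, tested parameter, and pairs the pipeline with a synthetic
phantom generator whose ground truth is exact, so each stage's accuracy
is measurable.

## The phantom model

`phantom_spec()` + `generate_network_graph()` build the tubule network
as the **Voronoi diagram of seed points** sampled with a minimum
separation inside the ROI (Delaunay triangulation by the Bowyer–Watson
algorithm; Voronoi vertices are circumcenters, hull edges contribute
clipped rays). This choice is deliberate: Voronoi vertices have degree 3
almost surely, and Voronoi cells are convex polygons — the two defining
features of cortical-ER geometry. Vertices then receive a small Gaussian
jitter (default s.d. 1 px) so the network is not perfectly polygonal.

The graph is kept *exactly consistent* with its rasterization, because
the ground truth would otherwise be wrong at the pixel level:

- edges shorter than twice the tubule width are contracted — two
  junctions closer than that are one junction at raster resolution
  (contraction changes V and E by one each, so the bounded-face count is
  invariant);
- pendant edges whose band would fuse with a non-adjacent tubule are
  dropped (dropping a pendant edge never changes the face count);
- jitter draws that cross two edges or bring a vertex within a tubule
  width of a non-incident edge are rejected and rebuilt from a
  deterministically derived seed (straight non-crossing segments attain
  their minimal distance at a vertex, so this vertex test is sufficient);
- single-pixel background holes at junction rasters (≤ 8 px) are filled.

With these rules the number of enclosed background polygons in the
rendered mask equals the number of bounded faces of the graph exactly,
and the face list is produced by angular half-edge traversal — an
enumeration that the Euler relation `faces = E − V + 1` cross-checks in
the tests.

Cisternae are convex patches anchored at junction vertices and grown
until a target area fraction is met (the last patch radius is bisected
to land within 0.5 percentage points). Distractors (mitochondria-like
bright blobs) are placed strictly outside a dilation of the ER mask.
Image formation is the standard confocal approximation: Gaussian PSF,
Poisson photon noise at a stated peak count, additive Gaussian read
noise; truth masks are recorded pre-optics.

Defaults are chosen to be realistic for plant cortical ER imaged at high
resolution: 512×512 px at 0.05 µm/px (a 25.6 µm field), tubule width
3 px (≈0.15 µm rendered, ≈0.25 µm apparent after the 1 px PSF),
cisternal patches ≈1.8 µm across, cisternae fraction 10% (wild-type
like), peak photon count 200. The image size and pixel size are
configuration, not assertions — no specific instrument is implied.

### Time-lapse motion

`motion_spec()` designates a disk covering a chosen fraction of the ROI
as mobile; vertices inside follow a discrete Ornstein–Uhlenbeck (AR(1))
displacement, `d[t+1] = ρ d[t] + sqrt(1−ρ²) s ε`, which is
mean-reverting with stationary s.d. `s` — bounded, locally
Brownian-like, and incapable of tearing the network. Static and mobile
regions therefore coexist in one field, as they do in real cells.
Labelled puncta ride on junction anchors (sampled with a minimum
separation of four punctum radii so spots are resolvable) plus their own
jitter. Merge, split and absorption events are scripted: a merge
re-anchors the consumed punctum at the junction nearest its partner —
merging structures are adjacent — and interpolates both trajectories to
a meeting point over ≤ 6 frames, keeping per-frame steps inside any
sensible linking gate. Frame 1 of a time-lapse is bit-identical to the
still render for the same spec.

## The analysis pipeline

**Segmentation.** Two paths share one surface. Threshold mode
contrast-normalizes the frame (quantile saturation, optional
noise-reduction smoothing) and applies a global threshold, Otsu's
between-class-variance criterion by default. Classifier mode
re-implements trainable pixel classification headlessly: a multi-scale
feature bank (Gaussian-smoothed intensity, gradient magnitude,
Laplacian, difference of Gaussians at scales 1, 2, 4 px; reflective
boundaries) feeds a seeded random forest over three classes — ER,
background, and a *rejected* class for bright non-ER organelles, which
are thereby excluded from the ER mask rather than absorbed into it.
Classifier features are computed on raw intensities, matching training;
per-image normalization is deliberately not applied in this mode, since
stretching a background-only frame would amplify noise into the
foreground range. A closing (disc radius 2, one iteration by default)
restores connectivity broken by noise.

**Polygons.** Background components inside the ROI use 4-connectivity —
the digital-topology dual of the 8-connected foreground, which prevents
diagonal leakage through tubules. "Completely enclosed" is
operationalized as: the component touches neither the image border nor
any non-ROI pixel. The identity `polygon area + ER area + excluded
background = ROI area` holds exactly and is tested.

**Cisternae.** ImageJ-style iterated opening: erode $k$ times then
dilate $k$ times with a disc of radius $r$ (defaults $r = 3$, $k = 3$,
minimum component area 0.25 µm²). The accumulated element (≈9 px,
0.45 µm) erases tubules up to ~3× their width while sheets ≥ ~1 µm
survive; the generator's patch size (≈1.8 µm) and the opening scale are
mutually consistent, which is exactly the regime the method assumes on
real data. The operation is anti-extensive and its output never grows
with more iterations (tested properties).

**Skeleton and junctions.** Zhang–Suen parallel thinning followed by a
deterministic raster-order condensation pass that removes the residual
2×2 pixel blocks the parallel algorithm leaves at junctions and on thick
diagonals — the skeleton is strictly 1 px wide. The cisternae mask
dilated by 2 px is subtracted (skeleton arcs hugging a sheet boundary
trace the sheet, not tubules), spurs shorter than 3 px are pruned, and
branch pixels are defined by a **ring crossing number ≥ 3** (the count
of 0→1 transitions around the 8-neighbour ring); a plain neighbour count
misfires on diagonal staircase corners. Branch-pixel clusters within
3 px merge into one junction, reported at the cluster centroid. A
ground-truth junction, for recovery measurements, is a degree-≥3 graph
vertex lying outside the cisternae mask dilated by the same 2 px margin
— a junction whose tubules run into a sheet is not recoverable from the
tubular skeleton by construction.

**Dynamics.** Frames are binarized by the segmentation threshold path;
occupancy sums give both the persistency composite (white = occupied in
all selected frames, otherwise hue encodes the latest occupied frame,
blue→red) and CFI. CFI distributions are compared as per-bin frequency
ratios (undefined bins reported as `NA`, never zero) with a one-sided
Wilcoxon rank-sum on per-pixel CFI values as the significance surface —
the direction "frozen dominates mobile" mirrors an
actin-depolymerization control. Tracking uses greedy nearest-neighbour
linking (gate 5 px/frame by default); a track whose gate contains only
taken detections has converged onto another track and is logged as a
merge. Motion classes use a 2 px displacement threshold and a 0.7
net-over-path straightness for "directed"; both are configuration echoed
in outputs.

**Statistics.** The Wilcoxon rank-sum is implemented directly because
the workflow needs an exact test under midrank ties (the reference
implementation in `stats` falls back to a normal approximation whenever
ties occur): for $n_a + n_b \le 20$ the null distribution of the
rank-sum is enumerated over all $\binom{n}{n_a}$ assignments of the
observed midranks; otherwise a tie-corrected normal approximation with
continuity correction is used (computed in double precision — sample
sizes reach hundreds of thousands of pixels for CFI). Welch's $t$ wraps
the standard implementation. Exactness is verified against a full
permutation oracle for all sample-size splits with $n \le 8$, against
`stats::wilcox.test` on tie-free data, and by a 500-simulation type-I
error check at $n = 12$ per group. Box plots use linear-interpolation
(type 7) quartiles and 1.5 IQR whiskers. Tests are two-sided by
default, and per-image values are pooled across replicates by default;
a per-replicate aggregation can be applied upstream of
`compare_groups()` if desired.

## What the phantoms do and do not show

The generator reproduces the *geometry* and *first-order statistics* the
pipeline quantifies: three-way-dominant planar networks, convex-ish
lacunae, sheet patches, bright distractors, confocal noise, and bounded
network motion with scripted events. It does not reproduce tubule
curvature, ring closure or cytoskeleton-driven streaming, intensity
heterogeneity along tubules, out-of-focus light from non-cortical ER, or
multi-cell fields. Passing recovery tests on phantoms therefore
demonstrates that the pipeline's operators are correct and calibrated at
realistic scales and noise levels — not that segmentation of any
particular real dataset is error-free. On real data the trainable
classifier, the closing radius, and the opening schedule remain the
user's responsibility, and every report echoes those parameters for that
reason.

## Numerical and reproducibility choices

- Coordinates are 1-based with `(x = column, y = row)` in pixels, areas
  converted via `pixel_size_um^2`; images are plain numeric matrices.
- All randomness flows from integer seeds; internal streams derive as
  `(seed × 131 + k) mod (2³¹ − 1)` so any 32-bit seed is safe. Fixed
  seed + spec gives bit-identical images, truth, and pipeline outputs.
- Thinning, condensation and tracking tie-breaks are raster-order
  deterministic; no step depends on hash or locale ordering.
- Degenerate inputs fail loudly with the stage named: zero-area ROIs,
  missing classes in training labels, events referencing unknown puncta,
  all-empty stacks, and corrupt TIFFs all raise errors rather than
  propagate.
- Verification problem sizes: 256×256 phantoms with 90 seeds for
  recovery measurements (the spatial statistics match the 512×512
  default at a quarter the cost), 512×512 with 400 seeds and 50 frames
  for the CFI dominance comparison, 500 simulations for test size,
  n = 12 images per group for the two-condition study.

## Known limitations

- The junction count inherits the raster resolution: junctions closer
  than about twice the tubule width are one detection (and, in the
  generator, one ground-truth junction by contraction). Densities are
  comparable across conditions imaged at the same scale, but absolute
  counts at different pixel sizes require the scale-invariance check in
  the test suite (densities agree within ~10% across a 2× pixel-size
  change).
- Iterated opening misclassifies very wide tubule bundles as cisternae
  if they exceed the accumulated element; on real data the opening
  schedule should be chosen against the imaged tubule width.
- The tracker is nearest-neighbour with a hard gate: it is accurate for
  bounded, gated motion (the regime the phantoms model and the tests
  verify) and will fragment tracks under displacements beyond the gate.
- CFI compares occupancy, not intensity; photobleaching affects it only
  through the per-frame binarization threshold.
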