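# ernet — quantification of ER network architecture and dynamics

The cortical endoplasmic reticulum (ER) of plant epidermal cells is a
continuously remodelling planar network of membrane tubules meeting at
three-way junctions, enclosing polygonal lacunae, with flat cisternal
sheets embedded in the network. Mutations in network-shaping proteins
(e.g. lunapark-family knockdowns) change this architecture: lacunae grow,
cisternae shrink, junction density may or may not change. `ernet`
implements the complete image-analysis workflow used to quantify such
changes from confocal fluorescence micrographs, plus the time-lapse
statistics used to quantify network motion, and a synthetic phantom
generator with exact ground truth so that every stage can be verified
without microscope data.

## What the package computes

For a single segmented cell with ROI area $A$ (µm²):

- **Polygonal-region analysis** — the background lacunae completely
  enclosed by the ER network (4-connected background against the
  8-connected foreground, components touching the ROI border excluded);
  each polygon's area $a_i$ in µm² via $a_i = n_i \cdot s^2$ for $n_i$
  pixels at pixel size $s$.
- **Cisternae isolation** — iterated morphological opening
  (erode×$k$, dilate×$k$ with a disc of radius $r$) removes tubules
  thinner than the accumulated element; surviving components ≥ a minimum
  area are cisternae. Reported as percent of cell area,
  $100 \cdot A_{cis}/A$.
- **Tubular skeleton and three-way junctions** — topology-preserving
  thinning to a strict 1-px skeleton, subtraction of the (dilated)
  cisternae mask, then branch-point detection by the ring
  crossing-number criterion with clustering of adjacent branch pixels.
  Junction density is the count divided by $A$ (µm⁻²).
- **Persistency and CFI** — per-pixel occupancy across binarized frames;
  a temporal colour-code composite (white = occupied at all sampled
  times) and the cumulative fluorescence intensity (CFI) distribution,
  where CFI of a pixel is the number of frames in which it is occupied:
  more mass at high CFI = a more static network. Conditions are compared
  as per-bin frequency ratios against a control plus a one-sided
  Wilcoxon rank-sum test on per-pixel CFI.
- **Puncta tracking** — detection of bright compact labelled structures,
  greedy nearest-neighbour linking under a displacement gate, merge
  events when two tracks converge on one detection, absorption calls
  against a cisterna mask, and motion classification
  (stationary / directed / mobile-undirected).
- **Group statistics** — Wilcoxon rank-sum (exact by enumeration with
  midrank ties for $n_a + n_b \le 20$, tie-corrected normal
  approximation with continuity correction otherwise) and Welch's
  unequal-variance $t$ test, with box-plot summaries
  (linear-interpolation quartiles, 1.5 IQR whiskers).

The phantom module generates all of this synthetically: a Voronoi-based
planar tubule graph (three-way-dominant junctions, convex-ish lacunae)
with exact bounded-face areas, cisternal patches grown to a target area
fraction, bright non-ER distractor blobs (mitochondria-like), Gaussian
PSF + Poisson photon noise + Gaussian read noise, and scripted
time-lapse motion (mean-reverting vertex jitter, static and mobile
regions, merge/split/absorption events) with ground-truth masks, graphs
and tracks.

## Worked example

```r
library(ernet)

spec  <- phantom_spec(width = 256, height = 256, n_seeds = 90,
                      cisternae_fraction = 0.10, n_distractors = 5, seed = 4)
graph <- generate_network_graph(spec)
graph
#> tubule_graph: 137 vertices, 195 edges, 107 junctions, 59 bounded faces

ph <- render_phantom(graph)
ph$truth
#> phantom_truth: ER 16992 px, cisternae 10.1%, 107 junctions, 353 distractor px

seg <- segment_image(ph$image$frames[[1]])      # Otsu threshold mode
er  <- close_mask(seg$er_mask, radius_px = 2, iterations = 1)
summarize_cell(er, pixel_size_um = 0.05)
#> morphometric_summary: 61 polygons (mean 1.111 um2), cisternae 10.72%,
#>   93 junctions (0.5676 per um2)

truth_junction_count(ph$truth)
#> [1] 88

wilcoxon_rank_sum(c(1.2, 1.9, 1.4, 2.2), c(4.5, 6.1, 5.0, 7.3))
#> wilcoxon test (exact, two.sided): statistic 10, p = 0.02857 (n = 4/4)
```

Reading the output: the generator placed 107 three-way junctions and 59
enclosed lacunae; after segmentation of the noisy rendering the pipeline
recovers the cisternae fraction to within ~0.6 percentage points of the
10.1% ground truth and 93 junctions against the 88 that remain
recoverable outside the cisternal sheets (junctions buried in a sheet
cannot be seen in the tubular skeleton). The polygon count (61) exceeds
the bounded-face count here because cisternal patches can split a
lacuna; on tubule-only phantoms the two are exactly equal.

A two-condition study (wild-type-like vs mutant-like with larger
polygons and fewer cisternae), including the frozen-vs-mobile CFI
comparison, runs with:

```r
demo_reproduction(seed = 1)
```

A thin command-line wrapper with `phantom`, `segment`, `morpho`,
`dynamics`, `compare`, `run` and `demo` subcommands is installed at
`inst/scripts/ernet.R`.

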