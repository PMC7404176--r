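---
title: "Methods: scoring tricellular tight-junction maturity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring tricellular tight-junction maturity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trijunct)
```

## The biological question and the measurement

In a maturing epithelial monolayer, tricellular tight junctions (tTJs) form
at the vertices where three cells meet. Their core component, tricellulin,
is first spread along the bicellular junctions and gradually concentrates
into a punctate pattern at the vertices as the junction matures. The degree
of that concentration is therefore a readout of junctional maturity, which
in turn tracks the jamming state of the tissue: jammed, mature monolayers
show compact, regular cells and bright tricellulin punctae; unjammed,
motile regions (e.g., behind a wound edge) show elongated cells and diffuse
tricellulin.

`trijunct` quantifies this from three fluorescence channels: a junctional
marker that outlines apical cell boundaries as thin lines (ZO-1-like), a
tricellular marker (tricellulin-like), and a nuclear stain. The pipeline
has four stages:

1. **Projection and contrast.** Confocal z-stacks are reduced to 2D with a
   junction-guided block projection, and the tricellular channel is
   background-subtracted and rescaled using a noise estimate taken under
   the nuclear mask (tricellulin is absent from nuclei).
2. **Junction graph.** The junctional image is binarized, thinned to a
   single-pixel skeleton, and parsed into a planar graph whose edges are
   bicellular junctions and whose vertices are candidate tricellular nodes;
   vertices are then relocated onto nearby point sources in the
   tricellular image.
3. **Cells and shape.** Cells are the connected components of the skeleton
   complement; each gets a polygon from its incident vertices and the
   jamming descriptors: apical shape index $q_a = p_a/\sqrt{A_a}$, aspect
   ratio AR with its SD, and density $\sigma$ (cells/mm²).
4. **Localization score.** Each vertex is scored by contrasting the mean
   adjusted tricellular intensity in a small disc at the vertex against the
   mean along its incident bicellular junctions.

## The localization score

With $I_{tri}$ the mean adjusted tricellular intensity over the
tricellular mask and $I_{bi}$ over the bicellular mask, the score is the
normalized ratio

$$T_L = \frac{I_{tri}}{I_{tri} + I_{bi}} \in [0, 1].$$

A raw ratio $I_{tri}/I_{bi}$ is unbounded, so it cannot by itself live in
$[0,1]$; the normalized form is the natural bounded variant with the right
qualitative behavior: $T_L = 0.5$ when the marker is spread evenly along
junctions, $\to 1$ under pure vertex enrichment, $\to 0$ under exclusion
from the vertex, and defined as $0$ when both means vanish. A
`tl_form = "raw-clipped"` option ($\min(I_{tri}/I_{bi}, 1)$) is available
for sensitivity analysis; it saturates quickly and is not the default.
Because the score is a ratio of means of the same image, it is invariant
under any global positive rescaling of the tricellular channel — in
particular under the SNR division of the contrast-adjustment step.

**Masks.** The tricellular mask is a disc of radius `r_tri` (default 4 px)
centred at the relocated vertex, intersected with a dilation (half-width
`w_bi`, default 2 px) of the skeleton so it stays on junctional signal.
The bicellular mask is the union of the vertex's incident edge paths
dilated by `w_bi`, intersected with the binarized junction foreground,
minus *every* tricellular disc. When two discs overlap, contested pixels
go to the nearer vertex. Only the vertex's own incident edges enter its
bicellular mask (not all junctions of the three incident cells). Vertices
whose bicellular mask ends up empty are flagged `unscorable` and carried
as missing values, never dropped from counts.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `block_size` | 20 | px | guided-projection patch size |
| `sensitivity` | 0.1 | fraction of max | offset over the local mean in binarization |
| `min_object_area` | 64 | px² | speck removal after binarization |
| `close_radius` | 2 | px | morphological closing of line gaps |
| `min_branch_len` | 10 | px | spur-pruning threshold in the graph |
| `search_radius` | 5 | px | maximum vertex relocation distance |
| `r_tri` | 4 | px | tricellular disc radius |
| `w_bi` | 2 | px | bicellular ribbon half-width |
| `pixel_size` | 0.3 | µm/px | physical scale for areas and densities |

`r_tri` and `w_bi` should be chosen so the disc covers the puncta (a few
times the apparent puncta sigma) without swallowing the adjacent edges;
results should be reported together with the radii used.

## Design choices in the junction graph

* **Binarization** uses a local adaptive threshold (pixel > local mean +
  offset) because junctional staining intensity varies across a field;
  global Otsu is available as a fallback. Closing bridges small gaps and a
  size filter removes specks.
* **Skeletonization** is Zhang–Suen thinning plus a cleanup pass that
  removes redundant pixels from residual 2×2 solid blocks only when
  deletion preserves local connectivity; the operation preserves the
  Euler number of the network and is idempotent.
* **Branch counting.** A skeleton pixel is a vertex pixel when at least
  three branches meet there, counted on a *path adjacency*: all axial
  neighbors, plus diagonal neighbors only when the step is not a shortcut
  past an orthogonal skeleton pixel. Counting raw 8-neighbors misfires on
  the staircase turns of thinned diagonal lines, and ring-transition
  counting misses junctions whose stem joins between two bar pixels; the
  path-adjacency degree handles both. Adjacent vertex pixels are merged
  into clusters, and clusters closer than 2 px are merged further — a
  near-degenerate four-cell contact thins into two branch clusters one
  pixel apart, which is physically a single (four-fold) nodal point.
  Four-fold vertices are retained with their degree recorded.
* **Robustness repairs.** Occasionally thinning renders a junction with no
  branch pixel at all; the orphaned wall then ends free against the flank
  of another path. Long free ends adjacent to another edge promote that
  pixel to a vertex and split the covering edge. Free ends within a few
  pixels of the image border are extended to the border so border cells do
  not leak around a wall cut by the field of view. Short free branches
  (below `min_branch_len`) are pruned, degree-2 vertices dissolved, and
  the whole cleanup iterated to a fixpoint.
* **Relocation.** Candidate point sources are strict local maxima of the
  Gaussian-smoothed (σ = 1 px) tricellular image. A candidate is accepted
  when its local prominence — its value minus the median network intensity
  in a surrounding annulus — exceeds
  $\max(k \cdot \mathrm{mad}, \; 0.1 \cdot \mathrm{median})$ with $k = 2$,
  both statistics over the dilated junction network. The relative floor
  matters: without punctae the smoothed boundary network still has shallow
  maxima near crossings, and the floor keeps those from being mistaken for
  point sources (an enrichment-free image leaves every vertex flagged
  `unrelocated`). Relocation never moves a vertex beyond `search_radius`,
  and it operates on the adjusted image — the monotone adjustment does not
  change the maxima.

## Geometry estimators

* **Perimeter** of a pixel region is the traced contour chain length
  (1 per axial step, $\sqrt2$ per diagonal) scaled by the classical 0.948
  staircase-bias factor, plus $\pi$ for the half-pixel dilation from pixel
  centres to pixel edges. The estimator is calibrated for convex,
  isotropically oriented regions — digital discs of cell size (40–80 px
  across) come out within 2% — and underestimates axis-aligned rectangles
  by a few percent. Polygon metrics use exact Euclidean edge lengths and
  the shoelace area, so the closed forms ($q_a = 4$ for a square, $3.7224$
  for a regular hexagon) are exact.
* **Aspect ratio** comes from the second-central-moment ellipse with a
  $1/12$ per-pixel variance term, which models each pixel as a unit
  square: a $40\times10$ rectangle gives exactly 4, and a single pixel row
  of length $n$ gives $n$ rather than a degenerate infinity.
* **Polygonization** orders a cell's incident vertices by angle about the
  region centroid. For strongly concave cells the angular ordering can
  self-intersect; those cells are flagged `non_polygonal` and their
  metrics fall back to the pixel-region estimators. Auxiliary points from
  edit scripts join the ordering.
* **Density** excludes border cells from the count and their pixels from
  the area denominator, so $\sigma$ reflects interior packing; a flag
  restores the plain count over the full imaged area.

## Projection and its provenance

The z-projection picks, per 20×20 block, the slice with the highest
intensity *energy* (sum of squared intensities) in the junctional guide
channel, then copies that block from the target channel. Energy rather
than the plain sum: defocus spreads light but nearly preserves a block's
summed intensity, so the sum barely distinguishes slices, whereas blur
always lowers the energy of a structured block. Ties (uniform or empty
blocks) resolve to the lowest slice index, edge blocks may be smaller than
the block size, and single-slice stacks project to themselves bitwise.
Focus is only defined where the guide has signal: an empty block sees
nothing but defocused light leaking in from its neighbors, so provenance
is compared against ground truth only on blocks with at least a few
full-intensity pixel equivalents of guide energy
(`focus_signal_blocks()`).

The noise model is the mean tricellular intensity under the nuclear mask;
SNR = max intensity / (2 × noise); the adjusted image is
`clip(I − noise, 0) / SNR`. When the mask area is truly dark (noise = 0)
the division is skipped with a warning and the subtracted image returned —
relevant only for synthetic noiseless inputs.

## The synthetic epithelium and what it does (not) emulate

The generator builds a centroidal-relaxed random-point Voronoi tessellation
(discrete, per-pixel nearest-seed, with Lloyd relaxation — 2 iterations by
default; 0 gives elongated, unjammed-looking cells). It renders
anti-aliased boundary lines of controllable width, additive Gaussian
punctae (peak = enrichment ρ × boundary intensity) at the true vertices,
one nuclear disc per cell, and additive Gaussian noise clipped at zero.
Because punctae sit on top of the lines, the puncta-centre intensity is
$(1+\rho)$ times the line intensity. Everything is bit-reproducible for a
fixed seed.

Each simulation carries exact ground truth: vertex coordinates, per-cell
polygons, adjacency, and a per-vertex expected score computed by scoring
the rendered *noiseless* tricellular channel with the same mask
construction the pipeline scorer uses — an exact oracle, rather than an
analytic formula in ρ that the discretized masks would only approximate.
The wound-front variant clears the cells on one side of the field, flags
the remaining cell nearest the wound as the leader, assigns rows by
breadth-first adjacency distance from it, and draws each vertex's
enrichment from the row of its youngest (lowest-row) incident cell.

What the generator does **not** emulate: realistic PSFs and depth
attenuation, Poisson (shot) noise, curved or ruffled junctions, intensity
inhomogeneity across a field, cytoplasmic background in the tricellular
channel, or 3D cell shape. Passing tests on these fixtures therefore
demonstrates the correctness of the measurement machinery — masks, graph
topology, estimators, statistics — not robustness to every real-world
imaging artifact; on real data the binarization sensitivity and the mask
radii are the parameters that need attention first, and the edit-script
mechanism exists precisely to patch residual segmentation errors.

## Statistics and group analyses

Group comparisons use the two-sample two-sided Kolmogorov–Smirnov test
(exact p-values when $n_a n_b \le 10^4$, asymptotic beyond). Scores can be
normalized to a control group's mean (the control then averages exactly
1); KS statistics are unchanged by that common rescaling. Row profiles
report per-row means with SEM (missing when a row has a single cell) and
an interior reference over rows at least 15 from the leader. Cell-cycle
triplet analysis classifies a vertex as phase-homogeneous only when *all*
incident cells (three, or four at a four-fold vertex) carry the same
label; vertices with any unlabeled incident cell are excluded.

Two aggregation levels exist — per-vertex scores and per-cell means over
incident vertices — and they are reported separately; their monolayer
means differ in general because cells weight vertices unevenly.

## Verification fixtures and problem sizes

The test suite works at sizes chosen to keep the full run around a minute
while leaving no estimator untested: 25-cell tessellations on 256² for the
unit tests, ten 25-cell 512² fields for detection accuracy (pooled F1
against ground truth at 3-px tolerance, planar Euler relation
$V - E + C = 1$ checked per connected patch of interior cells), six
enrichment levels on 130-cell 512² fields with 5% noise (≥ 200 scored
vertices each) for score recovery, and wound fixtures of 60 cells on 420²
pooled over independent seeds until the leader row accumulates 30 scored
vertices — one field contains a single leader, so several fields (as in
any real wound-edge experiment) are needed for a row-1 sample.

## Known limitations

* The binarization default assumes thin *bright* lines on a darker
  background; inverted or membrane-filling stains need preprocessing.
* Very small cells (diameter approaching 4× the line width) collapse in
  rendering and detection alike; the generator refuses such
  specifications, and on real data such cells merge with a neighbor.
* Relocation assumes punctae within `search_radius` of the skeleton
  crossing; grossly displaced tricellular signal is left unrelocated
  rather than chased.
* Time-lapse tracking of vertices, automatic leader detection and
  cell-cycle phase calling from reporter intensities are out of scope;
  labels and leader ids are user-supplied inputs.
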