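---
title: "Persistence-based segmentation of ramified cells: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistence-based segmentation of ramified cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbcseg)
```

## The model

A fluorescence volume of a cell marker such as IBA-1 is a scalar field
$f$ on a voxel grid. Sweeping a threshold $\alpha$ from $\max f$ downward,
the connected components of the superlevel set $\{f \ge \alpha\}$ form a
filtration: a component is *born* at a local maximum of $f$ and *dies*
(elder rule) at the saddle value where it first meets a component with a
higher peak. The *lifespan* (prominence) of a peak is $\mathrm{birth} -
\mathrm{death}$. A ramified cell — a bright soma with dimmer, thin
processes — carries one high-prominence peak at its soma and a trail of
shallow ripples along its branches. Clustering by prominence (the ToMATo
scheme) therefore captures a whole cell as one cluster while a plain
threshold would fragment it or fuse it with neighbors.

Concretely, foreground voxels are processed in order of decreasing density.
A voxel with no previously processed neighbor founds a *fine cluster* (a
local-max basin); any other voxel joins the cluster of its
highest-density processed neighbor. When clusters meet at a saddle voxel
$v$, a cluster whose current peak is less than $\delta$ above $f(v)$ is
merged into the most prominent cluster present. The surviving *coarse
clusters* are putative cells: each has prominence at least $\delta$, or is
the sole cluster of its connected component. Sub-$\delta$ structure with no
prominent cluster in its component is only retained when it clears the
`min_cluster_voxels` floor; otherwise it is flagged noise.

Because a cell is one connected structure, only adjacent clusters are ever
merged: adjacency is grid connectivity (6, 18 or 26 neighbors) on the
foreground mask, never long-range.

The nuclear channel then converts coarse clusters into cells with exactly
one nucleus each. Internally the rules run as remove → split → merge
(R1 → R3 → R2): removal first discards nucleus-free clusters, splitting
then guarantees every remaining voxel set maps to a single nucleus, and
merging groups same-nucleus parts. This fixed order realizes the same final
bijection as any order in which the three rules could be stated, because
after splitting, the merge step is a pure grouping by nucleus id;
`refine()` is idempotent on its own output, which the tests assert.

## Assumptions

* One dominant density peak per cell (bright soma, dimmer processes). The
  method does not require cells to be convex or of uniform shape, but a
  cell whose soma is dimmer than its processes would be mis-clustered.
* Each cell is one connected component of the thresholded foreground at
  the chosen threshold.
* Every true cell contains exactly one segmentable nucleus; cells without a
  nuclear signal are deliberately removed as artifacts.

## Parameters

| parameter | units | default | rationale |
|---|---|---|---|
| `delta` | intensity | *required* | separates soma peaks from branch/noise ripple; no automatic selection is offered because the right value depends on staining contrast. Choose it between the typical branch ripple prominence and the soma-to-saddle drop (the persistence diagram plot makes this gap visible). |
| `connectivity` | — | 26 | full 3D neighborhood; thin diagonal processes stay connected. Adjacency is in voxel steps — anisotropic spacing never reweights edges; spacing enters only physical measurements and geodesic splitting. |
| `min_cluster_voxels` | voxels | 1 | noise floor disabled by default; raise it to drop speckle clusters. |
| `min_overlap_voxels` | voxels | 1 | any geometric intersection counts as cluster–nucleus overlap; the refinement rules never quantify "overlap" beyond intersection. |
| Otsu `n_bins` | — | 256 | histogram over the observed min–max range, independent of bit depth; the threshold is a single global volume statistic, never per slice. The foreground rule is at-or-above, so the threshold value itself is foreground and the mask shrinks monotonically as the threshold rises. |

The nuclei × cell-marker channel product (`channel_product()`) is provided
for flagging candidate cell regions where both signals co-occur; the
clustering density is always the raw cell-marker intensity, since the
product is nonzero only near nuclei and cannot carry process morphology.

## Numerical choices

* **Ties.** Equal densities are ordered lexicographically by `(z, y, x)`,
  both for processing order and for the steepest-neighbor choice; on equal
  peak heights the lexicographically smaller peak survives a merge. This
  makes labelings bit-reproducible.
* **Diagram deaths.** The persistence diagram follows the classical elder
  rule on component merges: every non-global peak dies at the saddle where
  its component first joins a component with a higher peak, and each
  component's global peak dies at the component minimum. Elder-rule deaths
  coincide with the $\delta$-merge saddle whenever a merge actually occurs;
  they additionally give refused merges a finite death, so the diagram has
  exactly one pair per fine cluster.
* **Geodesic splits.** Multinucleate clusters are partitioned by
  multi-source Dijkstra on the cluster's voxel subgraph with edge length
  equal to the spacing-scaled Euclidean step, so anisotropic z does not
  distort the split; exact distance ties go to the smaller nucleus id. This
  seeded-geodesic heuristic is this package's own construction for the
  one-nucleus-per-cell contract and is validated against the bijection
  property and synthetic ground truth, including fully touching pairs.
* **Cell matching for evaluation** is greedy one-to-one by descending
  shared voxels (ties by gt id, then pred id). On realistic segmentations,
  where each prediction predominantly covers one true cell, this attains
  the exhaustive maximum-weight pairing (asserted on such fixtures); it is
  not an optimal assignment in adversarial cases.
* **Degenerate inputs.** Constant volumes have no Otsu threshold (error);
  empty masks cannot form a graph (error); an empty ground-truth mask has
  no defined percentages (error); labels above $2^{16}-1$ are written to
  TIFF in a two-word 16-bit encoding that round-trips exactly below
  $2^{32}$.

## The synthetic generator

`generate_scene()` emulates the structure the segmenter relies on: spherical
somata with random-walk branched tubes, intensity `plateau +
ramp_per_um × depth-below-surface` (a centerline-peaked profile that
guarantees one dominant peak per cell and shallow sub-$\delta$ ridges along
branches), bright nuclear spheres strictly inside somata, Gaussian blur,
then Gaussian (optionally Poisson) noise. Touching pairs are placed so
their voxel sets are disjoint but 26-adjacent — the configuration in which
intensity-only methods return a single fused cell and the nuclear split is
exercised. Branches keep a one-voxel clearance from other cells so that
only deliberate pairs ever touch.

Default conditions: a 64 × 128 × 128 grid at (1, 0.5, 0.5) μm spacing — a
32 × 64 × 64 μm confocal-like tile — with 4 cells (2–8 is the intended
range), soma radii 3.5–5 μm, nuclei 2.5 μm, 2–5 branches of 8–16 μm,
plateau 100, background 10, PSF σ 0.4 μm, and Gaussian noise of sd 5 (5% of
the plateau). A full pipeline run on one such scene takes a few seconds on
one CPU; the test suite uses 20 of them for the noisy-recovery check and
δ = 30 for the pipeline, sitting between the branch ripple (≲ 15) and the
soma prominence (≈ 60–110) of these scenes.

What passing these tests shows — and does not. Noise-free, blur-free scenes
are recovered exactly (per-cell Jaccard 1 for separated cells, exact cell
counts even fully touching); with default blur and noise, cells are
recovered with Jaccard ≈ 0.99. Real tissue adds what the generator omits:
non-uniform background and staining, optical anisotropy beyond a Gaussian
PSF, light-sheet striping, touching somata with ambiguous true boundaries,
and nuclei that a real nuclear segmenter may miss or merge. Results on the
phantom bound what the algorithm can do when its assumptions hold, not its
accuracy on any particular tissue.

## Design choices where the design was open

* **Nuclear masks** from a dedicated (e.g. deep-learning) segmenter are the
  first-class input, ingested as integer-label TIFFs; the built-in fallback
  (global Otsu + 3D components + size filter) exists so the pipeline and
  its tests run self-contained, and is adequate for well-separated DAPI
  blobs only.
* **Editing granularity** is the fine cluster, never the voxel: edits move
  whole basins, every operation is logged, and replaying the log on the
  saved base state reproduces the current labels exactly. A fine cluster
  can belong to at most one cell. Sessions are a versioned JSON manifest
  plus a label TIFF.
* **TIFF dialect.** Stacks are multi-page TIFFs, z-major with channels
  fastest, 16-bit; the internal axis order is `(channel, z, y, x)`,
  0-background integer labels, intensities kept in their native integer
  range with no rescaling and no hidden resampling.
* **CLI precedence** is flags > YAML config > defaults, and every run
  writes a report with all effective parameters, the Otsu threshold,
  counts, the seed and the package version.

## Limitations

* $\delta$ is a user decision; poor contrast between soma and ripple
  prominence leaves no good value.
* Cells genuinely lacking a nuclear signal are removed by design — the
  nuclear requirement is the price of separating touching cells.
* Only 0-dimensional persistence is used (components; no loops/voids), and
  there is no GPU path or out-of-core tiling; volumes must fit in memory.
* The voxel-wise scores carry no boundary-distance or skeleton morphometry.
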