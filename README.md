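# pbcseg — persistence-based 3D cell segmentation

`pbcseg` segments ramified cells — microglia are the motivating case — in
multi-channel 3D fluorescence z-stacks. Cells like resting microglia have a
small soma and long, thin, branching processes; uniform-shape segmenters and
plain thresholding fragment them or fuse neighbors. `pbcseg` instead treats
the cell-marker intensity as a scalar field and clusters its foreground
voxels by **zero-dimensional persistence** (ToMATo-style mode seeking), then
uses the **nuclear channel** to enforce a one-to-one cell↔nucleus
correspondence — which is what makes physically touching cells separable.

It is written for microscopists and image analysts who have a two-channel
TIFF (nuclear stain + cell marker), voxel spacing in μm, and optionally
nuclear instance masks from a dedicated segmenter.

## The method

Sweep a threshold α from the intensity maximum downward. Components of the
superlevel set `{f ≥ α}` are *born* at local maxima and *die* when they meet
a component with a higher peak; the **lifespan** (prominence) of a peak is
`birth − death`. Voxels are processed in decreasing density: each voxel
joins the cluster of its steepest previously-processed neighbor, and when
clusters meet at a saddle voxel `v`, any cluster whose peak is less than a
user threshold **δ** above `f(v)` is merged into the more prominent one.
Surviving coarse clusters are the putative cells; the un-merged local-max
basins are **fine clusters**, the editable units.

Nuclear masks (external, or a built-in Otsu + connected-components fallback)
then refine the coarse clusters:

1. clusters overlapping **no** nucleus are removed (incomplete cells,
   artifacts);
2. clusters overlapping **one shared** nucleus are merged into one cell;
3. clusters overlapping **k ≥ 2** nuclei are split into k cells by seeded
   geodesic propagation (multi-source shortest paths in physical μm).

Evaluation against ground truth is voxel-wise and per cell:
`F1 = 2TP/(2TP+FP+FN)` (Dice), `Jaccard = TP/(TP+FP+FN)`, and false
positive / negative percentages with the ground-truth cell size as the
denominator — so either percentage can exceed 100.

## Worked example

Generate a synthetic scene (four branched cells, two of them touching,
realistic blur and noise), segment it, and score it against the scene's
exact ground truth:

```r
library(pbcseg)

scene <- generate_scene(synth_params(seed = 17, n_cells = 4,
                                     touching_pair_fraction = 0.5))
cells_ch  <- scene$stack$data[2, , , ]
nuclei_ch <- scene$stack$data[1, , , ]
sp <- scene$stack$spacing_um

mask  <- foreground_mask(cells_ch, otsu_threshold(cells_ch), sp)
graph <- build_voxel_graph(mask, cells_ch, connectivity = 26)
hier  <- tomato_cluster(graph, pbc_params(delta = 30))
hier
#> cluster_hierarchy: 7527 foreground voxels, 83 fine / 4 coarse clusters (0 noise), delta = 30

nuclei <- segment_nuclei_simple(nuclei_ch, sp, min_voxels = 20)
seg <- refine(hier, nuclei)
seg
#> cell_segmentation: 4 cell(s), 83 fine cluster(s), 7527 voxels

head(persistence_diagram(hier), 4)
#> # A tibble: 4 × 8
#>    fine coarse peak_z peak_y peak_x birth death lifespan
#>   <int>  <int>  <int>  <int>  <int> <dbl> <dbl>    <dbl>
#> 1     1      1     26     63     24   177    61      116
#> 2     3      2     36     45     76   173    61      112
#> 3     6      4     46    102    102   165    61      104
#> 4     5      3     29     68     41   165   106       59

summary(evaluate_segmentation(seg$cell_labels, scene$gt_cells))
#> # A tibble: 4 × 4
#>   metric   mean      sd     n
#>   <chr>   <dbl>   <dbl> <int>
#> 1 f1      0.992 0.00362     4
#> 2 jaccard 0.985 0.00712     4
#> 3 fp_pct  0.448 0.284       4
#> 4 fn_pct  1.11  0.556       4
```

The 83 fine clusters are the soma peak plus low-prominence ripples along
each cell's processes; at δ = 30 they collapse into exactly one coarse
cluster per cell. Each of the four persistence pairs shown is one cell's
soma peak (`birth` ≈ soma-center intensity, `death` at the component
minimum or the saddle to a stronger neighbor — the fourth row is the
touching cell that meets its partner at intensity 106). All four cells are
recovered with Jaccard ≈ 0.99, and the touching pair is split correctly
because each half owns its own nucleus.

Cluster-level proofreading mirrors the interactive workflow headlessly:

```r
s <- edit_session(seg)
s <- add_cluster(s, cell_id = 2, fine_cluster_id = 40)   # adjacent process
s <- remove_cluster(s, cell_id = 2, fine_cluster_id = 40)
save_session(s, "session.json")                          # replayable log
```

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/pbcseg synth   --out scene --seed 17 --n-cells 4 --touching 0.5
Rscript inst/cli/pbcseg segment --input scene/stack.tif --out run \
                                --delta 30 --spacing 1,0.5,0.5
Rscript inst/cli/pbcseg evaluate --pred run/cells.tif --gt scene/gt_cells.tif \
                                 --out eval --spacing 1,0.5,0.5
```

Exit codes: 0 ok, 2 user error, 3 data error. `segment` writes coarse/fine
cluster labels, refined cell labels, the persistence diagram CSV, a per-cell
manifest, an edit-session JSON, and a run report with every parameter and
seed needed to reproduce the run.

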