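# fixtures built in code at test time

# random foreground grid with continuous densities (ties have measure zero)
random_grid <- function(max_fg = 200L, p_fg = NULL, dims = NULL) {
  if (is.null(dims))
    dims <- c(sample(2:4, 1), sample(4:8, 1), sample(4:8, 1))
  if (is.null(p_fg)) p_fg <- runif(1, 0.3, 0.8)
  mask <- array(runif(prod(dims)) < p_fg, dims)
  if (sum(mask) == 0L) mask[sample(length(mask), 1L)] <- TRUE
  if (sum(mask) > max_fg)
    mask[sample(which(mask), sum(mask) - max_fg)] <- FALSE
  dens <- array(0, dims)
  dens[mask] <- runif(sum(mask))
  list(mask = mask, dens = dens, dims = dims)
}

# small fast synthetic scene for module tests
small_scene_params <- function(seed, n_cells = 2L, touching = 0, ...) {
  synth_params(shape = c(32L, 80L, 80L), spacing_um = c(1, 0.5, 0.5),
               n_cells = n_cells, soma_radius_um = c(2.6, 3.4),
               nucleus_radius_um = 2.0, branch_length_um = c(4, 8),
               n_branches = c(2L, 3L), touching_pair_fraction = touching,
               seed = seed, ...)
}

# full pipeline on a scene: Otsu foreground -> persistence clustering ->
# fallback nuclei -> nucleus refinement
segment_scene <- function(scene, delta = 30, connectivity = 26L,
                          nuclei_min_voxels = 20L) {
  cells_ch <- scene$stack$data[2, , , ]
  nuclei_ch <- scene$stack$data[1, , , ]
  sp <- scene$stack$spacing_um
  mask <- foreground_mask(cells_ch, otsu_threshold(cells_ch), sp)
  g <- build_voxel_graph(mask, cells_ch, connectivity)
  h <- tomato_cluster(g, pbc_params(delta, connectivity))
  nuc <- segment_nuclei_simple(nuclei_ch, sp, min_voxels = nuclei_min_voxels,
                               connectivity = connectivity)
  list(h = h, nuclei = nuc, seg = refine(h, nuc))
}

# straight-line 1D density profile embedded as a 1 x 1 x n grid
profile_graph <- function(dens_values, connectivity = 6L) {
  n <- length(dens_values)
  dens <- array(dens_values, c(1, 1, n))
  mask <- binary_volume(array(TRUE, c(1, 1, n)), c(1, 1, 1))
  build_voxel_graph(mask, dens, connectivity)
}

# two cells plus unassigned fine clusters adjacent to each
session_fixture <- function() {
  sp <- c(1, 1, 1)
  fine <- array(0L, c(2, 4, 12))
  fine[, 1:2, 1:3] <- 1L          # cell 1
  fine[, 1:2, 4:5] <- 2L          # unassigned, adjacent to cluster 1
  fine[, 4, 8:10] <- 3L           # cell 2, far away
  fine[, 4, 11:12] <- 4L          # unassigned, adjacent to cluster 3
  seg <- structure(list(cell_labels = NULL, fine_labels = label_volume(fine, sp),
                        cells = list(`1` = 1L, `2` = 3L),
                        nucleus_of = c(`1` = 1L, `2` = 2L),
                        connectivity = 26L),
                   class = "cell_segmentation")
  edit_session(seg)
}

expect_same_partition <- function(a, b) {
  expect_identical(canon_labels(a), canon_labels(b))
}
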