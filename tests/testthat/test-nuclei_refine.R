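test_that("fallback nuclear segmenter labels and size-filters components", {
  # two bright blobs, one below the size floor
  ch <- array(0, c(6, 12, 12))
  ch[2:4, 2:4, 2:4] <- 200      # 27 voxels
  ch[3, 9:10, 9] <- 200         # 2 voxels
  lab <- segment_nuclei_simple(ch, c(1, 1, 1), min_voxels = 1L)
  expect_equal(max(lab$labels), 2L)
  lab2 <- segment_nuclei_simple(ch, c(1, 1, 1), min_voxels = 5L)
  expect_equal(max(lab2$labels), 1L)
  expect_true(all(lab2$labels[3, 9:10, 9] == 0L))
})

test_that("component labeling agrees with a flood-fill oracle on random blobs", {
  set.seed(31)
  for (rep in 1:10) {
    rg <- random_grid()
    ch <- array(0, rg$dims); ch[rg$mask] <- 100
    lab <- segment_nuclei_simple(ch, c(1, 1, 1), threshold = 50)
    expect_same_partition(lab$labels, oracle_components(rg$mask, 26L))
  }
})

test_that("overlap table counts equal the per-voxel double-loop tally", {
  sp <- c(1, 1, 1)
  # disjoint volumes -> empty table
  a <- array(0L, c(3, 4, 4)); a[1, 1, 1] <- 1L
  b <- array(0L, c(3, 4, 4)); b[3, 4, 4] <- 1L
  expect_equal(nrow(overlap_table(label_volume(a, sp), label_volume(b, sp))), 0L)
  # nucleus fully inside one cluster: one entry of the nucleus's size
  cl <- array(0L, c(4, 6, 6)); cl[, , ] <- 0L; cl[1:3, 1:5, 1:5] <- 2L
  nu <- array(0L, c(4, 6, 6)); nu[2, 2:3, 2:3] <- 7L
  tb <- overlap_table(label_volume(cl, sp), label_volume(nu, sp))
  expect_equal(tb$voxels, 4L)
  expect_equal(tb$cluster, 2L); expect_equal(tb$nucleus, 7L)
  # random volumes
  set.seed(32)
  for (rep in 1:5) {
    c1 <- array(sample(0:3, 96, replace = TRUE), c(4, 4, 6))
    n1 <- array(sample(0:2, 96, replace = TRUE), c(4, 4, 6))
    got <- as.data.frame(overlap_table(label_volume(c1, sp), label_volume(n1, sp)))
    ref <- oracle_overlap(as.vector(c1), as.vector(n1))
    rownames(got) <- rownames(ref) <- NULL
    expect_equal(got, ref)
  }
  expect_error(overlap_table(label_volume(c1, sp),
                             label_volume(array(0L, c(1, 2, 3)), sp)), "shapes")
})

test_that("geodesic split of a 7-voxel path matches the distance table", {
  # path along x, seeds at positions 2 and 6 (nucleus ids 1, 2); position 4
  # is equidistant and goes to the smaller id
  lin <- which(array(TRUE, c(1, 1, 7)))
  seed <- c(0L, 1L, 0L, 0L, 0L, 2L, 0L)
  part <- split_multinucleate(lin, seed, c(1L, 1L, 7L), c(1, 1, 1), 6L)
  expect_equal(part, c(1L, 1L, 1L, 1L, 2L, 2L, 2L))
  # single seed claims everything
  one <- split_multinucleate(lin, c(0L, 1L, rep(0L, 5)), c(1L, 1L, 7L),
                             c(1, 1, 1), 6L)
  expect_equal(one, rep(1L, 7))
  expect_error(split_multinucleate(lin, rep(0L, 7), c(1L, 1L, 7L),
                                   c(1, 1, 1), 6L), "seed")
})

test_that("geodesic split matches Floyd-Warshall distances with anisotropy", {
  set.seed(33)
  for (rep in 1:8) {
    # connected random cluster of up to ~40 voxels
    rg <- random_grid(max_fg = 60L, p_fg = 0.7)
    comp <- oracle_components(rg$mask, 26L)
    big <- which.max(tabulate(comp[comp > 0]))
    lin <- which(comp == big)
    if (length(lin) < 6L) next
    spacing <- c(sample(c(1, 2), 1), 0.5, 0.5)
    seed_of <- integer(length(lin))
    seed_of[sample(length(lin), 2L)] <- c(1L, 2L)
    got <- split_multinucleate(lin, seed_of, rg$dims, spacing, 26L)
    coord <- arrayInd(lin, rg$dims)
    ref <- oracle_geodesic(coord, seed_of, spacing, 26L)
    expect_equal(got, ref)
    # partition: union is the cluster, parts connected, each holds its seed
    for (s in 1:2) {
      part_mask <- array(FALSE, rg$dims); part_mask[lin[got == s]] <- TRUE
      cc <- oracle_components(part_mask, 26L)
      expect_equal(max(cc), 1L)
      expect_true(all(got[seed_of == s] == s))
    }
  }
})

make_two_cluster_scene <- function() {
  # clusters C1, C2 over nucleus N1; C3 overlaps nothing
  sp <- c(1, 1, 1)
  cl <- array(0L, c(2, 4, 10))
  cl[, 1:2, 1:3] <- 1L; cl[, 3:4, 1:3] <- 2L; cl[, 1:2, 8:10] <- 3L
  nu <- array(0L, c(2, 4, 10)); nu[, 2:3, 1:2] <- 1L
  fine <- cl  # one fine cluster per coarse cluster
  seg <- structure(list(cell_labels = label_volume(cl, sp),
                        fine_labels = label_volume(fine, sp),
                        cells = list(`1` = 1L, `2` = 2L, `3` = 3L),
                        nucleus_of = c(`1` = 1L, `2` = 1L, `3` = 2L),
                        connectivity = 26L),
                   class = "cell_segmentation")
  list(seg = seg, nuclei = label_volume(nu, sp))
}

test_that("refine removes nucleus-free clusters and merges same-nucleus clusters", {
  sc <- make_two_cluster_scene()
  out <- refine(sc$seg, sc$nuclei)
  expect_equal(length(out$cells), 1L)               # C1+C2 one cell, C3 gone
  expect_equal(unname(out$nucleus_of), 1L)
  lab <- out$cell_labels$labels
  expect_true(all(lab[, 1:4, 1:3] == 1L))
  expect_true(all(lab[, , 8:10] == 0L))
})

test_that("refine splits a dumbbell cluster spanning two nuclei", {
  sp <- c(1, 1, 1)
  cl <- array(0L, c(2, 3, 11)); cl[, , ] <- 0L
  cl[, 1:3, 1:3] <- 1L; cl[, 2, 4:8] <- 1L; cl[, 1:3, 9:11] <- 1L
  nu <- array(0L, c(2, 3, 11)); nu[, 2, 2] <- 1L; nu[, 2, 10] <- 2L
  h <- structure(list(cell_labels = label_volume(cl, sp),
                      fine_labels = label_volume(cl, sp),
                      cells = list(`1` = 1L), nucleus_of = c(`1` = 1L),
                      connectivity = 26L),
                 class = "cell_segmentation")
  out <- refine(h, label_volume(nu, sp))
  expect_equal(length(out$cells), 2L)
  expect_equal(unname(out$nucleus_of), c(1L, 2L))
  lab <- out$cell_labels$labels
  expect_true(all(lab[, 1:3, 1:3] == 1L))
  expect_true(all(lab[, 1:3, 9:11] == 2L))
  # the bridge is divided, no voxel lost
  expect_equal(sum(lab > 0L), sum(cl > 0L))
})

test_that("refinement yields a cell-nucleus bijection and is idempotent", {
  set.seed(34)
  for (seed in c(101, 102)) {
    scene <- generate_scene(small_scene_params(seed, n_cells = 3L,
                                               touching = 2 / 3))
    res <- segment_scene(scene)
    seg <- res$seg
    nuc_ids <- unname(seg$nucleus_of)
    expect_equal(length(nuc_ids), length(unique(nuc_ids)))   # injective
    expect_equal(length(seg$cells), 3L)
    # every retained voxel belongs to exactly one cell (labels partition)
    expect_true(all(seg$cell_labels$labels[seg$fine_labels$labels > 0L] > 0L))
    # idempotent: refining the refined segmentation changes nothing
    again <- refine(seg, res$nuclei)
    expect_identical(again$cell_labels$labels, seg$cell_labels$labels)
    expect_identical(again$nucleus_of, seg$nucleus_of)
    expect_identical(again$cells, seg$cells)
  }
})

test_that("touching cells that a nucleus-free method fuses are resolved", {
  scene <- generate_scene(small_scene_params(201, n_cells = 2L, touching = 1))
  # with a huge delta the touching pair is a single coarse cluster -- the
  # failure mode of purely intensity-based segmentation
  res_fused <- segment_scene(scene, delta = 1e6)
  expect_equal(sum(!res_fused$h$noise), 1L)
  expect_equal(length(res_fused$seg$cells), 2L)   # nuclei rescue the split
  rep <- evaluate_segmentation(res_fused$seg$cell_labels, scene$gt_cells)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$jaccard > 0.9))
})
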