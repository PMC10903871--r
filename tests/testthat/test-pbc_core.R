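test_that("voxel graph edges match exhaustive neighborhood enumeration", {
  # 1x1x3 line at 6-connectivity: a path with 2 edges
  g <- profile_graph(c(1, 2, 3))
  expect_equal(length(g$lin), 3L)
  expect_equal(nrow(voxel_graph_edges(g)), 2L)

  # 2x2x2 solid cube at 26-connectivity: all 28 pairs are adjacent
  mask <- binary_volume(array(TRUE, c(2, 2, 2)), c(1, 1, 1))
  g <- build_voxel_graph(mask, array(1, c(2, 2, 2)), 26L)
  expect_equal(nrow(voxel_graph_edges(g)), 28L)

  # diagonal offset (0,1,1): not 6-adjacent, 18-adjacent
  m <- array(FALSE, c(3, 3, 3)); m[2, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  for (conn in c(6L, 18L, 26L)) {
    g <- build_voxel_graph(binary_volume(m, c(1, 1, 1)), array(1, c(3, 3, 3)), conn)
    expect_equal(nrow(voxel_graph_edges(g)), if (conn == 6L) 0L else 1L)
  }

  # random grids: edge sets equal the pairwise-adjacency oracle
  set.seed(21)
  for (conn in c(6L, 18L, 26L)) {
    rg <- random_grid(max_fg = 60L)
    g <- build_voxel_graph(binary_volume(rg$mask, c(1, 1, 1)), rg$dens, conn)
    coord <- arrayInd(g$lin, rg$dims)
    expect_equal(nrow(voxel_graph_edges(g)),
                 sum(oracle_adjacency(coord, conn)) / 2)
  }

  expect_error(build_voxel_graph(
    binary_volume(array(FALSE, c(2, 2, 2)), c(1, 1, 1)),
    array(1, c(2, 2, 2))), "empty")
})

test_that("the 1D profile reproduces the emerge-and-die worked example", {
  g <- profile_graph(c(0, 2, 1, 3, 0))
  h <- tomato_cluster(g, pbc_params(0.5, connectivity = 6L))
  lab <- as.vector(cut_hierarchy(h, "coarse")$labels)
  # two clusters: the peak-3 basin {x3,x4,x5} and the peak-2 basin {x1,x2}
  expect_equal(length(unique(lab)), 2L)
  expect_equal(lab[3], lab[4]); expect_equal(lab[4], lab[5])
  expect_equal(lab[1], lab[2])
  expect_true(lab[1] != lab[3])
  d <- persistence_diagram(h)
  sec <- d[d$birth == 2, ]
  expect_equal(sec$death, 1)
  expect_equal(sec$lifespan, 1)
  # delta above the secondary lifespan merges everything
  h2 <- tomato_cluster(g, pbc_params(1.5, connectivity = 6L))
  expect_equal(length(unique(as.vector(cut_hierarchy(h2, "coarse")$labels))), 1L)
})

test_that("coarse clustering equals the brute-force superlevel-sweep oracle", {
  set.seed(22)
  for (rep in 1:40) {
    rg <- random_grid()
    conn <- sample(c(6L, 18L, 26L), 1)
    delta <- runif(1)
    g <- build_voxel_graph(binary_volume(rg$mask, c(1, 1, 1)), rg$dens, conn)
    h <- tomato_cluster(g, pbc_params(delta, conn))
    expect_same_partition(cut_hierarchy(h, "coarse")$labels,
                          oracle_tomato(rg$dens, rg$mask, conn, delta))
  }
})

test_that("persistence pairs equal the per-threshold flood-fill elder rule", {
  set.seed(23)
  for (rep in 1:15) {
    rg <- random_grid(max_fg = 60L)
    conn <- sample(c(6L, 26L), 1)
    g <- build_voxel_graph(binary_volume(rg$mask, c(1, 1, 1)), rg$dens, conn)
    h <- tomato_cluster(g, pbc_params(0.2, conn))
    d <- persistence_diagram(h)
    ref <- oracle_persistence_pairs(rg$dens, rg$mask, conn)
    expect_equal(nrow(d), nrow(ref))  # one pair per local-max basin
    o1 <- order(d$birth, d$death); o2 <- order(ref$birth, ref$death)
    expect_equal(d$birth[o1], ref$birth[o2])
    expect_equal(d$death[o1], ref$death[o2])
  }
})

test_that("delta = Inf degenerates to connected components", {
  set.seed(24)
  for (rep in 1:10) {
    rg <- random_grid()
    conn <- sample(c(6L, 18L, 26L), 1)
    g <- build_voxel_graph(binary_volume(rg$mask, c(1, 1, 1)), rg$dens, conn)
    h <- tomato_cluster(g, pbc_params(Inf, conn))
    expect_same_partition(cut_hierarchy(h, "coarse")$labels,
                          oracle_components(rg$mask, conn))
  }
})

test_that("cluster count is non-increasing in delta", {
  set.seed(25)
  for (rep in 1:10) {
    rg <- random_grid()
    g <- build_voxel_graph(binary_volume(rg$mask, c(1, 1, 1)), rg$dens, 26L)
    deltas <- sort(runif(5, 0, 1.2))
    counts <- vapply(deltas, function(d) {
      h <- tomato_cluster(g, pbc_params(d, 26L))
      length(unique(h$coarse_of_fine))
    }, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("labels partition the foreground and fine refines coarse", {
  set.seed(26)
  for (rep in 1:10) {
    rg <- random_grid()
    g <- build_voxel_graph(binary_volume(rg$mask, c(1, 1, 1)), rg$dens, 26L)
    h <- tomato_cluster(g, pbc_params(runif(1, 0, 0.8), 26L))
    fine <- cut_hierarchy(h, "fine")$labels
    coarse <- cut_hierarchy(h, "coarse")$labels
    # every foreground voxel labeled, nothing outside the mask
    expect_true(all(fine[rg$mask] > 0L))
    expect_true(all(fine[!rg$mask] == 0L))
    expect_true(all(coarse[!rg$mask] == 0L))
    # each fine cluster lies inside exactly one coarse cluster
    for (f in unique(fine[fine > 0L]))
      expect_equal(length(unique(coarse[fine == f])), 1L)
    # each coarse cluster is one connected component of the voxel graph
    for (cl in unique(coarse[coarse > 0L])) {
      cc <- oracle_components(coarse == cl, 26L)
      expect_equal(max(cc), 1L)
    }
  }
})

test_that("identical inputs give identical labelings, including ties", {
  set.seed(27)
  dens <- array(sample(0:3, 4 * 5 * 5, replace = TRUE), c(4, 5, 5))
  mask <- binary_volume(array(TRUE, c(4, 5, 5)), c(1, 1, 1))
  g <- build_voxel_graph(mask, dens, 26L)
  h1 <- tomato_cluster(g, pbc_params(1))
  h2 <- tomato_cluster(g, pbc_params(1))
  expect_identical(cut_hierarchy(h1, "coarse")$labels,
                   cut_hierarchy(h2, "coarse")$labels)
  expect_identical(h1$diagram, h2$diagram)
})

test_that("min_cluster_voxels flags small coarse clusters as noise", {
  # two components: a 4-voxel bar and an isolated voxel
  m <- array(FALSE, c(1, 3, 5)); m[1, 1, 1:4] <- TRUE; m[1, 3, 1] <- TRUE
  d <- array(1, c(1, 3, 5))
  g <- build_voxel_graph(binary_volume(m, c(1, 1, 1)), d, 6L)
  h <- tomato_cluster(g, pbc_params(0.5, 6L, min_cluster_voxels = 2L))
  lab <- cut_hierarchy(h, "coarse", drop_noise = TRUE)$labels
  expect_equal(lab[1, 3, 1], 0L)        # singleton dropped as noise
  expect_true(all(lab[1, 1, 1:4] > 0L))
  keep <- cut_hierarchy(h, "coarse", drop_noise = FALSE)$labels
  expect_gt(keep[1, 3, 1], 0L)
})
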