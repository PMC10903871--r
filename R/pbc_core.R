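#' Parameters for persistence-based clustering
#'
#' @param delta prominence threshold in intensity units: a density peak whose
#'   lifespan (birth minus death) falls below `delta` is merged into a more
#'   prominent neighboring cluster. Must be supplied by the user; there is no
#'   automatic selection.
#' @param connectivity voxel grid connectivity, one of 6, 18, 26 (default 26,
#'   the full 3D neighborhood). Adjacency is in voxel steps; anisotropic
#'   spacing never alters it.
#' @param min_cluster_voxels coarse clusters smaller than this are flagged
#'   noise (default 1, i.e. disabled).
#' @return A `pbc_params` object.
#' @export
pbc_params <- function(delta, connectivity = 26L, min_cluster_voxels = 1L) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("delta must be a single non-negative number")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  if (min_cluster_voxels < 1L) stop("min_cluster_voxels must be >= 1")
  structure(list(delta = delta, connectivity = as.integer(connectivity),
                 min_cluster_voxels = as.integer(min_cluster_voxels)),
            class = "pbc_params")
}

#' Build the foreground voxel graph
#'
#' Nodes are the foreground voxels of `mask`, each carrying the raw
#' cell-marker intensity as its density; edges join voxels within one grid
#' step at the chosen connectivity. Edges are enumerated lazily via
#' [voxel_graph_edges()] since the clustering kernel never materializes them.
#'
#' @param mask a [binary_volume] of foreground voxels.
#' @param density_channel 3D intensity array of the same shape.
#' @param connectivity 6, 18 or 26.
#' @return A `voxel_graph` object.
#' @export
build_voxel_graph <- function(mask, density_channel, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_volume"))
  if (!identical(dim(mask$mask), dim(density_channel)))
    stop("mask and density channel shapes differ")
  lin <- which(mask$mask)
  if (length(lin) == 0L) stop("empty mask: no foreground voxels")
  dens <- as.numeric(density_channel[lin])
  if (any(!is.finite(dens)) || any(dens < 0))
    stop("densities must be finite and non-negative")
  structure(list(dim = dim(mask$mask), lin = lin, density = dens,
                 connectivity = as.integer(connectivity),
                 spacing_um = mask$spacing_um),
            class = "voxel_graph")
}

#' Enumerate the edges of a voxel graph
#'
#' @param graph a `voxel_graph`.
#' @return Integer matrix with one row per undirected edge, columns `i`, `j`
#'   indexing into the graph's node list (`i < j`).
#' @export
voxel_graph_edges <- function(graph) {
  e <- voxel_edges_cpp(graph$dim, graph$lin, graph$connectivity)
  colnames(e) <- c("i", "j")
  e
}

# (z, y, x) coordinates of 1-based linear indices in a (z, y, x) array
lin_to_zyx <- function(lin, dm) {
  lin0 <- lin - 1L
  cbind(z = lin0 %% dm[1] + 1L,
        y = (lin0 %/% dm[1]) %% dm[2] + 1L,
        x = lin0 %/% (dm[1] * dm[2]) + 1L)
}

#' ToMATo persistence-based clustering
#'
#' Clusters the foreground voxels under the superlevel-set filtration of
#' their density. Voxels are processed in decreasing density (ties broken by
#' lexicographic `(z, y, x)` coordinate); a voxel with no previously
#' processed neighbor founds a fine cluster at its own density (birth), any
#' other voxel joins the cluster of its highest-density processed neighbor.
#' When clusters meet at a saddle voxel `v`, a cluster whose current peak is
#' less than `delta` above `f(v)` is merged into the most prominent cluster
#' present (equal peak heights: the lexicographically smaller peak survives).
#' Surviving coarse clusters therefore have prominence at least `delta`, or
#' are the unique cluster of their connected component. Coarse clusters with
#' fewer than `min_cluster_voxels` voxels are flagged noise.
#'
#' @param graph a `voxel_graph` from [build_voxel_graph()].
#' @param params a [pbc_params] object.
#' @return A `cluster_hierarchy` with per-node fine labels, the fine-to-coarse
#'   parent map, noise flags, and the persistence diagram (one pair per fine
#'   cluster; a component's global peak dies at the component minimum).
#' @export
tomato_cluster <- function(graph, params) {
  stopifnot(inherits(graph, "voxel_graph"), inherits(params, "pbc_params"))
  zyx <- lin_to_zyx(graph$lin, graph$dim)
  ord <- order(-graph$density, zyx[, 1], zyx[, 2], zyx[, 3], method = "radix")
  res <- tomato_cpp(graph$dim, graph$lin[ord], graph$density[ord],
                    graph$connectivity, params$delta)

  n_fine <- length(res$birth)
  # fine labels come back in founding order (descending peak density with the
  # lexicographic tie rule) and are kept; coarse ids are numbered the same way
  coarse_roots <- sort(unique(res$coarse_root))
  coarse_id_of_root <- setNames(seq_along(coarse_roots), coarse_roots)
  coarse_of_fine <- as.integer(coarse_id_of_root[as.character(res$coarse_root)])

  fine_per_node <- integer(length(graph$lin))
  fine_per_node[ord] <- res$fine

  peak_zyx <- lin_to_zyx(res$peak_node, graph$dim)
  diagram <- tibble::tibble(
    fine = seq_len(n_fine),
    coarse = coarse_of_fine,
    peak_z = peak_zyx[, 1], peak_y = peak_zyx[, 2], peak_x = peak_zyx[, 3],
    birth = res$birth, death = res$death,
    lifespan = res$birth - res$death)

  coarse_sizes <- tabulate(coarse_of_fine[fine_per_node], nbins = length(coarse_roots))
  noise <- coarse_sizes < params$min_cluster_voxels

  structure(list(dim = graph$dim, lin = graph$lin, density = graph$density,
                 spacing_um = graph$spacing_um,
                 connectivity = graph$connectivity,
                 fine = fine_per_node, coarse_of_fine = coarse_of_fine,
                 comp_of_fine = res$comp_root,
                 noise = noise, diagram = diagram, params = params),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  cat(sprintf(paste0("cluster_hierarchy: %d foreground voxels, %d fine / %d ",
                     "coarse clusters (%d noise), delta = %g\n"),
              length(x$lin), max(x$fine), length(x$noise), sum(x$noise),
              x$params$delta))
  invisible(x)
}

#' Persistence diagram of a clustering
#'
#' @param h a `cluster_hierarchy`.
#' @return Tibble with one row per fine cluster (peak coordinate, birth,
#'   death, lifespan), sorted by descending lifespan.
#' @export
persistence_diagram <- function(h) {
  stopifnot(inherits(h, "cluster_hierarchy"))
  d <- h$diagram
  d[order(-d$lifespan, d$fine), ]
}

#' Export a persistence diagram as CSV
#'
#' @param h a `cluster_hierarchy`.
#' @param path output CSV path.
#' @export
export_diagram <- function(h, path) {
  write.csv(persistence_diagram(h), path, row.names = FALSE)
  invisible(path)
}

#' Cut a cluster hierarchy into a label volume
#'
#' @param h a `cluster_hierarchy`.
#' @param level `"coarse"` (delta-merged putative cells) or `"fine"` (one
#'   label per local-maximum basin, the editable units). Fine labels always
#'   refine coarse labels.
#' @param drop_noise set noise-flagged coarse clusters (and their fine
#'   clusters) to background (default TRUE).
#' @return A [label_volume].
#' @export
cut_hierarchy <- function(h, level = c("coarse", "fine"), drop_noise = TRUE) {
  stopifnot(inherits(h, "cluster_hierarchy"))
  level <- match.arg(level)
  lab_of_fine <- if (level == "fine") seq_along(h$coarse_of_fine) else h$coarse_of_fine
  if (drop_noise) lab_of_fine[h$noise[h$coarse_of_fine]] <- 0L
  out <- array(0L, dim = h$dim)
  out[h$lin] <- lab_of_fine[h$fine]
  label_volume(out, h$spacing_um)
}
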