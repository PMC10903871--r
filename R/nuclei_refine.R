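#' Simple nuclear segmentation fallback
#'
#' Thresholds the nuclear channel (Otsu when no threshold is given), labels
#' 3D connected components, and drops components below a size floor. External
#' nuclear masks from a dedicated segmenter are the first-class path (load
#' them with [read_labels()]); this fallback exists so the pipeline runs
#' end-to-end without any model.
#'
#' @param nuclei_channel 3D intensity array.
#' @param spacing_um voxel spacing `(z, y, x)` in micrometres.
#' @param threshold optional intensity threshold; Otsu if `NULL`.
#' @param min_voxels drop components smaller than this many voxels.
#' @param connectivity 6, 18 or 26.
#' @return A [label_volume] with nuclei labeled `1..N` in scan order.
#' @export
segment_nuclei_simple <- function(nuclei_channel, spacing_um, threshold = NULL,
                                  min_voxels = 1L, connectivity = 26L) {
  if (is.null(threshold)) threshold <- otsu_threshold(nuclei_channel)
  mask <- nuclei_channel >= threshold
  label_components(mask, spacing_um, connectivity, min_voxels = min_voxels)
}

# 3D connected-component labeling: degenerate ToMATo run at unit density and
# delta = Inf (every component collapses to one cluster). Components are
# numbered 1..N by first voxel in (z, y, x) scan order.
label_components <- function(mask, spacing_um, connectivity = 26L,
                             min_voxels = 1L) {
  out <- array(0L, dim = dim(mask))
  lin <- which(mask)
  if (length(lin) > 0L) {
    res <- tomato_cpp(dim(mask), lin, rep(1, length(lin)),
                      as.integer(connectivity), Inf)
    comp <- res$coarse_root[res$fine]       # nodes already in lex order
    sizes <- tabulate(comp, nbins = max(comp))
    keep <- sizes >= min_voxels
    relab <- integer(max(comp))
    first_seen <- unique(comp)              # founding order = scan order
    nxt <- 1L
    for (r in first_seen) if (keep[r]) { relab[r] <- nxt; nxt <- nxt + 1L }
    out[lin] <- relab[comp]
  }
  label_volume(out, spacing_um)
}

#' Cluster-nucleus overlap table
#'
#' Exact shared-voxel counts for every (cluster, nucleus) label pair meeting
#' the overlap floor.
#'
#' @param clusters,nuclei [label_volume]s over the same grid.
#' @param min_overlap_voxels pairs sharing fewer voxels are dropped
#'   (default 1: any intersection counts).
#' @return Tibble with columns `cluster`, `nucleus`, `voxels`, sorted by
#'   (cluster, nucleus).
#' @export
overlap_table <- function(clusters, nuclei, min_overlap_voxels = 1L) {
  stopifnot(inherits(clusters, "label_volume"), inherits(nuclei, "label_volume"))
  if (!identical(dim(clusters$labels), dim(nuclei$labels)))
    stop("label volume shapes differ")
  sel <- clusters$labels > 0L & nuclei$labels > 0L
  if (!any(sel))
    return(tibble::tibble(cluster = integer(), nucleus = integer(),
                          voxels = integer()))
  tb <- dplyr::count(
    tibble::tibble(cluster = as.integer(clusters$labels[sel]),
                   nucleus = as.integer(nuclei$labels[sel])),
    .data$cluster, .data$nucleus, name = "voxels")
  tb <- tb[tb$voxels >= min_overlap_voxels, ]
  dplyr::arrange(tb, .data$cluster, .data$nucleus)
}

#' Split a multinucleate cluster by seeded geodesic propagation
#'
#' Partitions a cluster's voxels among the nuclei it overlaps: multi-source
#' shortest paths on the cluster's voxel subgraph, seeded at each nucleus's
#' overlap voxels, with edge lengths equal to the physical (spacing-scaled)
#' Euclidean grid step so anisotropic z does not distort the split. Distance
#' ties go to the smaller nucleus id. Every subcluster contains its seeds and
#' is connected, and the subclusters partition the cluster.
#'
#' @param cluster_lin 1-based linear voxel indices of the cluster.
#' @param seed_of integer vector parallel to `cluster_lin`: nucleus id of
#'   seed voxels, 0 elsewhere.
#' @param dim volume dimensions `(z, y, x)`.
#' @param spacing_um voxel spacing `(z, y, x)` in micrometres.
#' @param connectivity 6, 18 or 26.
#' @return Integer vector parallel to `cluster_lin`: assigned nucleus id.
#' @export
split_multinucleate <- function(cluster_lin, seed_of, dim, spacing_um,
                                connectivity = 26L) {
  if (length(cluster_lin) != length(seed_of))
    stop("seed_of must be parallel to cluster_lin")
  if (!any(seed_of > 0L))
    stop("no seed voxels: overlap table inconsistent with the label volumes")
  geodesic_partition_cpp(as.integer(dim), as.integer(cluster_lin),
                         as.integer(seed_of), as.numeric(spacing_um),
                         as.integer(connectivity))
}

#' Refinement parameters
#'
#' @param min_overlap_voxels minimum shared voxels for a cluster-nucleus
#'   overlap to count (default 1).
#' @export
refine_params <- function(min_overlap_voxels = 1L) {
  structure(list(min_overlap_voxels = as.integer(min_overlap_voxels)),
            class = "refine_params")
}

#' Refine clusters into a one-to-one cell/nucleus segmentation
#'
#' Applies the three nucleus-driven rules to the coarse clusters: clusters
#' overlapping no nucleus are removed (likely incomplete cells or artifacts);
#' clusters overlapping two or more nuclei are split with
#' [split_multinucleate()]; clusters (or split parts) overlapping the same
#' single nucleus are merged into one cell. Removal runs first, then
#' splitting, then merging; after the split every voxel set maps to a single
#' nucleus, so the final bijection is the same under any ordering of the
#' three rules. The result binds each cell to exactly one nucleus.
#'
#' Applying `refine` to its own output is the identity: each refined cell
#' already overlaps exactly its own nucleus.
#'
#' @param h a `cluster_hierarchy` (or an existing `cell_segmentation` to
#'   re-refine).
#' @param nuclei a [label_volume] of nuclear instances over the same grid.
#' @param params a [refine_params] object.
#' @return A `cell_segmentation`: cell label volume, updated fine label
#'   volume (fine clusters divided by a split get fresh ids), the
#'   cell-to-fine-cluster map, and the injective `nucleus_of` map.
#' @export
refine <- function(h, nuclei, params = refine_params()) {
  stopifnot(inherits(nuclei, "label_volume"))
  if (inherits(h, "cluster_hierarchy")) {
    clusters <- cut_hierarchy(h, "coarse", drop_noise = TRUE)
    fine <- cut_hierarchy(h, "fine", drop_noise = TRUE)
    connectivity <- h$connectivity
  } else if (inherits(h, "cell_segmentation")) {
    clusters <- h$cell_labels
    fine <- h$fine_labels
    connectivity <- h$connectivity
  } else stop("`h` must be a cluster_hierarchy or cell_segmentation")
  if (!identical(dim(clusters$labels), dim(nuclei$labels)))
    stop("clusters and nuclei are on different grids")

  dm <- dim(clusters$labels)
  spacing <- clusters$spacing_um
  ov <- overlap_table(clusters, nuclei, params$min_overlap_voxels)

  # R1: drop clusters with no nucleus; R3: split multinucleate clusters.
  # After these, every retained voxel set maps to exactly one nucleus.
  nuc_of_voxel_sets <- list()   # per retained part: list(lin, nucleus)
  for (cl in unique(ov$cluster)) {
    nuc <- ov$nucleus[ov$cluster == cl]
    lin <- which(clusters$labels == cl)
    if (length(nuc) == 1L) {
      nuc_of_voxel_sets[[length(nuc_of_voxel_sets) + 1L]] <-
        list(lin = lin, nucleus = nuc)
    } else {
      seed <- as.integer(nuclei$labels[lin])
      seed[!seed %in% nuc] <- 0L
      part <- split_multinucleate(lin, seed, dm, spacing, connectivity)
      for (nu in nuc)
        nuc_of_voxel_sets[[length(nuc_of_voxel_sets) + 1L]] <-
          list(lin = lin[part == nu], nucleus = nu)
    }
  }

  # R2: merge parts sharing a nucleus; cells numbered by ascending nucleus id
  nuc_ids <- sort(unique(vapply(nuc_of_voxel_sets, `[[`, 0L, "nucleus")))
  cell_lab <- array(0L, dim = dm)
  for (p in nuc_of_voxel_sets)
    cell_lab[p$lin] <- match(p$nucleus, nuc_ids)

  # rebuild fine labels: a fine cluster divided by a split gets one fresh id
  # per part so edits stay cluster-granular and consistent with cells
  sel <- cell_lab > 0L
  key <- paste(fine$labels[sel], cell_lab[sel])
  new_fine <- array(0L, dim = dm)
  new_fine[sel] <- as.integer(factor(key, levels = unique(key)))

  cells <- lapply(seq_along(nuc_ids), function(cid)
    sort(unique(as.integer(new_fine[cell_lab == cid]))))
  names(cells) <- as.character(seq_along(nuc_ids))

  structure(list(cell_labels = label_volume(cell_lab, spacing),
                 fine_labels = label_volume(new_fine, spacing),
                 cells = cells,
                 nucleus_of = setNames(as.integer(nuc_ids),
                                       as.character(seq_along(nuc_ids))),
                 connectivity = connectivity),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("cell_segmentation: %d cell(s), %d fine cluster(s), %d voxels\n",
              length(x$cells), max(c(0L, x$fine_labels$labels)),
              sum(x$cell_labels$labels > 0L)))
  invisible(x)
}

#' Per-cell manifest of a segmentation
#'
#' @param seg a `cell_segmentation`.
#' @return Tibble with one row per cell: cell id, nucleus id, voxel count,
#'   volume in cubic micrometres, and bounding box.
#' @export
cell_manifest <- function(seg) {
  stopifnot(inherits(seg, "cell_segmentation"))
  lab <- seg$cell_labels$labels
  sp <- seg$cell_labels$spacing_um
  ids <- seq_along(seg$cells)
  rows <- lapply(ids, function(cid) {
    lin <- which(lab == cid)
    zyx <- lin_to_zyx(lin, dim(lab))
    tibble::tibble(cell = cid, nucleus = unname(seg$nucleus_of[as.character(cid)]),
                   voxels = length(lin), volume_um3 = length(lin) * prod(sp),
                   z0 = min(zyx[, 1]), z1 = max(zyx[, 1]),
                   y0 = min(zyx[, 2]), y1 = max(zyx[, 2]),
                   x0 = min(zyx[, 3]), x1 = max(zyx[, 3]))
  })
  dplyr::bind_rows(rows)
}
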