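#' Start an editing session over a segmentation
#'
#' Cluster-level proofreading of a cell segmentation: fine clusters (the
#' editable units, never single voxels) can be moved into or out of cells,
#' every operation is logged, and replaying the log on the base state
#' reproduces the current state exactly, so a previous segmentation can be
#' resumed and refined.
#'
#' @param seg a `cell_segmentation` from [refine()] (fine clusters outside
#'   any cell — removed or noise clusters — remain addable; pass a
#'   `fine_labels` volume covering them to make them available).
#' @param fine_labels optional [label_volume] of fine clusters covering the
#'   full original foreground (defaults to the segmentation's own).
#' @return An `edit_session`.
#' @export
edit_session <- function(seg, fine_labels = NULL) {
  stopifnot(inherits(seg, "cell_segmentation"))
  if (is.null(fine_labels)) fine_labels <- seg$fine_labels
  stopifnot(inherits(fine_labels, "label_volume"))
  base <- list(cells = seg$cells, nucleus_of = seg$nucleus_of,
               fine_labels = fine_labels, connectivity = seg$connectivity)
  structure(list(base = base, cells = seg$cells, nucleus_of = seg$nucleus_of,
                 ops_log = empty_log(), version = 1L),
            class = "edit_session")
}

empty_log <- function() {
  tibble::tibble(op = character(), cell = integer(), cluster = integer(),
                 force = logical(), time = character())
}

log_row <- function(op, cell, cluster, force = FALSE) {
  tibble::tibble(op = op, cell = as.integer(cell), cluster = as.integer(cluster),
                 force = force, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
}

owner_of <- function(s, cluster_id) {
  for (cid in names(s$cells))
    if (cluster_id %in% s$cells[[cid]]) return(as.integer(cid))
  NA_integer_
}

#' Assign a fine cluster to a cell
#'
#' The cluster must be grid-adjacent (share at least one voxel-graph edge) to
#' the target cell unless `force = TRUE`. A cluster owned by another cell is
#' moved; assigning a cluster already in the target cell is an error. A
#' cluster can never belong to two cells.
#'
#' @param s an `edit_session`.
#' @param cell_id target cell id.
#' @param fine_cluster_id fine cluster to add.
#' @param force skip the adjacency requirement.
#' @return The updated session.
#' @export
add_cluster <- function(s, cell_id, fine_cluster_id, force = FALSE) {
  stopifnot(inherits(s, "edit_session"))
  cell_id <- as.integer(cell_id); fine_cluster_id <- as.integer(fine_cluster_id)
  if (!as.character(cell_id) %in% names(s$cells)) stop("unknown cell id ", cell_id)
  fl <- s$base$fine_labels$labels
  clus_lin <- which(fl == fine_cluster_id)
  if (length(clus_lin) == 0L) stop("unknown fine cluster id ", fine_cluster_id)
  if (fine_cluster_id %in% s$cells[[as.character(cell_id)]])
    stop("cluster ", fine_cluster_id, " already belongs to cell ", cell_id)
  if (!force) {
    cell_lin <- which(fl %in% s$cells[[as.character(cell_id)]])
    adj <- count_adjacent_pairs_cpp(dim(fl), clus_lin, cell_lin,
                                    s$base$connectivity)
    if (adj == 0) stop("cluster ", fine_cluster_id, " is not adjacent to cell ",
                       cell_id, " (use force = TRUE to override)")
  }
  s <- apply_op(s, "add", cell_id, fine_cluster_id)
  s$ops_log <- dplyr::bind_rows(s$ops_log, log_row("add", cell_id,
                                                   fine_cluster_id, force))
  s
}

#' Remove a fine cluster from a cell
#'
#' Removing the last cluster of a cell deletes the cell (and this is what
#' replay reproduces); the cluster becomes unassigned either way.
#'
#' @inheritParams add_cluster
#' @param fine_cluster_id fine cluster to remove; must belong to the cell.
#' @return The updated session.
#' @export
remove_cluster <- function(s, cell_id, fine_cluster_id) {
  stopifnot(inherits(s, "edit_session"))
  cell_id <- as.integer(cell_id); fine_cluster_id <- as.integer(fine_cluster_id)
  if (!as.character(cell_id) %in% names(s$cells)) stop("unknown cell id ", cell_id)
  if (!fine_cluster_id %in% s$cells[[as.character(cell_id)]])
    stop("cluster ", fine_cluster_id, " does not belong to cell ", cell_id)
  s <- apply_op(s, "remove", cell_id, fine_cluster_id)
  s$ops_log <- dplyr::bind_rows(s$ops_log, log_row("remove", cell_id,
                                                   fine_cluster_id))
  s
}

# state transition shared by live editing and replay
apply_op <- function(s, op, cell_id, cluster_id) {
  key <- as.character(cell_id)
  if (op == "add") {
    prev <- owner_of(s, cluster_id)
    if (!is.na(prev)) {
      pk <- as.character(prev)
      s$cells[[pk]] <- setdiff(s$cells[[pk]], cluster_id)
      if (length(s$cells[[pk]]) == 0L) {
        s$cells[[pk]] <- NULL
        s$nucleus_of <- s$nucleus_of[names(s$nucleus_of) != pk]
      }
    }
    s$cells[[key]] <- sort(c(s$cells[[key]], cluster_id))
  } else if (op == "remove") {
    s$cells[[key]] <- setdiff(s$cells[[key]], cluster_id)
    if (length(s$cells[[key]]) == 0L) {
      s$cells[[key]] <- NULL
      s$nucleus_of <- s$nucleus_of[names(s$nucleus_of) != key]
    }
  } else stop("unknown op: ", op)
  s
}

#' Replay an operations log on a session's base state
#'
#' @param s an `edit_session`.
#' @return A session whose state is the base patched by the log; equal to the
#'   live session for any sequence of edits.
#' @export
replay_session <- function(s) {
  stopifnot(inherits(s, "edit_session"))
  out <- s
  out$cells <- s$base$cells
  out$nucleus_of <- s$base$nucleus_of
  for (i in seq_len(nrow(s$ops_log)))
    out <- apply_op(out, s$ops_log$op[i], s$ops_log$cell[i], s$ops_log$cluster[i])
  out
}

#' Current cell label volume of a session
#'
#' @param s an `edit_session`.
#' @return A [label_volume] of cell ids; never contains voxels outside the
#'   original foreground (edits only move whole fine clusters).
#' @export
session_labels <- function(s) {
  stopifnot(inherits(s, "edit_session"))
  fl <- s$base$fine_labels$labels
  out <- array(0L, dim = dim(fl))
  for (cid in names(s$cells))
    out[fl %in% s$cells[[cid]]] <- as.integer(cid)
  label_volume(out, s$base$fine_labels$spacing_um)
}

#' Save an editing session
#'
#' Writes a versioned JSON manifest plus the base fine-label TIFF next to it,
#' so the session can be reloaded and the log replayed later.
#'
#' @param s an `edit_session`.
#' @param path output path for the JSON manifest; the fine labels go to the
#'   same path with a `_fine.tif` suffix.
#' @export
save_session <- function(s, path) {
  stopifnot(inherits(s, "edit_session"))
  tif <- sub("\\.json$", "", path)
  tif <- paste0(tif, "_fine.tif")
  write_labels(tif, s$base$fine_labels)
  manifest <- list(
    schema = "pbcseg-edit-session", version = s$version,
    connectivity = s$base$connectivity,
    spacing_um = s$base$fine_labels$spacing_um,
    fine_labels_file = basename(tif),
    base_cells = s$base$cells,
    base_nucleus_of = as.list(s$base$nucleus_of),
    ops_log = s$ops_log)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an editing session
#'
#' @param path JSON manifest written by [save_session()].
#' @return The `edit_session`, with the log replayed onto the base state.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("corrupt session file: ",
                                         conditionMessage(e)))
  if (!identical(m$schema, "pbcseg-edit-session"))
    stop("not an edit-session file")
  if (!identical(as.integer(m$version), 1L))
    stop("unsupported session version: ", m$version)
  fl <- read_labels(file.path(dirname(path), m$fine_labels_file), m$spacing_um)
  base <- list(cells = lapply(m$base_cells, as.integer),
               nucleus_of = setNames(as.integer(unlist(m$base_nucleus_of)),
                                     names(m$base_nucleus_of)),
               fine_labels = fl, connectivity = as.integer(m$connectivity))
  log <- tibble::as_tibble(m$ops_log)
  if (nrow(log) == 0L) log <- empty_log()
  s <- structure(list(base = base, cells = base$cells,
                      nucleus_of = base$nucleus_of,
                      ops_log = log, version = 1L),
                 class = "edit_session")
  replay_session(s)
}
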