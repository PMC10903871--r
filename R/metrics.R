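#' Match predicted to ground-truth cells
#'
#' Greedy one-to-one matching by descending shared-voxel count, ties broken
#' by (gt id, pred id); pairs with zero overlap are never matched.
#'
#' @param pred,gt [label_volume]s over the same grid.
#' @return Tibble with columns `pred`, `gt`, `overlap` (one row per matched
#'   pair); attributes `unmatched_pred` and `unmatched_gt` list leftover ids.
#' @export
match_cells <- function(pred, gt) {
  stopifnot(inherits(pred, "label_volume"), inherits(gt, "label_volume"))
  if (!identical(dim(pred$labels), dim(gt$labels)))
    stop("label volume shapes differ")
  ov <- overlap_table(pred, gt, min_overlap_voxels = 1L)
  names(ov) <- c("pred", "gt", "overlap")
  ov <- ov[order(-ov$overlap, ov$gt, ov$pred), ]
  used_p <- integer(); used_g <- integer(); keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    if (ov$pred[i] %in% used_p || ov$gt[i] %in% used_g) next
    keep[i] <- TRUE
    used_p <- c(used_p, ov$pred[i]); used_g <- c(used_g, ov$gt[i])
  }
  out <- ov[keep, ]
  attr(out, "unmatched_pred") <-
    setdiff(sort(unique(as.integer(pred$labels[pred$labels > 0L]))), out$pred)
  attr(out, "unmatched_gt") <-
    setdiff(sort(unique(as.integer(gt$labels[gt$labels > 0L]))), out$gt)
  out
}

#' Voxel overlap scores for one cell
#'
#' F1 (Dice) and Jaccard plus false positive / false negative percentages.
#' The percentage denominators are the ground-truth cell's voxel count, so
#' either percentage can exceed 100 when the prediction is much larger than
#' the truth.
#'
#' @param pred_mask,gt_mask 3D logical arrays of equal shape; `gt_mask` must
#'   be non-empty.
#' @return Tibble row with `tp`, `fp`, `fn`, `f1`, `jaccard`, `fp_pct`,
#'   `fn_pct`.
#' @export
cell_scores <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) stop("mask shapes differ")
  ngt <- sum(gt_mask)
  if (ngt == 0L) stop("empty ground-truth mask")
  tp <- sum(pred_mask & gt_mask)
  fp <- sum(pred_mask & !gt_mask)
  fn <- ngt - tp
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 f1 = 2 * tp / (2 * tp + fp + fn),
                 jaccard = tp / (tp + fp + fn),
                 fp_pct = 100 * fp / ngt,
                 fn_pct = 100 * fn / ngt)
}

#' Voxel-wise error map
#'
#' Codes every voxel of the union of prediction and truth: 1 = true
#' positive, 2 = false positive, 3 = false negative.
#'
#' @param pred,gt 3D logical arrays of equal shape, or [label_volume]s whose
#'   nonzero voxels are used.
#' @param spacing_um spacing for the output (taken from `pred` when it is a
#'   [label_volume]).
#' @return A [label_volume] of error codes.
#' @export
error_map <- function(pred, gt, spacing_um = c(1, 1, 1)) {
  if (inherits(pred, "label_volume")) { spacing_um <- pred$spacing_um; pred <- pred$labels > 0L }
  if (inherits(gt, "label_volume")) gt <- gt$labels > 0L
  if (!identical(dim(pred), dim(gt))) stop("shapes differ")
  out <- array(0L, dim = dim(pred))
  out[pred & gt] <- 1L
  out[pred & !gt] <- 2L
  out[!pred & gt] <- 3L
  label_volume(out, spacing_um)
}

#' Evaluate a segmentation against ground truth
#'
#' Matches cells with [match_cells()] and scores every matched pair with
#' [cell_scores()], treating each segmented cell as a data point.
#'
#' @param pred,gt [label_volume]s over the same grid.
#' @return An `eval_report`: a tibble with one row per matched cell and
#'   attributes `unmatched_pred` / `unmatched_gt`.
#' @export
evaluate_segmentation <- function(pred, gt) {
  m <- match_cells(pred, gt)
  rows <- lapply(seq_len(nrow(m)), function(i)
    dplyr::bind_cols(tibble::tibble(pred = m$pred[i], gt = m$gt[i]),
                     cell_scores(pred$labels == m$pred[i],
                                 gt$labels == m$gt[i])))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    out <- tibble::tibble(pred = integer(), gt = integer(), tp = integer(),
                          fp = integer(), fn = integer(), f1 = double(),
                          jaccard = double(), fp_pct = double(),
                          fn_pct = double())
  attr(out, "unmatched_pred") <- attr(m, "unmatched_pred")
  attr(out, "unmatched_gt") <- attr(m, "unmatched_gt")
  class(out) <- c("eval_report", class(out))
  out
}

#' Summarize an evaluation report
#'
#' Mean and standard deviation of each score across cells.
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return Tibble with one row per metric: `mean`, `sd`, `n`.
#' @export
summary.eval_report <- function(object, ...) {
  mets <- c("f1", "jaccard", "fp_pct", "fn_pct")
  tibble::tibble(
    metric = mets,
    mean = vapply(mets, function(m) mean(object[[m]]), 0, USE.NAMES = FALSE),
    sd = vapply(mets, function(m) sd(object[[m]]), 0, USE.NAMES = FALSE),
    n = nrow(object))
}
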