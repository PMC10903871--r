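#' Plot a persistence diagram
#'
#' Death versus birth of every fine cluster; points far from the diagonal are
#' the prominent peaks that survive a given prominence threshold, which can
#' be drawn as an offset guide line.
#'
#' @param h a `cluster_hierarchy` or a diagram tibble from
#'   [persistence_diagram()].
#' @param delta optional prominence threshold to draw as a dashed guide.
#' @return A ggplot object.
#' @export
plot_persistence_diagram <- function(h, delta = NULL) {
  d <- if (inherits(h, "cluster_hierarchy")) {
    if (is.null(delta)) delta <- h$params$delta
    persistence_diagram(h)
  } else h
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$birth, y = .data$death)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "birth (intensity)", y = "death (intensity)",
                  title = "0-dimensional persistence diagram") +
    ggplot2::theme_minimal()
  if (!is.null(delta))
    p <- p + ggplot2::geom_abline(slope = 1, intercept = -delta,
                                  linetype = "dashed", color = "firebrick")
  p
}

#' Plot per-cell evaluation scores
#'
#' One point per segmented cell for each metric, with mean and standard
#' deviation overlaid.
#'
#' @param report an `eval_report` from [evaluate_segmentation()].
#' @return A ggplot object.
#' @export
plot_eval_report <- function(report) {
  long <- dplyr::bind_rows(lapply(c("f1", "jaccard", "fp_pct", "fn_pct"),
    function(m) tibble::tibble(metric = m, value = report[[m]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          color = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
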