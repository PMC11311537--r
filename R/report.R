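# Rendering the QC report: a clustered percentile-rank heatmap (dendrograms,
# condition colour strip, darker shades = lower ranks) plus a tab-delimited
# export of the ranked matrix in clustered order.

#' Render the clustered heatmap report
#'
#' Writes (a) a heatmap image with row/column dendrograms and, when group
#' labels are present, a condition colour strip — grayscale fill mapped so
#' that rank 0 is darkest and rank 100 lightest — and (b) a TSV export of
#' the percentile-ranked matrix with rows and columns in clustered order.
#'
#' @param mat A percentile-ranked `mzqc_metric_matrix` (see
#'   [percentile_rank_matrix()]).
#' @param orders Clustering orders from [cluster_metric_matrix()]; computed
#'   here if missing.
#' @param group_labels Optional named vector run -> condition; defaults to
#'   the matrix's own labels.
#' @param out_prefix Output path prefix; `<prefix>.png` and `<prefix>.tsv`
#'   are written.
#' @return Invisible named character vector with elements `image` and
#'   `table`.
#' @export
render_qc_report <- function(mat, orders = NULL, group_labels = NULL,
                             out_prefix = "qc_report") {
  stopifnot(inherits(mat, "mzqc_metric_matrix"))
  out_dir <- dirname(out_prefix)
  if (!dir.exists(out_dir)) {
    mzqc_abort(sprintf("output directory '%s' does not exist", out_dir),
               class = "mzqc_io_error")
  }
  orders <- orders %||% cluster_metric_matrix(mat)
  group_labels <- group_labels %||% mat$group_labels
  v <- mat$values[orders$metric_order, orders$run_order, drop = FALSE]

  img_path <- paste0(out_prefix, ".png")
  tsv_path <- paste0(out_prefix, ".tsv")

  ann <- NA
  if (!is.null(group_labels)) {
    ann <- data.frame(condition = unname(group_labels[colnames(v)]),
                      row.names = colnames(v))
  }
  # the hclust objects were fitted on the label-sorted matrix
  vs <- mat$values[sort(rownames(mat$values)), sort(colnames(mat$values)),
                   drop = FALSE]
  shades <- grDevices::gray.colors(101, start = 0.05, end = 0.97, gamma = 1)
  pheatmap::pheatmap(
    vs,
    cluster_rows = orders$metric_hclust,
    cluster_cols = orders$run_hclust,
    color = shades, breaks = seq(0, 100, length.out = 102),
    annotation_col = ann, filename = img_path, silent = TRUE,
    main = "QC metrics, percentile-ranked")

  tab <- tibble::as_tibble(v, rownames = "metric")
  readr::write_tsv(tab, tsv_path, progress = FALSE)
  invisible(c(image = img_path, table = tsv_path))
}

#' Heatmap of a metric matrix as a ggplot
#'
#' A tile heatmap of the (typically percentile-ranked) matrix with darker
#' tiles for lower values; rows and columns follow the clustered order when
#' `orders` is given.
#'
#' @param object An `mzqc_metric_matrix`.
#' @param orders Optional result of [cluster_metric_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mzqc_metric_matrix <- function(object, orders = NULL, ...) {
  long <- tidy(object)
  if (!is.null(orders)) {
    long$metric <- factor(long$metric, levels = rev(orders$metric_order))
    long$run <- factor(long$run, levels = orders$run_order)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$metric,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey10", high = "grey95",
                                 limits = c(0, 100), name = "percentile\nrank") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
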