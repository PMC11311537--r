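# Runs x metrics matrix, percentile-rank scaling, and hierarchical
# clustering of both axes — the machinery behind the heatmap report.

#' Describe how to pull one numeric value per run out of a document
#'
#' A selection row names a metric accession and how to reduce its value to a
#' single number: `"value"` for scalars, a summary statistic (`"sum"`,
#' `"mean"`, `"median"`, `"min"`, `"max"`, `"count"`) over a table column or
#' a tuple, or an integer position into a tuple via `index`.
#'
#' @param accession Metric accession.
#' @param label Row label in the matrix (defaults to the catalog name or the
#'   accession).
#' @param reduce Reduction: `"value"`, `"sum"`, `"mean"`, `"median"`,
#'   `"min"`, `"max"`, `"count"`, or `"index"`.
#' @param column Table column the reduction applies to (defaults to the last
#'   numeric column).
#' @param index 1-based tuple position when `reduce = "index"`.
#' @return A one-row tibble; rows from several calls can be bound together.
#' @export
metric_selection <- function(accession, label = NULL, reduce = "value",
                             column = NA_character_, index = NA_integer_) {
  tibble::tibble(accession = accession, label = label %||% accession,
                 reduce = reduce, column = column, index = as.integer(index))
}

#' Default metric selection for the heatmap report
#'
#' Scalar counts as-is, summed total ion current, maximum base peak
#' intensity, median injection times per MS level, mean and spread of the
#' precursor mass error, the fraction-defining counts of the missed-cleavage
#' histogram (count at zero), and the width of the identified RT range.
#'
#' @return A selection tibble, see [metric_selection()].
#' @export
default_metric_selection <- function() {
  dplyr::bind_rows(
    metric_selection("QCX:0000020", "MS/MS spectrum count"),
    metric_selection("QCX:0000021", "identified MS/MS spectra"),
    metric_selection("QCX:0000022", "identified peptides"),
    metric_selection("QCX:0000023", "identified proteins"),
    metric_selection("QCX:0000004", "summed total ion current",
                     reduce = "sum", column = "intensity"),
    metric_selection("QCX:0000005", "max base peak intensity",
                     reduce = "max", column = "intensity"),
    metric_selection("QCX:0000010", "median MS1 injection time (ms)",
                     reduce = "index", index = 4L),
    metric_selection("QCX:0000011", "median MS2 injection time (ms)",
                     reduce = "index", index = 4L),
    metric_selection("QCX:0000025", "mean precursor mass error (ppm)",
                     reduce = "index", index = 1L),
    metric_selection("QCX:0000026", "PSMs without missed cleavage",
                     reduce = "index", index = 1L, column = "count"),
    metric_selection("QCX:0000027", "identified RT range width (s)",
                     reduce = "range-width")
  )
}

reduce_value <- function(value, reduce, column, index, accession) {
  data <- value$data
  if (value$kind == "table") {
    col <- if (!is.na(column)) column else {
      num <- names(data)[vapply(data, is.numeric, logical(1))]
      if (!length(num)) mzqc_abort(sprintf("metric %s has no numeric column", accession))
      num[length(num)]
    }
    if (!col %in% names(data)) {
      mzqc_abort(sprintf("metric %s has no column '%s'", accession, col))
    }
    data <- data[[col]]
  }
  if (value$kind == "tuple") data <- unlist(as.list(data))
  if (value$kind == "scalar" && !identical(reduce, "value")) {
    # a scalar has nothing to reduce; take it as-is
    reduce <- "value"
  }
  switch(reduce,
    "value" = as.numeric(data[[1]]),
    "sum" = sum(data), "mean" = mean(data), "median" = stats::median(data),
    "min" = min(data), "max" = max(data), "count" = length(data),
    "index" = as.numeric(data[[index]]),
    "range-width" = as.numeric(data[[2]] - data[[1]]),
    mzqc_abort(sprintf("unknown reduction '%s'", reduce))
  )
}

#' Build the runs x metrics matrix from a merged document
#'
#' One row per selected metric, one column per runQuality (labelled by the
#' first input file's name); a run lacking a metric yields a missing cell.
#'
#' @param doc A merged `mzqc_document`.
#' @param selection Selection tibble, see [metric_selection()]; defaults to
#'   [default_metric_selection()]. A selected accession that appears in no
#'   run of the document is an error.
#' @param group_labels Optional named character vector mapping run label to a
#'   condition tag (used as the heatmap's colour strip).
#' @return An `mzqc_metric_matrix`: list with `values` (numeric matrix,
#'   metrics x runs), `metric_labels`, `run_labels`, `group_labels`.
#' @export
build_metric_matrix <- function(doc, selection = default_metric_selection(),
                                group_labels = NULL) {
  stopifnot(inherits(doc, "mzqc_document"))
  els <- doc$runQualities
  if (!length(els)) mzqc_abort("document has no runQualities")
  run_labels <- vapply(els, function(el) el$metadata$inputFiles[[1]]$name,
                       character(1))
  values <- matrix(NA_real_, nrow = nrow(selection), ncol = length(els),
                   dimnames = list(selection$label, run_labels))
  seen_any <- logical(nrow(selection))
  for (j in seq_along(els)) {
    metrics <- els[[j]]$qualityMetrics
    accs <- vapply(metrics, function(m) m$accession, character(1))
    for (i in seq_len(nrow(selection))) {
      k <- match(selection$accession[i], accs)
      if (is.na(k)) next
      seen_any[i] <- TRUE
      values[i, j] <- reduce_value(metrics[[k]]$value, selection$reduce[i],
                                   selection$column[i], selection$index[i],
                                   selection$accession[i])
    }
  }
  if (any(!seen_any)) {
    mzqc_abort(sprintf("selection names accession(s) absent from every run: %s",
                       paste(selection$accession[!seen_any], collapse = ", ")))
  }
  structure(list(values = values, metric_labels = rownames(values),
                 run_labels = run_labels,
                 group_labels = group_labels),
            class = "mzqc_metric_matrix")
}

#' Percentile ranks of a numeric vector (mean-rank convention)
#'
#' `rank(x) = 100 * (count(values < x) + 0.5 * count(values == x)) / n` over
#' the non-missing values; missing entries stay missing. Ties share their
#' mean rank, so an all-ties vector maps to all 50 and ranks always lie
#' strictly inside (0, 100).
#'
#' @param x Numeric vector, possibly with `NA`s (but at least one value).
#' @return Numeric vector of the same length with ranks in (0, 100).
#' @examples
#' percentile_rank(c(10, 20, 30, 40)) # 12.5 37.5 62.5 87.5
#' @export
percentile_rank <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) mzqc_abort("percentile_rank needs at least one non-missing value")
  out <- rep(NA_real_, length(x))
  v <- x[ok]
  out[ok] <- 100 * (rank(v, ties.method = "average") - 0.5) / length(v)
  out
}

#' Percentile-rank a metric matrix row-wise
#'
#' Each metric (row) is ranked across the runs, because the report compares
#' every metric across runs; ranking across metrics would mix units.
#'
#' @param mat An `mzqc_metric_matrix`.
#' @return The matrix with `values` replaced by percentile ranks and a
#'   `percentiled` flag set.
#' @export
percentile_rank_matrix <- function(mat) {
  stopifnot(inherits(mat, "mzqc_metric_matrix"))
  mat$values <- t(apply(mat$values, 1L, percentile_rank))
  dimnames(mat$values) <- list(mat$metric_labels, mat$run_labels)
  mat$percentiled <- TRUE
  mat
}

#' Hierarchical clustering orders for the heatmap
#'
#' Agglomerative clustering (average linkage, Euclidean distance over
#' pairwise-complete entries) applied independently to the metric rows and
#' the run columns of a percentile-ranked matrix. For determinism under
#' input permutation, rows and columns are pre-sorted by label before
#' clustering.
#'
#' @param mat An `mzqc_metric_matrix` (percentile-ranked), at least 2 x 2.
#' @param method Linkage method for [stats::hclust()].
#' @return List with `metric_order`, `run_order` (label character vectors in
#'   leaf order) and the underlying `metric_hclust`, `run_hclust` objects.
#'   A row/column sharing no complete entries with any other is an error
#'   naming it.
#' @export
cluster_metric_matrix <- function(mat, method = "average") {
  stopifnot(inherits(mat, "mzqc_metric_matrix"))
  v <- mat$values
  if (nrow(v) < 2L || ncol(v) < 2L) {
    mzqc_abort("clustering needs at least 2 metrics and 2 runs")
  }
  v <- v[order(rownames(v)), order(colnames(v)), drop = FALSE]
  cluster_axis <- function(m, what) {
    d <- stats::dist(m, method = "euclidean")
    if (anyNA(d)) {
      dm <- as.matrix(d)
      bad <- rownames(dm)[rowSums(!is.na(dm)) <= 1L]
      mzqc_abort(sprintf("%s '%s' has no pairwise-complete overlap with any other",
                         what, paste(bad, collapse = "', '")))
    }
    stats::hclust(d, method = method)
  }
  hr <- cluster_axis(v, "metric")
  hc <- cluster_axis(t(v), "run")
  list(metric_order = rownames(v)[hr$order],
       run_order = colnames(v)[hc$order],
       metric_hclust = hr, run_hclust = hc)
}

#' @export
print.mzqc_metric_matrix <- function(x, ...) {
  cat(sprintf("<metric matrix: %d metric(s) x %d run(s)%s>\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$percentiled)) ", percentile-ranked" else ""))
  print(x$values, ...)
  invisible(x)
}

#' Metric matrix in long (tidy) form
#'
#' @param x An `mzqc_metric_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `metric`, `run`, `value` and, if group labels
#'   are attached, `condition`.
#' @exportS3Method generics::tidy
tidy.mzqc_metric_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$values, rownames = "metric") |>
    tidyr::pivot_longer(-"metric", names_to = "run", values_to = "value")
  if (!is.null(x$group_labels)) {
    out$condition <- unname(x$group_labels[out$run])
  }
  out
}
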