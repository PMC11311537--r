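# Merging partial reports, the metric matrix, percentile ranking,
# clustering, and report rendering.

two_metric_docs <- function() {
  mA <- list(mzqc_metric("QCX:0000020", "MS/MS spectrum count", 100))
  mB <- list(mzqc_metric("QCX:0000001", "chromatogram count", 2))
  list(A = minimal_doc(mA), B = minimal_doc(mB))
}

test_that("merging one document is the identity up to creationDate", {
  doc <- minimal_doc()
  merged <- merge_mzqc(list(doc), creation_date = doc$creationDate)
  expect_true(mzqc_equal(merged, doc))
})

test_that("same run with disjoint metric sets coalesces to their union", {
  d <- two_metric_docs()
  merged <- merge_mzqc(list(d$A, d$B))
  expect_length(merged$runQualities, 1L)
  accs <- vapply(merged$runQualities[[1]]$qualityMetrics,
                 function(m) m$accession, character(1))
  expect_setequal(accs, c("QCX:0000020", "QCX:0000001"))
})

test_that("an identical duplicated metric merges without error, a conflicting one errors", {
  doc <- minimal_doc()
  merged <- merge_mzqc(list(doc, doc))
  expect_length(merged$runQualities[[1]]$qualityMetrics, 1L)

  changed <- minimal_doc(list(mzqc_metric("QCX:0000020", "MS/MS spectrum count", 11)))
  expect_error(merge_mzqc(list(doc, changed)),
               class = "mzqc_merge_conflict_error")
  expect_error(merge_mzqc(list(doc, changed)), "QCX:0000020")
  expect_warning(kept <- merge_mzqc(list(doc, changed), on_conflict = "keep-first"),
                 "keeping the first")
  expect_identical(kept$runQualities[[1]]$qualityMetrics[[1]]$value$data, 10)
})

test_that("merging is idempotent and order-insensitive for conflict-free input", {
  d <- two_metric_docs()
  m1 <- merge_mzqc(list(d$A, d$B), creation_date = "2024-06-26T12:00:00")
  m2 <- merge_mzqc(list(m1), creation_date = "2024-06-26T12:00:00")
  expect_true(mzqc_equal(m1, m2))
  m3 <- merge_mzqc(list(d$B, d$A), creation_date = "2024-06-26T12:00:00")
  a1 <- sort(vapply(m1$runQualities[[1]]$qualityMetrics, function(m) m$accession, ""))
  a3 <- sort(vapply(m3$runQualities[[1]]$qualityMetrics, function(m) m$accession, ""))
  expect_identical(a1, a3)
})

test_that("the metric matrix has one row per metric, one column per run", {
  exp <- small_experiment()
  docs <- experiment_to_documents(exp, creation_date = "2024-06-26T10:00:00")
  merged <- merge_mzqc(docs, creation_date = "2024-06-26T12:00:00")
  mat <- build_metric_matrix(merged)
  expect_identical(dim(mat$values), c(11L, 8L))
  expect_false(anyNA(mat$values))
  expect_error(
    build_metric_matrix(merged, metric_selection("QCX:9999999", "ghost")),
    "absent from every run")

  # TIC reduced by "sum" equals the generator's total intensity
  sel <- metric_selection("QCX:0000004", "tic sum", reduce = "sum",
                          column = "intensity")
  tic_row <- build_metric_matrix(merged, sel)$values[1, ]
  oracle <- vapply(exp$truth, function(tr) sum(tr$tic$intensity), numeric(1))
  expect_equal(unname(tic_row), unname(oracle[colnames(mat$values)]),
               tolerance = 1e-12)
})

test_that("a run lacking a metric yields exactly one missing cell", {
  d <- two_metric_docs()
  other <- minimal_doc(list(mzqc_metric("QCX:0000020", "MS/MS spectrum count", 7)))
  other$runQualities[[1]]$metadata$inputFiles[[1]]$name <- "run2"
  other$runQualities[[1]]$metadata$inputFiles[[1]]$location <- "file:///data/run2.mzML"
  merged <- merge_mzqc(list(d$A, d$B, other))
  mat <- build_metric_matrix(merged, dplyr::bind_rows(
    metric_selection("QCX:0000020", "msms"),
    metric_selection("QCX:0000001", "chroms")))
  expect_identical(sum(is.na(mat$values)), 1L)
  expect_true(is.na(mat$values["chroms", "run2"]))
})

test_that("percentile ranks follow the counting convention", {
  expect_equal(percentile_rank(c(10, 20, 30, 40)), c(12.5, 37.5, 62.5, 87.5))
  expect_equal(percentile_rank(rep(5, 4)), rep(50, 4))
  expect_equal(percentile_rank(42), 50)
  expect_error(percentile_rank(c(NA_real_, NA_real_)), "non-missing")
  x <- c(3, NA, 7, 7, 1)
  r <- percentile_rank(x)
  expect_true(is.na(r[2]))
  counting <- function(v, vals) 100 * (sum(vals < v) + 0.5 * sum(vals == v)) / length(vals)
  vals <- x[!is.na(x)]
  expect_equal(r[!is.na(x)], vapply(vals, counting, numeric(1), vals = vals))
})

test_that("percentile ranks are monotone-invariant and centred", {
  set.seed(12)
  for (i in 1:25) {
    x <- sample(1:8, 12, replace = TRUE) # ties likely
    expect_equal(percentile_rank(x), percentile_rank(exp(x / 2)))
    y <- sample(1:1000, 15) # tie-free
    r <- percentile_rank(y)
    expect_equal(mean(r), 50)
    expect_true(all(r > 0 & r < 100))
  }
})

test_that("identical runs cluster adjacently and blocks stay together", {
  # two well-separated blocks of runs, generator-controlled
  v <- rbind(m1 = c(10, 11, 90, 91), m2 = c(12, 10, 88, 93),
             m3 = c(8, 12, 95, 90))
  colnames(v) <- c("r1", "r2", "r3", "r4")
  mat <- structure(list(values = v,
                        metric_labels = rownames(v),
                        run_labels = c("r1", "r2", "r3", "r4"),
                        group_labels = NULL),
                   class = "mzqc_metric_matrix")
  orders <- cluster_metric_matrix(mat)
  pos <- match(c("r1", "r2", "r3", "r4"), orders$run_order)
  expect_equal(abs(pos[1] - pos[2]), 1)
  expect_equal(abs(pos[3] - pos[4]), 1)

  # zero-distance duplicate columns are adjacent leaves
  v2 <- cbind(v, r5 = v[, "r2"])
  mat2 <- structure(list(values = v2, metric_labels = rownames(v2),
                         run_labels = colnames(v2), group_labels = NULL),
                    class = "mzqc_metric_matrix")
  o2 <- cluster_metric_matrix(mat2)
  pos2 <- match(c("r2", "r5"), o2$run_order)
  expect_equal(abs(pos2[1] - pos2[2]), 1)
})

test_that("clustering is invariant under input column permutation (tie-free)", {
  set.seed(31)
  v <- matrix(runif(6 * 5, 0, 100), nrow = 6,
              dimnames = list(paste0("m", 1:6), paste0("r", 1:5)))
  mk <- function(vals) structure(
    list(values = vals, metric_labels = rownames(vals),
         run_labels = colnames(vals), group_labels = NULL),
    class = "mzqc_metric_matrix")
  o1 <- cluster_metric_matrix(mk(v))
  perm <- c(4, 1, 5, 2, 3)
  o2 <- cluster_metric_matrix(mk(v[, perm]))
  expect_identical(o1$run_order, o2$run_order)
  expect_equal(o1$run_hclust$height, o2$run_hclust$height)
})

test_that("a column with no pairwise overlap is an error naming it", {
  v <- rbind(m1 = c(1, 2, NA), m2 = c(3, 4, NA))
  mat <- structure(list(values = `colnames<-`(v, c("a", "b", "lonely")),
                        metric_labels = rownames(v),
                        run_labels = colnames(v), group_labels = NULL),
                   class = "mzqc_metric_matrix")
  expect_error(cluster_metric_matrix(mat), "lonely")
})

test_that("the rendered report round-trips its TSV in clustered order", {
  exp <- small_experiment()
  docs <- experiment_to_documents(exp, creation_date = "2024-06-26T10:00:00")
  merged <- merge_mzqc(docs, creation_date = "2024-06-26T12:00:00")
  ranked <- percentile_rank_matrix(
    build_metric_matrix(merged, group_labels = exp$conditions))
  orders <- cluster_metric_matrix(ranked)
  prefix <- file.path(withr::local_tempdir(), "report")
  paths <- render_qc_report(ranked, orders, out_prefix = prefix)
  expect_true(file.exists(paths["image"]))
  expect_gt(file.info(paths["image"])$size, 0)
  tsv <- readr::read_tsv(paths["table"], show_col_types = FALSE)
  expect_identical(tsv$metric, orders$metric_order)
  expect_identical(colnames(tsv)[-1], orders$run_order)
  got <- as.matrix(tsv[, -1])
  rownames(got) <- tsv$metric
  expect_equal(got, ranked$values[orders$metric_order, orders$run_order],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(render_qc_report(ranked, orders,
                                out_prefix = "/no/such/dir/report"),
               class = "mzqc_io_error")
})

test_that("the grayscale mapping is monotone: low ranks darker", {
  shades <- grDevices::gray.colors(101, start = 0.05, end = 0.97, gamma = 1)
  lum <- colSums(grDevices::col2rgb(shades))
  expect_true(all(diff(lum) >= 0))
  expect_lt(lum[1], lum[101])
})

test_that("autoplot returns a tile heatmap of the long matrix", {
  exp <- small_experiment()
  docs <- experiment_to_documents(exp, creation_date = "2024-06-26T10:00:00")
  merged <- merge_mzqc(docs, creation_date = "2024-06-26T12:00:00")
  ranked <- percentile_rank_matrix(
    build_metric_matrix(merged, group_labels = exp$conditions))
  p <- ggplot2::autoplot(ranked, orders = cluster_metric_matrix(ranked))
  expect_s3_class(p, "ggplot")
  long <- tidy(ranked)
  expect_identical(nrow(long), length(ranked$values))
  expect_true("condition" %in% names(long))
})
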