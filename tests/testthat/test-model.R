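# Document model: construction invariants, value classification, metric
# addition.

test_that("a minimal valid document constructs and re-validates idempotently", {
  doc <- minimal_doc()
  expect_s3_class(doc, "mzqc_document")
  expect_identical(doc$version, "1.0.0")
  expect_invisible(validate_mzqc_model(doc))
  expect_invisible(validate_mzqc_model(doc)) # idempotent
})

test_that("document-level invariants are enforced with named errors", {
  cvs <- list(mzqc_cv_reference("CV", "file:///cv.obo"))
  expect_error(
    mzqc_document(controlledVocabularies = cvs, runQualities = list(),
                  setQualities = list()),
    "no quality elements")
  rq <- minimal_doc()$runQualities
  expect_error(
    mzqc_document(controlledVocabularies = cvs, runQualities = rq,
                  version = "1.0"),
    "malformed version")
  expect_error(
    mzqc_document(controlledVocabularies = cvs, runQualities = rq,
                  version = "2.0.0"),
    "unsupported format version")
  expect_error(
    mzqc_document(controlledVocabularies = list(), runQualities = rq),
    "controlledVocabularies")
  expect_error(
    mzqc_document(controlledVocabularies = cvs, runQualities = rq,
                  creationDate = "yesterday"),
    "ISO-8601")
})

test_that("classify_metric_value maps atoms, lists and mappings to kinds", {
  expect_identical(classify_metric_value(42), "scalar")
  expect_identical(classify_metric_value("text"), "scalar")
  expect_identical(classify_metric_value(TRUE), "scalar")
  expect_identical(classify_metric_value(c(1, 2, 3)), "tuple")
  expect_identical(classify_metric_value(list(1, "a")), "tuple")
  expect_identical(classify_metric_value(list(RT = c(1, 2), TIC = c(10, 20))),
                   "table")
  expect_identical(classify_metric_value(tibble::tibble(a = 1:3)), "table")
  expect_error(classify_metric_value(list(RT = c(1, 2), TIC = 10)),
               "ragged table")
  expect_error(classify_metric_value(NULL), "null")
})

test_that("accession, uniqueness and set-cardinality invariants hold", {
  expect_error(mzqc_metric("bad accession", "x", 1), "malformed")
  expect_error(mzqc_metric("qcx:123", "x", 1), "malformed")
  expect_silent(mzqc_metric("QCX2:123", "x", 1))
  md <- minimal_doc()$runQualities[[1]]$metadata
  m <- mzqc_metric("QCX:0000001", "chromatogram count", 1)
  expect_error(mzqc_run_quality(md, list(m, m)), "duplicate metric accession")
  expect_error(mzqc_set_quality(md, list(m)), "at least two input files")
  f <- mzqc_input_file("a", "file:///a")
  expect_error(
    mzqc_metadata(inputFiles = list(f, f),
                  analysisSoftware = md$analysisSoftware),
    "duplicate input file")
})

test_that("add_metric appends, preserves uniqueness, and counts", {
  el <- minimal_doc()$runQualities[[1]]
  n0 <- n_metrics(el)
  m <- mzqc_metric("QCX:0000001", "chromatogram count", 3)
  el2 <- add_metric(el, m)
  expect_identical(n_metrics(el2), n0 + 1L)
  expect_error(add_metric(el2, m), "duplicate metric")
})

test_that("every seeded random document passes its own invariants", {
  for (seed in 1:15) {
    doc <- random_valid_document(seed)
    expect_invisible(validate_mzqc_model(doc))
  }
})

test_that("tidy and glance summarise a document", {
  doc <- minimal_doc()
  g <- glance(doc)
  expect_identical(g$n_run_qualities, 1L)
  expect_identical(g$n_metrics, 1L)
  td <- tidy(doc)
  expect_identical(nrow(td), 1L)
  expect_identical(td$accession, "QCX:0000020")
  expect_identical(td$scalar, 10)
})
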