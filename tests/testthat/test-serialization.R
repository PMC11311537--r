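# JSON (de)serialization: round trips, representation rules, tolerant
# reading of unknown members.

test_that("a minimal document round-trips through JSON", {
  doc <- minimal_doc()
  txt <- write_mzqc(doc)
  expect_true(mzqc_equal(read_mzqc(txt), doc))
})

test_that("reader rejects non-JSON and missing root with typed errors", {
  expect_error(read_mzqc("{ not json"), class = "mzqc_parse_error")
  expect_error(read_mzqc('{"notMzQC": {}}'), class = "mzqc_format_error")
  expect_error(read_mzqc('{"notMzQC": {}}'), "missing mzQC root")
})

test_that("strict reading reports the path of an invariant violation", {
  doc <- minimal_doc()
  bad <- sub('"QCX:0000020"', '"bad acc"', write_mzqc(doc), fixed = TRUE)
  err <- tryCatch(read_mzqc(bad), error = function(e) conditionMessage(e))
  expect_match(err, "mzQC/runQualities/0")
  # lenient parsing accepts the same text
  expect_s3_class(read_mzqc(bad, strict = FALSE), "mzqc_document")
})

test_that("file reading equals string reading and fails cleanly on bad paths", {
  doc <- minimal_doc()
  path <- withr::local_tempfile(fileext = ".mzqc")
  write_mzqc_file(doc, path)
  expect_true(mzqc_equal(read_mzqc_file(path), doc))
  expect_error(read_mzqc_file(file.path(tempdir(), "nope.mzqc")),
               class = "mzqc_io_error")
  expect_error(read_mzqc_file(tempdir()), class = "mzqc_io_error")
})

test_that("representation rules: tables as column arrays, optionals omitted", {
  doc <- minimal_doc(list(mzqc_metric(
    "QCX:0000004", "total ion chromatogram",
    tibble::tibble(rt = c(1, 2), intensity = c(10, 20)))))
  txt <- write_mzqc(doc, pretty = FALSE)
  raw <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  val <- raw$mzQC$runQualities[[1]]$qualityMetrics[[1]]$value
  expect_named(val, c("rt", "intensity"))
  expect_length(val$rt, 2L)
  expect_false(grepl('"description"', txt, fixed = TRUE))
  expect_false(grepl("null", txt, fixed = TRUE))
})

test_that("a one-element tuple survives the round trip as a tuple", {
  doc <- minimal_doc(list(mzqc_metric(
    "QCX:0000027", "identified retention time range",
    mzqc_value(list(42.5), kind = "tuple"))))
  back <- read_mzqc(write_mzqc(doc))
  expect_identical(back$runQualities[[1]]$qualityMetrics[[1]]$value$kind, "tuple")
  expect_true(mzqc_equal(back, doc))
})

test_that("numbers keep full double precision across the round trip", {
  vals <- c(1 / 3, pi, 2 + 1e-9, 123456.789012345)
  doc <- minimal_doc(list(mzqc_metric("QCX:0000025",
                                      "precursor mass error summary", vals)))
  back <- read_mzqc(write_mzqc(doc))
  got <- unlist(as.list(back$runQualities[[1]]$qualityMetrics[[1]]$value$data))
  expect_identical(got, vals)
})

test_that("unknown members are preserved on read and re-emitted on write", {
  doc <- minimal_doc()
  raw <- jsonlite::fromJSON(write_mzqc(doc), simplifyVector = FALSE)
  raw$mzQC$`x-extension` <- list(origin = "future-format-release")
  raw$mzQC$runQualities[[1]]$qualityMetrics[[1]]$`x-flag` <- TRUE
  txt <- as.character(jsonlite::toJSON(raw, auto_unbox = TRUE))
  back <- read_mzqc(txt)
  expect_identical(back$extras$`x-extension`$origin, "future-format-release")
  re <- jsonlite::fromJSON(write_mzqc(back), simplifyVector = FALSE)
  expect_identical(re$mzQC$`x-extension`$origin, "future-format-release")
  expect_true(isTRUE(re$mzQC$runQualities[[1]]$qualityMetrics[[1]]$`x-flag`))
})

test_that("seeded random documents round-trip structurally", {
  for (seed in 101:130) {
    doc <- random_valid_document(seed)
    expect_true(mzqc_equal(read_mzqc(write_mzqc(doc)), doc),
                label = sprintf("round trip of seed %d", seed))
  }
})

test_that("serializer refuses an invariant-violating document", {
  doc <- minimal_doc()
  doc$version <- "0.9.0"
  expect_error(write_mzqc(doc), class = "mzqc_version_error")
})
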