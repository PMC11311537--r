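# Semantic validation against the toy CV.

ERROR_RULES <- c("unknown-accession", "value-type-mismatch", "duplicate-metric",
                 "duplicate-input-file")
WARNING_RULES <- c("name-mismatch", "obsolete-term", "unlisted-cv-prefix")

test_that("a document using correct CV terms has zero findings", {
  store <- cv_store_cached()
  for (seed in c(1, 2, 3)) {
    rep <- validate_mzqc_semantics(random_valid_document(seed), store)
    expect_identical(nrow(rep$findings), 0L)
    expect_true(rep$valid)
  }
})

test_that("each seeded semantic violation yields exactly its rule id", {
  store <- cv_store_cached()
  ids <- fixture_case_ids()
  sem_ids <- ids$case_id[ids$stage == "semantic"]
  expect_gte(length(sem_ids), 7L)
  for (cid in sem_ids) {
    case <- generate_mzqc_fixture(cid)
    doc <- read_mzqc(case$text, strict = FALSE)
    rep <- validate_mzqc_semantics(doc, store)
    expect_identical(unique(rep$findings$ruleId), case$expected_rule,
                     label = cid)
    if (case$expected_rule %in% WARNING_RULES) {
      expect_true(rep$valid, label = paste(cid, "warning keeps verdict valid"))
      expect_identical(unique(rep$findings$severity), "warning", label = cid)
    } else {
      expect_false(rep$valid, label = cid)
      expect_identical(unique(rep$findings$severity), "error", label = cid)
    }
  }
})

test_that("findings carry the metric's document path", {
  store <- cv_store_cached()
  case <- generate_mzqc_fixture("sem-unknown-accession")
  rep <- validate_mzqc_semantics(read_mzqc(case$text, strict = FALSE), store)
  expect_match(rep$findings$path, "^mzQC/runQualities/0/qualityMetrics/0")
})

test_that("name mismatches report the expected CV name", {
  store <- cv_store_cached()
  case <- generate_mzqc_fixture("sem-name-mismatch")
  rep <- validate_mzqc_semantics(read_mzqc(case$text, strict = FALSE), store)
  expect_match(rep$findings$message, "MS/MS spectrum count")
})

test_that("a missing required table column is a value-type mismatch", {
  store <- cv_store_cached()
  doc <- minimal_doc(list(mzqc_metric(
    "QCX:0000004", "total ion chromatogram",
    tibble::tibble(rt = c(1, 2), wrong = c(3, 4)))))
  rep <- validate_mzqc_semantics(doc, store)
  expect_identical(rep$findings$ruleId, "value-type-mismatch")
  expect_match(rep$findings$message, "intensity")
})

test_that("a boolean where the CV declares a number is an error", {
  store <- cv_store_cached()
  doc <- minimal_doc(list(mzqc_metric("QCX:0000020", "MS/MS spectrum count",
                                      TRUE)))
  rep <- validate_mzqc_semantics(doc, store)
  expect_identical(rep$findings$ruleId, "value-type-mismatch")
})

test_that("semantic verdicts are stable across a write/read cycle", {
  store <- cv_store_cached()
  for (cid in c("sem-value-type-mismatch", "sem-name-mismatch", "valid-01")) {
    doc <- read_mzqc(generate_mzqc_fixture(cid)$text, strict = FALSE)
    rep1 <- validate_mzqc_semantics(doc, store)
    doc2 <- read_mzqc(write_mzqc(doc), strict = FALSE)
    rep2 <- validate_mzqc_semantics(doc2, store)
    expect_identical(rep1$findings, rep2$findings, label = cid)
  }
})
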