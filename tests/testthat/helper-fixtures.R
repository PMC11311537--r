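# Shared fixture builders. The small experiment is generated once per test
# run and memoised; tests that need other scales build their own spec.

.fixture_cache <- new.env(parent = emptyenv())

small_experiment <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_experiment(
      experiment_spec(ms1_per_run = 30L, ms2_per_ms1 = 5L, seed = 101L))
  }
  .fixture_cache$small
}

cv_store_cached <- function() {
  if (is.null(.fixture_cache$cv)) .fixture_cache$cv <- toy_cv_store()
  .fixture_cache$cv
}

minimal_doc <- function(metrics = NULL) {
  metrics <- metrics %||% list(mzqc_metric("QCX:0000020", "MS/MS spectrum count", 10))
  md <- mzqc_metadata(
    inputFiles = list(mzqc_input_file("run1", "file:///data/run1.mzML")),
    analysisSoftware = list(mzqc_analysis_software("QCX:1000001", "mzqckit", "0.1.0")))
  mzqc_document(
    controlledVocabularies = list(
      mzqc_cv_reference("Toy Quality Control Vocabulary (QCX)", "file:///qcx.obo")),
    runQualities = list(mzqc_run_quality(md, metrics)),
    creationDate = "2024-06-26T12:00:00")
}
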