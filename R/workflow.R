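# Convenience orchestration of the demonstration workflow: three partial
# per-run reports (basic acquisition metrics / injection-time statistics /
# identification metrics), as if produced by three independent tools, ready
# to be merged into one document.

#' Partial mzQC documents for a synthetic experiment
#'
#' Computes the requested metric stages for every run of a generated
#' experiment and packages each stage as its own mzQC document with one
#' runQuality per run — emulating a pipeline where different tools
#' contribute different metric groups that are merged afterwards.
#'
#' @param exp Result of [generate_experiment()].
#' @param stages Subset of `c("basic", "injection", "id")`.
#' @param q_threshold q-value threshold for the identification stage.
#' @param creation_date Timestamp stamped on the partial documents.
#' @return Named list of `mzqc_document`, one per stage.
#' @export
experiment_to_documents <- function(exp, stages = c("basic", "injection", "id"),
                                    q_threshold = 0.01,
                                    creation_date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  stages <- match.arg(stages, several.ok = TRUE)
  metric_fun <- list(
    basic = function(nm) run_basic_metrics(exp$runs[[nm]]),
    injection = function(nm) injection_time_stats(exp$runs[[nm]]),
    id = function(nm) identification_metrics(exp$runs[[nm]], exp$psms[[nm]],
                                             q_threshold = q_threshold))
  docs <- lapply(stages, function(stage) {
    els <- lapply(names(exp$runs), function(nm)
      run_quality_from_metrics(exp$runs[[nm]], metric_fun[[stage]](nm)))
    mzqc_document(controlledVocabularies = default_cv_references(),
                  runQualities = els, creationDate = creation_date,
                  description = sprintf("partial QC report: %s metrics", stage))
  })
  stats::setNames(docs, stages)
}
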