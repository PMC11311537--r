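# mzqckit

Quality control (QC) is how mass-spectrometry labs detect drifting
instruments, failed gradients, and outlier runs before those problems
contaminate downstream biology. The HUPO-PSI **mzQC** format is the
community's JSON exchange format for QC metrics: each report groups metrics
into `runQuality` (one MS run) or `setQuality` (several runs) elements,
anchors every metric to a controlled-vocabulary (CV) term, and stores values
as scalars, tuples, or tables.

`mzqckit` is an R toolkit for that format, aimed at proteomics and
metabolomics bioinformaticians who need to produce, check, combine, and
visualise QC reports:

* **Document model** — typed constructors with construction-time invariant
  checks (version pinned to `1.0.0`, accession pattern
  `^[A-Z]+[A-Z0-9]*:[0-9]+$`, unique metric accessions per element, ≥2 input
  files for set-level elements, …).
* **Serialization** — faithful JSON reading/writing: tables become tibbles,
  numbers keep full double precision, unknown members are preserved, absent
  optionals are omitted; `read(write(doc))` is structurally identical to
  `doc`.
* **Syntactic validation** — structured findings (`ruleId`, `severity`,
  `path`, `message`) instead of exceptions; all problems collected.
* **Semantic validation** — against a CV parsed from OBO: term existence,
  name agreement, declared value types (including required table columns),
  obsolete terms, uniqueness rules, unlisted CV prefixes.
* **QC metrics** — chromatogram count, m/z and RT acquisition ranges, total
  ion chromatogram, base peak chromatogram, ion injection-time statistics
  per MS level, and identification metrics from PSM tables filtered at a
  q-value threshold (default 0.01): spectrum/peptide/protein counts,
  precursor mass-error distribution, missed-cleavage histogram, identified
  RT range.
* **Merge + report** — coalesce partial per-run reports into one document,
  percentile-rank each metric across runs, cluster both axes
  (average-linkage, Euclidean), and render a heatmap plus a TSV export.
* **Synthetic fixtures** — a seeded generator of a two-condition, 8-run DDA
  experiment with exact ground truth, plus a catalog of labeled
  valid/invalid mzQC documents, so everything is testable offline.

## The core quantities

For a peptide with monoisotopic mass *M* observed at charge *z*, the
theoretical m/z is *(M + z·m_p)/z* (proton mass *m_p* = 1.00727646688 Da)
and the signed precursor mass error in parts per million is

```
ppm = 1e6 · (mz_observed − mz_theoretical) / mz_theoretical
```

Missed cleavages follow the trypsin rule: an internal residue K or R counts
as a missed site unless followed by P. Percentile ranks use the mean-rank
convention across the *n* runs carrying a metric:

```
rank(x) = 100 · (#{values < x} + 0.5 · #{values = x}) / n
```

so ties share their mean rank, an all-ties vector maps to 50 everywhere,
and ranks lie strictly inside (0, 100).

## Worked example

```r
library(mzqckit)

exp <- generate_experiment(experiment_spec(ms1_per_run = 50L,
                                           ms2_per_ms1 = 5L, seed = 7L))
run <- exp$runs[["Ecoli_DMSO_rep1"]]
run
#> <MS run 'Ecoli_DMSO_rep1': 50 MS1 + 250 MS2 spectra, 1 chromatogram(s)>

metrics <- c(run_basic_metrics(run), injection_time_stats(run),
             identification_metrics(run, exp$psms[["Ecoli_DMSO_rep1"]]))
doc <- mzqc_document(
  controlledVocabularies = list(mzqc_cv_reference(
    "Toy Quality Control Vocabulary (QCX)", "file:///qcx_toy_cv.obo")),
  runQualities = list(run_quality_from_metrics(run, metrics)))
glance(doc)
#> # A tibble: 1 × 6
#>   version creationDate        n_cvs n_run_qualities n_set_qualities n_metrics
#> 1 1.0.0   2026-09-21T15:11:36     1               1               0        15
```

`tidy(doc)` gives one row per metric (accession, name, value kind, scalar
value where applicable). The three-stage workflow — basic metrics,
injection statistics, and identification metrics written as three partial
documents and then combined — looks like:

```r
docs   <- experiment_to_documents(exp)      # 3 partial mzQC documents
merged <- merge_mzqc(docs)                  # 8 runQualities, metric union
ranked <- percentile_rank_matrix(
  build_metric_matrix(merged, group_labels = exp$conditions))
round(ranked$values[1:4, 1:4], 1)
#>                          Ecoli_DMSO_rep1 Ecoli_DMSO_rep2 Ecoli_DMSO_rep3 Ecoli_DMSO_rep4
#> MS/MS spectrum count                50.0            50.0            50.0            50.0
#> identified MS/MS spectra            50.0            50.0            50.0            50.0
#> identified peptides                 87.5            87.5            62.5            43.8
#> identified proteins                 43.8            68.8            31.2            68.8

orders <- cluster_metric_matrix(ranked)
render_qc_report(ranked, orders, out_prefix = "qc_report")
# writes qc_report.png (clustered heatmap, condition strip, darker = lower
# rank) and qc_report.tsv (ranked matrix in clustered order)
```

Validation, from text or file, with optional CV-aware semantics:

```r
validate_mzqc_syntax('{"notMzQC": {}}')
#> <mzQC validation report: INVALID, 1 finding(s)>  (ruleId "missing-root")
store <- toy_cv_store()                      # or read_obo("psi-ms.obo")
validate_mzqc_semantics(doc, store)
```

A command-line wrapper with `validate`, `extract`, `merge`, `report` and
`fixtures` subcommands is installed at `inst/cli/mzqctool.R`
(`Rscript mzqctool.R validate file.mzqc --json`).

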