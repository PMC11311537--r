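# Toy controlled vocabulary and the labeled fixture catalog: seeded valid
# documents plus invalid documents that each violate exactly one syntactic or
# semantic rule, with the expected rule id attached. These drive the
# validator tests and the validator-vs-schema-oracle comparison.

#' OBO text of the toy QC controlled vocabulary
#'
#' Generated from [qc_metric_catalog()] (so the CV can never drift from the
#' metrics the package emits) plus unit terms, a software term, an mzML
#' file-format term, one deliberately obsolete term, and one term under a
#' second prefix (`ZZ`) used to exercise the unlisted-CV-prefix check. Value
#' types are declared via `xref: value-type:...` lines and table columns via
#' repeatable `xref: required-column:...` lines.
#'
#' @return A single string of OBO 1.2 stanzas.
#' @export
toy_cv_obo <- function() {
  catalog <- qc_metric_catalog()
  header <- c("format-version: 1.2", "data-version: 0.1", "ontology: qcx", "")
  root <- c("[Term]", "id: QCX:0000000", "name: QC metric",
            'def: "A quality-control metric." []', "")
  stanzas <- unlist(lapply(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    cols <- if (nzchar(row$columns)) strsplit(row$columns, ",")[[1]] else character()
    c("[Term]",
      paste0("id: ", row$accession),
      paste0("name: ", row$name),
      sprintf('def: "QC metric: %s." []', row$name),
      "is_a: QCX:0000000 ! QC metric",
      paste0("xref: value-type:", row$value_type),
      if (length(cols)) paste0("xref: required-column:", cols),
      "")
  }))
  units <- qc_unit_catalog()
  unit_stanzas <- unlist(lapply(seq_len(nrow(units)), function(i) {
    c("[Term]", paste0("id: ", units$accession[i]),
      paste0("name: ", units$name[i]), "")
  }))
  misc <- c(
    "[Term]", "id: QCX:1000001", "name: mzqckit",
    'def: "The mzqckit software." []', "",
    "[Term]", "id: QCX:1000002", "name: mzML format",
    'def: "Standard raw spectra file format." []', "",
    "[Term]", "id: QCX:0000099", "name: legacy metric",
    'def: "A retired QC metric." []', "is_a: QCX:0000000", "is_obsolete: true", "",
    "[Term]", "id: ZZ:0000001", "name: external example metric",
    'def: "A metric defined by an external vocabulary." []', "",
    "[Typedef]", "id: part_of", "name: part of", "")
  paste(c(header, root, stanzas, unit_stanzas, misc), collapse = "\n")
}

#' The toy CV as a loaded store
#'
#' @return An `mzqc_cv_store` of [toy_cv_obo()].
#' @export
toy_cv_store <- function() load_obo(toy_cv_obo())

random_value_for <- function(row) {
  if (row$value_type == "scalar-number") return(sample(0:5000, 1L))
  if (row$value_type == "tuple") {
    n <- sample(2:4, 1L)
    return(sort(round(stats::runif(n, 0, 1000), 3)))
  }
  cols <- strsplit(row$columns, ",")[[1]]
  n <- sample(3:10, 1L)
  tbl <- lapply(cols, function(cn) {
    if (cn == "missed_cleavages") 0:(n - 1L) else round(stats::runif(n, 0, 1e6), 3)
  })
  names(tbl) <- cols
  tibble::as_tibble(tbl)
}

random_quality_element <- function(kind, idx) {
  catalog <- qc_metric_catalog()
  n_m <- sample(3:8, 1L)
  rows <- sort(sample(nrow(catalog), n_m))
  metrics <- lapply(rows, function(i) qc_metric(catalog$accession[i],
                                                random_value_for(catalog[i, ])))
  n_files <- if (kind == "set") sample(2:3, 1L) else 1L
  files <- lapply(seq_len(n_files), function(f)
    mzqc_input_file(sprintf("run_%d_%d", idx, f),
                    sprintf("file:///data/run_%d_%d.mzML", idx, f),
                    fileFormat = if (stats::runif(1) < 0.5)
                      mzqc_cv_param("QCX:1000002", "mzML format") else NULL))
  md <- mzqc_metadata(
    inputFiles = files, analysisSoftware = list(default_software()),
    label = if (stats::runif(1) < 0.3) sprintf("batch %d", idx) else NULL)
  el <- new_quality_element(md, metrics, kind,
                            extras = if (stats::runif(1) < 0.2)
                              list(`x-note` = "extension data") else list())
  el
}

#' A seeded random valid mzQC document
#'
#' Structure (number of elements, metric subsets, value shapes, optional
#' fields, extension members) varies with the seed; every draw is both
#' syntactically valid and semantically clean against the toy CV.
#'
#' @param seed Integer seed.
#' @return An `mzqc_document`.
#' @export
random_valid_document <- function(seed) {
  with_seed_local(seed, {
    n_runs <- sample(1:3, 1L)
    rq <- lapply(seq_len(n_runs), function(i) random_quality_element("run", i))
    sq <- if (stats::runif(1) < 0.3)
      list(random_quality_element("set", 99L)) else list()
    cvs <- default_cv_references()
    if (stats::runif(1) < 0.3) {
      cvs <- c(cvs, list(mzqc_cv_reference("External Example Vocabulary (ZZ)",
                                           "file:///zz.obo")))
    }
    mzqc_document(
      controlledVocabularies = cvs, runQualities = rq, setQualities = sq,
      creationDate = sprintf("2024-06-26T%02d:%02d:%02d",
                             sample(0:23, 1L), sample(0:59, 1L), sample(0:59, 1L)),
      description = if (stats::runif(1) < 0.4) "synthetic QC fixture" else NULL,
      contactName = if (stats::runif(1) < 0.3) "QC Robot" else NULL,
      extras = if (stats::runif(1) < 0.2) list(`x-pipeline` = "fixture") else list())
  })
}

minimal_fixture_doc <- function() {
  md <- mzqc_metadata(
    inputFiles = list(mzqc_input_file("run_A", "file:///data/run_A.mzML")),
    analysisSoftware = list(default_software()))
  metrics <- list(
    qc_metric("QCX:0000020", 1234),
    qc_metric("QCX:0000004", tibble::tibble(rt = c(1, 2, 3),
                                            intensity = c(10, 20, 30))))
  mzqc_document(controlledVocabularies = default_cv_references(),
                runQualities = list(mzqc_run_quality(md, metrics)),
                creationDate = "2024-06-26T12:00:00")
}

mutate_json <- function(doc, fun) {
  parsed <- jsonlite::fromJSON(write_mzqc(doc), simplifyVector = FALSE)
  parsed$mzQC <- fun(parsed$mzQC)
  as.character(jsonlite::toJSON(parsed, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE))
}

fixture_case <- function(text, stage, rule = NA_character_) {
  list(text = text, stage = stage, expected_rule = rule)
}

syntactic_cases <- function() {
  base <- minimal_fixture_doc()
  list(
    `not-json` = fixture_case("{ \"mzQC\": ", "syntax", "not-json"),
    `missing-root` = fixture_case('{"notMzQC": {}}', "syntax", "missing-root"),
    `missing-version` = fixture_case(
      mutate_json(base, function(b) { b$version <- NULL; b }),
      "syntax", "required-missing"),
    `bad-version` = fixture_case(
      mutate_json(base, function(b) { b$version <- "1.0"; b }),
      "syntax", "invalid-version"),
    `no-quality-elements` = fixture_case(
      mutate_json(base, function(b) { b$runQualities <- NULL; b }),
      "syntax", "no-quality-elements"),
    `ragged-table` = fixture_case(
      mutate_json(base, function(b) {
        b$runQualities[[1]]$qualityMetrics[[2]]$value$intensity <- list(10, 20)
        b
      }), "syntax", "ragged-table"),
    `duplicate-metric` = fixture_case(
      mutate_json(base, function(b) {
        b$runQualities[[1]]$qualityMetrics <-
          c(b$runQualities[[1]]$qualityMetrics,
            b$runQualities[[1]]$qualityMetrics[1])
        b
      }), "syntax", "duplicate-metric"),
    `bad-accession` = fixture_case(
      mutate_json(base, function(b) {
        b$runQualities[[1]]$qualityMetrics[[1]]$accession <- "qcx:0000020"
        b
      }), "syntax", "invalid-accession")
  )
}

semantic_cases <- function() {
  base <- minimal_fixture_doc()
  list(
    `sem-unknown-accession` = fixture_case(
      mutate_json(base, function(b) {
        b$runQualities[[1]]$qualityMetrics[[1]]$accession <- "QCX:0009999"
        b$runQualities[[1]]$qualityMetrics[[1]]$name <- "mystery metric"
        b
      }), "semantic", "unknown-accession"),
    `sem-name-mismatch` = fixture_case(
      mutate_json(base, function(b) {
        b$runQualities[[1]]$qualityMetrics[[1]]$name <- "number of spectra"
        b
      }), "semantic", "name-mismatch"),
    `sem-value-type-mismatch` = fixture_case(
      mutate_json(base, function(b) {
        b$runQualities[[1]]$qualityMetrics[[2]]$value <- 5
        b
      }), "semantic", "value-type-mismatch"),
    `sem-obsolete-term` = fixture_case(
      mutate_json(base, function(b) {
        b$runQualities[[1]]$qualityMetrics[[1]]$accession <- "QCX:0000099"
        b$runQualities[[1]]$qualityMetrics[[1]]$name <- "legacy metric"
        b
      }), "semantic", "obsolete-term"),
    `sem-duplicate-metric` = fixture_case(
      mutate_json(base, function(b) {
        b$runQualities[[1]]$qualityMetrics <-
          c(b$runQualities[[1]]$qualityMetrics,
            b$runQualities[[1]]$qualityMetrics[1])
        b
      }), "semantic", "duplicate-metric"),
    `sem-duplicate-input-file` = fixture_case(
      mutate_json(base, function(b) {
        f <- b$runQualities[[1]]$metadata$inputFiles[[1]]
        f$location <- "file:///data/other.mzML"
        b$runQualities[[1]]$metadata$inputFiles <-
          c(b$runQualities[[1]]$metadata$inputFiles, list(f))
        b
      }), "semantic", "duplicate-input-file"),
    `sem-unlisted-cv-prefix` = fixture_case(
      mutate_json(base, function(b) {
        b$runQualities[[1]]$qualityMetrics[[1]]$accession <- "ZZ:0000001"
        b$runQualities[[1]]$qualityMetrics[[1]]$name <- "external example metric"
        b
      }), "semantic", "unlisted-cv-prefix")
  )
}

fixture_catalog <- function() {
  valid <- stats::setNames(
    lapply(1:20, function(i)
      fixture_case(write_mzqc(random_valid_document(1000L + i)), "valid")),
    sprintf("valid-%02d", 1:20))
  c(valid, syntactic_cases(), semantic_cases())
}

#' Case ids of the labeled mzQC fixture catalog
#'
#' @return Tibble with `case_id`, `stage` (`"valid"`, `"syntax"`,
#'   `"semantic"`), and `expected_rule` (`NA` for valid cases).
#' @export
fixture_case_ids <- function() {
  cases <- fixture_catalog()
  tibble::tibble(
    case_id = names(cases),
    stage = unname(vapply(cases, function(x) x$stage, character(1))),
    expected_rule = unname(vapply(cases, function(x) x$expected_rule,
                                  character(1))))
}

#' Generate one labeled mzQC fixture
#'
#' Each invalid case violates exactly one validation rule; the expectation
#' names that rule id and the validation stage it belongs to.
#'
#' @param case_id One of [fixture_case_ids()]`$case_id`.
#' @return List with `text` (the mzQC JSON, possibly deliberately broken),
#'   `stage`, and `expected_rule`.
#' @export
generate_mzqc_fixture <- function(case_id) {
  cases <- fixture_catalog()
  if (!case_id %in% names(cases)) {
    mzqc_abort(sprintf("unknown fixture case id '%s'", case_id))
  }
  cases[[case_id]]
}

#' Write the complete fixture corpus to a directory
#'
#' Emits a synthetic experiment (runs as JSON, PSM tables as TSV), the toy
#' CV as OBO, and the full labeled mzQC fixture catalog, so that every
#' module — and the command-line pipeline — can operate on files without any
#' download.
#'
#' @param dir Output directory (created if needed).
#' @param spec An [experiment_spec()]; its seed governs the experiment.
#' @return Invisible list with the written paths (`runs`, `psms`, `cv`,
#'   `mzqc` named by case id).
#' @export
write_fixture_corpus <- function(dir, spec = experiment_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "runs"), showWarnings = FALSE)
  dir.create(file.path(dir, "psms"), showWarnings = FALSE)
  dir.create(file.path(dir, "mzqc"), showWarnings = FALSE)
  exp <- generate_experiment(spec)
  run_paths <- vapply(names(exp$runs), function(nm) {
    write_run_json(exp$runs[[nm]], file.path(dir, "runs", paste0(nm, ".json")))
  }, character(1))
  psm_paths <- vapply(names(exp$psms), function(nm) {
    write_psm_tsv(exp$psms[[nm]], file.path(dir, "psms", paste0(nm, ".tsv")))
  }, character(1))
  cv_path <- file.path(dir, "qcx_toy_cv.obo")
  writeLines(toy_cv_obo(), cv_path, useBytes = TRUE)
  cases <- fixture_catalog()
  mzqc_paths <- vapply(names(cases), function(nm) {
    p <- file.path(dir, "mzqc", paste0(nm, ".mzqc"))
    writeLines(cases[[nm]]$text, p, useBytes = TRUE)
    p
  }, character(1))
  cond_path <- file.path(dir, "conditions.tsv")
  readr::write_tsv(tibble::tibble(run = names(exp$conditions),
                                  condition = unname(exp$conditions)),
                   cond_path, progress = FALSE)
  invisible(list(runs = run_paths, psms = psm_paths, cv = cv_path,
                 mzqc = mzqc_paths, conditions = cond_path))
}
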