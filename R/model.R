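# Typed in-memory representation of the mzQC format.
#
# Every constructor checks its invariants at construction time and fails with
# an error naming the violated invariant, so that an object that exists is an
# object that is well formed. Field names mirror the JSON member names of the
# format (camelCase) to keep serialization transparent.

MZQC_SUPPORTED_VERSION <- "1.0.0"
MZQC_VERSION_PATTERN <- "^[0-9]+\\.[0-9]+\\.[0-9]+$"
MZQC_ACCESSION_PATTERN <- "^[A-Z]+[A-Z0-9]*:[0-9]+$"
# ISO-8601 date + time at seconds precision; fractional seconds and an
# optional timezone designator are accepted and kept verbatim.
MZQC_TIMESTAMP_PATTERN <-
  "^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}(\\.[0-9]+)?(Z|[+-][0-9]{2}:?[0-9]{2})?$"

mzqc_abort <- function(message, class = "mzqc_model_error", ...) {
  rlang::abort(message, class = c(class, "mzqc_error"), ...)
}

chk_nonempty_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(trimws(x))) {
    mzqc_abort(sprintf("%s must be a non-empty string", what))
  }
  invisible(x)
}

chk_accession <- function(x, what = "accession") {
  chk_nonempty_string(x, what)
  if (!grepl(MZQC_ACCESSION_PATTERN, x)) {
    mzqc_abort(sprintf("malformed %s '%s': must match PREFIX:digits", what, x),
               class = "mzqc_accession_error")
  }
  invisible(x)
}

accession_prefix <- function(x) sub(":.*$", "", x)

#' Classify a raw value into the format's metric value kinds
#'
#' The format stores metric values as single values, tuples, or tabular data.
#' A named collection of equal-length columns is a `"table"`, an unnamed
#' vector or list is a `"tuple"`, and a single atomic value is a `"scalar"`.
#'
#' @param x A value: atomic scalar, atomic vector, unnamed list, named list of
#'   equal-length columns, or data frame.
#' @return One of `"scalar"`, `"tuple"`, `"table"`.
#' @examples
#' classify_metric_value(42)
#' classify_metric_value(c(1, 2, 3))
#' classify_metric_value(list(RT = c(1, 2), TIC = c(10, 20)))
#' @export
classify_metric_value <- function(x) {
  if (is.null(x)) mzqc_abort("metric value must not be null")
  if (is.data.frame(x)) {
    if (nrow(x) < 1L || ncol(x) < 1L) mzqc_abort("table must have at least one row and column")
    return("table")
  }
  if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    lens <- vapply(x, length, integer(1))
    if (length(lens) == 0L) mzqc_abort("table must have at least one column")
    if (any(lens < 1L) || length(unique(lens)) != 1L) {
      mzqc_abort("ragged table: columns must all have identical length >= 1",
                 class = "mzqc_ragged_table_error")
    }
    return("table")
  }
  if (is.list(x) || (is.atomic(x) && length(x) != 1L)) {
    if (length(x) < 1L) mzqc_abort("tuple must have length >= 1")
    return("tuple")
  }
  "scalar"
}

#' Construct a metric value of an explicit or inferred kind
#'
#' @param x Raw value (see [classify_metric_value()]).
#' @param kind Optional kind override (`"scalar"`, `"tuple"`, `"table"`);
#'   needed e.g. for a one-element tuple, which would otherwise classify as a
#'   scalar.
#' @return An object of class `mzqc_value` with elements `kind` and `data`
#'   (tables are held as tibbles, tuples as unnamed vectors/lists, scalars as
#'   length-one atomics).
#' @export
mzqc_value <- function(x, kind = NULL) {
  inferred <- classify_metric_value(x)
  kind <- kind %||% inferred
  if (!kind %in% c("scalar", "tuple", "table")) {
    mzqc_abort(sprintf("unknown value kind '%s'", kind))
  }
  if (kind != inferred) {
    ok <- kind == "tuple" && inferred == "scalar" # 1-element tuple
    if (!ok) mzqc_abort(sprintf("value classifies as %s, not %s", inferred, kind))
  }
  data <- switch(kind,
    scalar = x,
    tuple = if (is.list(x)) x else as.vector(x),
    table = tibble::as_tibble(lapply(x, function(col) unlist(col, use.names = FALSE)))
  )
  if (kind == "table" && nrow(data) < 1L) {
    mzqc_abort("table must have at least one row")
  }
  structure(list(kind = kind, data = data), class = "mzqc_value")
}

#' @export
print.mzqc_value <- function(x, ...) {
  cat(sprintf("<mzqc_value: %s>\n", x$kind))
  print(x$data, ...)
  invisible(x)
}

as_mzqc_value <- function(x) {
  if (inherits(x, "mzqc_value")) x else mzqc_value(x)
}

#' Controlled-vocabulary reference of a document
#'
#' @param name CV name (non-empty).
#' @param uri Resource locator of the CV (non-empty).
#' @param version Optional CV version string.
#' @param extras Named list of unknown extra JSON members to preserve.
#' @return An `mzqc_cv_reference` object.
#' @export
mzqc_cv_reference <- function(name, uri, version = NULL, extras = list()) {
  chk_nonempty_string(name, "controlled vocabulary name")
  chk_nonempty_string(uri, "controlled vocabulary uri")
  structure(list(name = name, uri = uri, version = version, extras = extras),
            class = "mzqc_cv_reference")
}

#' CV-anchored parameter (file format, file property, analysis setting)
#'
#' @param accession CV accession matching `PREFIX:digits`.
#' @param name Term name.
#' @param value Optional scalar value.
#' @param extras Named list of preserved unknown members.
#' @return An `mzqc_cv_param` object.
#' @export
mzqc_cv_param <- function(accession, name, value = NULL, extras = list()) {
  chk_accession(accession)
  chk_nonempty_string(name, "cvParameter name")
  structure(list(accession = accession, name = name, value = value, extras = extras),
            class = "mzqc_cv_param")
}

#' Analysis software reference
#'
#' @param accession CV accession of the software term.
#' @param name Software name.
#' @param version Software version string.
#' @param uri Optional resource locator.
#' @param extras Named list of preserved unknown members.
#' @return An `mzqc_analysis_software` object.
#' @export
mzqc_analysis_software <- function(accession, name, version, uri = NULL, extras = list()) {
  chk_accession(accession)
  chk_nonempty_string(name, "software name")
  chk_nonempty_string(version, "software version")
  structure(list(accession = accession, name = name, version = version,
                 uri = uri, extras = extras),
            class = "mzqc_analysis_software")
}

#' Input file of a quality element's metadata
#'
#' @param name File identifier, unique within one metadata block.
#' @param location Resource locator of the file.
#' @param fileFormat Optional [mzqc_cv_param()] describing the format.
#' @param fileProperties Optional list of [mzqc_cv_param()].
#' @param extras Named list of preserved unknown members.
#' @return An `mzqc_input_file` object.
#' @export
mzqc_input_file <- function(name, location, fileFormat = NULL,
                            fileProperties = NULL, extras = list()) {
  chk_nonempty_string(name, "input file name")
  chk_nonempty_string(location, "input file location")
  structure(list(name = name, location = location, fileFormat = fileFormat,
                 fileProperties = fileProperties, extras = extras),
            class = "mzqc_input_file")
}

#' Provenance metadata of a quality element
#'
#' @param inputFiles List of [mzqc_input_file()] (at least one); names must be
#'   unique within the element.
#' @param analysisSoftware List of [mzqc_analysis_software()] (at least one).
#' @param label Optional free-text label.
#' @param cvParameters Optional list of [mzqc_cv_param()].
#' @param extras Named list of preserved unknown members.
#' @return An `mzqc_metadata` object.
#' @export
mzqc_metadata <- function(inputFiles, analysisSoftware, label = NULL,
                          cvParameters = NULL, extras = list()) {
  if (!is.list(inputFiles) || length(inputFiles) < 1L) {
    mzqc_abort("metadata requires at least one input file")
  }
  if (!is.list(analysisSoftware) || length(analysisSoftware) < 1L) {
    mzqc_abort("metadata requires at least one analysisSoftware entry")
  }
  nm <- vapply(inputFiles, function(f) f$name, character(1))
  if (anyDuplicated(nm)) {
    mzqc_abort(sprintf("duplicate input file name '%s'", nm[duplicated(nm)][1]),
               class = "mzqc_duplicate_input_file_error")
  }
  structure(list(inputFiles = inputFiles, analysisSoftware = analysisSoftware,
                 label = label, cvParameters = cvParameters, extras = extras),
            class = "mzqc_metadata")
}

#' One CV-anchored quality metric
#'
#' @param accession CV accession matching `PREFIX:digits`.
#' @param name Metric name as given by the CV term.
#' @param value Metric value (raw value or [mzqc_value()]); null is rejected
#'   because a metric without a value carries no QC information.
#' @param unit Optional [mzqc_cv_param()] (or list thereof) naming the unit.
#' @param description Optional free text.
#' @param extras Named list of preserved unknown members.
#' @return An `mzqc_metric` object.
#' @export
mzqc_metric <- function(accession, name, value, unit = NULL,
                        description = NULL, extras = list()) {
  chk_accession(accession)
  chk_nonempty_string(name, "metric name")
  value <- as_mzqc_value(value)
  structure(list(accession = accession, name = name, description = description,
                 value = value, unit = unit, extras = extras),
            class = "mzqc_metric")
}

new_quality_element <- function(metadata, qualityMetrics, kind, extras = list()) {
  stopifnot(kind %in% c("run", "set"))
  if (!inherits(metadata, "mzqc_metadata")) {
    mzqc_abort("quality element requires metadata")
  }
  if (!is.list(qualityMetrics) || length(qualityMetrics) < 1L) {
    mzqc_abort("quality element requires at least one metric")
  }
  acc <- vapply(qualityMetrics, function(m) m$accession, character(1))
  if (anyDuplicated(acc)) {
    mzqc_abort(sprintf("duplicate metric accession '%s' within one quality element",
                       acc[duplicated(acc)][1]),
               class = "mzqc_duplicate_metric_error")
  }
  n_files <- length(metadata$inputFiles)
  if (kind == "set" && n_files < 2L) {
    mzqc_abort("a setQuality must reference at least two input files")
  }
  structure(list(metadata = metadata, qualityMetrics = qualityMetrics,
                 kind = kind, extras = extras),
            class = "mzqc_quality_element")
}

#' Quality element holding metrics for a single MS run
#'
#' @param metadata An [mzqc_metadata()]; at least one input file.
#' @param qualityMetrics List of [mzqc_metric()] with unique accessions.
#' @param extras Named list of preserved unknown members.
#' @return An `mzqc_quality_element` with kind `"run"`.
#' @export
mzqc_run_quality <- function(metadata, qualityMetrics, extras = list()) {
  new_quality_element(metadata, qualityMetrics, "run", extras)
}

#' Quality element holding metrics for a set of MS runs
#'
#' @inheritParams mzqc_run_quality
#' @return An `mzqc_quality_element` with kind `"set"`; its metadata must
#'   reference at least two input files.
#' @export
mzqc_set_quality <- function(metadata, qualityMetrics, extras = list()) {
  new_quality_element(metadata, qualityMetrics, "set", extras)
}

#' Construct an mzQC document
#'
#' The root container of an mzQC report: format version, creation timestamp,
#' the controlled vocabularies the metrics are anchored in, and the run-level
#' and/or set-level quality elements.
#'
#' @param controlledVocabularies List of [mzqc_cv_reference()] (at least one).
#' @param runQualities,setQualities Lists of quality elements; at least one of
#'   the two must be non-empty.
#' @param version Format version; only `"1.0.0"` is supported.
#' @param creationDate ISO-8601 timestamp string (date + time, seconds
#'   precision); defaults to the current time. Stored verbatim.
#' @param description,contactName,contactAddress Optional free text.
#' @param extras Named list of preserved unknown members.
#' @return An `mzqc_document` object satisfying all model invariants.
#' @examples
#' doc <- mzqc_document(
#'   controlledVocabularies = list(mzqc_cv_reference("Toy QC CV (QCX)", "file:///qcx.obo")),
#'   runQualities = list(mzqc_run_quality(
#'     mzqc_metadata(
#'       inputFiles = list(mzqc_input_file("run1", "file:///run1.mzML")),
#'       analysisSoftware = list(mzqc_analysis_software("QCX:1000001", "mzqckit", "0.1.0"))
#'     ),
#'     list(mzqc_metric("QCX:0000020", "MS/MS spectrum count", 1234))
#'   ))
#' )
#' @export
mzqc_document <- function(controlledVocabularies, runQualities = list(),
                          setQualities = list(),
                          version = MZQC_SUPPORTED_VERSION,
                          creationDate = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                          description = NULL, contactName = NULL,
                          contactAddress = NULL, extras = list()) {
  if (!is.character(version) || length(version) != 1L ||
      !grepl(MZQC_VERSION_PATTERN, version)) {
    mzqc_abort("malformed version: must match digits.digits.digits",
               class = "mzqc_version_error")
  }
  if (version != MZQC_SUPPORTED_VERSION) {
    mzqc_abort(sprintf("unsupported format version '%s' (supported: %s)",
                       version, MZQC_SUPPORTED_VERSION),
               class = "mzqc_version_error")
  }
  if (!grepl(MZQC_TIMESTAMP_PATTERN, creationDate)) {
    mzqc_abort("creationDate must be an ISO-8601 date-time at seconds precision",
               class = "mzqc_timestamp_error")
  }
  if (!is.list(controlledVocabularies) || length(controlledVocabularies) < 1L) {
    mzqc_abort("controlledVocabularies must be non-empty")
  }
  if (length(runQualities) + length(setQualities) == 0L) {
    mzqc_abort("no quality elements: at least one runQuality or setQuality is required")
  }
  doc <- structure(
    list(version = version, creationDate = creationDate,
         description = description, contactName = contactName,
         contactAddress = contactAddress,
         controlledVocabularies = controlledVocabularies,
         runQualities = runQualities, setQualities = setQualities,
         extras = extras),
    class = "mzqc_document")
  check_elements(doc)
  doc
}

#' Re-validate a whole document against the model invariants
#'
#' Walks an existing document and re-checks every construction-time invariant
#' (version, timestamp, CV list, quality elements, metrics). Used by the
#' strict reader and before serialization; validation is idempotent, so a
#' freshly constructed document always passes.
#'
#' @param doc An `mzqc_document`.
#' @return `doc`, invisibly; aborts with the path of the first violation.
#' @export
validate_mzqc_model <- function(doc) {
  if (!inherits(doc, "mzqc_document")) mzqc_abort("not an mzqc_document")
  if (!is.character(doc$version) || length(doc$version) != 1L ||
      !grepl(MZQC_VERSION_PATTERN, doc$version)) {
    mzqc_abort("malformed version: must match digits.digits.digits (at mzQC/version)",
               class = "mzqc_version_error")
  }
  if (doc$version != MZQC_SUPPORTED_VERSION) {
    mzqc_abort(sprintf("unsupported format version '%s' (at mzQC/version)", doc$version),
               class = "mzqc_version_error")
  }
  if (!is.character(doc$creationDate) || !grepl(MZQC_TIMESTAMP_PATTERN, doc$creationDate)) {
    mzqc_abort("creationDate must be ISO-8601 at seconds precision (at mzQC/creationDate)",
               class = "mzqc_timestamp_error")
  }
  if (length(doc$controlledVocabularies) < 1L) {
    mzqc_abort("controlledVocabularies must be non-empty (at mzQC/controlledVocabularies)")
  }
  if (length(doc$runQualities) + length(doc$setQualities) == 0L) {
    mzqc_abort("no quality elements (at mzQC)")
  }
  for (i in seq_along(doc$controlledVocabularies)) {
    r <- doc$controlledVocabularies[[i]]
    tryCatch(mzqc_cv_reference(r$name, r$uri, r$version, r$extras %||% list()),
             mzqc_error = function(e) {
               mzqc_abort(sprintf("%s (at mzQC/controlledVocabularies/%d)",
                                  conditionMessage(e), i - 1L))
             })
  }
  check_elements(doc)
  invisible(doc)
}

check_elements <- function(doc) {
  walk_one <- function(el, kind, path) {
    tryCatch(revalidate_element(el, kind),
             mzqc_error = function(e) {
               rlang::abort(paste0(conditionMessage(e), " (at ", path, ")"),
                            class = class(e)[class(e) != "rlang_error"])
             })
  }
  for (i in seq_along(doc$runQualities)) {
    walk_one(doc$runQualities[[i]], "run", sprintf("mzQC/runQualities/%d", i - 1L))
  }
  for (i in seq_along(doc$setQualities)) {
    walk_one(doc$setQualities[[i]], "set", sprintf("mzQC/setQualities/%d", i - 1L))
  }
  invisible(doc)
}

revalidate_element <- function(el, kind) {
  md <- el$metadata
  mzqc_metadata(md$inputFiles, md$analysisSoftware, md$label, md$cvParameters,
                md$extras %||% list())
  ms <- lapply(el$qualityMetrics, function(m) {
    mzqc_metric(m$accession, m$name, m$value, m$unit, m$description,
                m$extras %||% list())
  })
  new_quality_element(md, ms, kind, el$extras %||% list())
}

#' Add a metric to a quality element
#'
#' @param element An `mzqc_quality_element`.
#' @param metric An [mzqc_metric()].
#' @return The element with the metric appended; adding an accession already
#'   present is an error ("duplicate metric").
#' @export
add_metric <- function(element, metric) {
  if (!inherits(element, "mzqc_quality_element")) {
    mzqc_abort("element must be an mzqc_quality_element")
  }
  if (!inherits(metric, "mzqc_metric")) metric <- as_mzqc_metric(metric)
  have <- vapply(element$qualityMetrics, function(m) m$accession, character(1))
  if (metric$accession %in% have) {
    mzqc_abort(sprintf("duplicate metric: accession '%s' already present",
                       metric$accession),
               class = "mzqc_duplicate_metric_error")
  }
  element$qualityMetrics <- c(element$qualityMetrics, list(metric))
  element
}

as_mzqc_metric <- function(x) {
  if (inherits(x, "mzqc_metric")) return(x)
  mzqc_abort("metric must be an mzqc_metric object")
}

#' Number of metrics held by a quality element
#'
#' @param element An `mzqc_quality_element`.
#' @return Integer count.
#' @export
n_metrics <- function(element) {
  length(element$qualityMetrics)
}

#' @export
print.mzqc_document <- function(x, ...) {
  cat(sprintf("<mzQC document v%s, created %s>\n", x$version, x$creationDate))
  cat(sprintf("  controlled vocabularies: %d\n", length(x$controlledVocabularies)))
  cat(sprintf("  runQualities: %d  setQualities: %d\n",
              length(x$runQualities), length(x$setQualities)))
  invisible(x)
}

#' @export
print.mzqc_quality_element <- function(x, ...) {
  cat(sprintf("<mzQC %sQuality: %d metric(s), %d input file(s)>\n",
              x$kind, length(x$qualityMetrics), length(x$metadata$inputFiles)))
  invisible(x)
}

#' One-row summary of an mzQC document
#'
#' @param x An `mzqc_document`.
#' @param ... Unused.
#' @return A one-row tibble with version, creation date and element/metric
#'   counts.
#' @exportS3Method generics::glance
glance.mzqc_document <- function(x, ...) {
  tibble::tibble(
    version = x$version,
    creationDate = x$creationDate,
    n_cvs = length(x$controlledVocabularies),
    n_run_qualities = length(x$runQualities),
    n_set_qualities = length(x$setQualities),
    n_metrics = sum(vapply(c(x$runQualities, x$setQualities),
                           function(el) length(el$qualityMetrics), integer(1)))
  )
}

#' Long tibble of the metrics in a document
#'
#' One row per metric per quality element, with the first input file's name
#' and location as run identifiers and scalar values carried in a numeric
#' column (non-scalar kinds get `NA` there and keep their full value in a
#' list-column).
#'
#' @param x An `mzqc_document`.
#' @param ... Unused.
#' @return A tibble with columns `element_kind`, `element_index`, `run_name`,
#'   `run_location`, `accession`, `name`, `kind`, `scalar`, `value`.
#' @exportS3Method generics::tidy
tidy.mzqc_document <- function(x, ...) {
  els <- c(x$runQualities, x$setQualities)
  kinds <- c(rep("run", length(x$runQualities)), rep("set", length(x$setQualities)))
  purrr::map2_dfr(els, seq_along(els), function(el, i) {
    f1 <- el$metadata$inputFiles[[1]]
    purrr::map_dfr(el$qualityMetrics, function(m) {
      tibble::tibble(
        element_kind = el$kind, element_index = i,
        run_name = f1$name, run_location = f1$location,
        accession = m$accession, name = m$name, kind = m$value$kind,
        scalar = if (m$value$kind == "scalar" && is.numeric(m$value$data))
          as.numeric(m$value$data) else NA_real_,
        value = list(m$value$data)
      )
    })
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
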