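# Syntactic validation: structure-against-format-rules checking with
# structured findings. The validator never throws — malformed JSON is itself
# a finding — and collects all problems instead of failing fast. Paths use
# slash notation with zero-based list indices ("mzQC/runQualities/0/...").

new_report <- function(findings) {
  findings <- findings %||% empty_findings()
  structure(list(findings = findings,
                 valid = !any(findings$severity == "error")),
            class = "mzqc_validation_report")
}

empty_findings <- function() {
  tibble::tibble(ruleId = character(), severity = character(),
                 path = character(), message = character())
}

finding_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$add <- function(ruleId, path, message, severity = "error") {
    env$rows[[length(env$rows) + 1L]] <-
      tibble::tibble(ruleId = ruleId, severity = severity,
                     path = path, message = message)
  }
  env$report <- function() {
    new_report(if (length(env$rows)) dplyr::bind_rows(env$rows) else empty_findings())
  }
  env
}

is_json_string <- function(x) is.character(x) && length(x) == 1L && !is.list(x)
is_json_array <- function(x) is.list(x) && is.null(names(x))
is_json_object <- function(x) is.list(x) && (!is.null(names(x)) || length(x) == 0L)

req_string <- function(fc, obj, field, path, pattern = NULL, patternRule = NULL,
                       patternMsg = NULL) {
  if (!field %in% names(obj) || is.null(obj[[field]])) {
    fc$add("required-missing", paste0(path, "/", field),
           sprintf("required field '%s' is missing", field))
    return(invisible(FALSE))
  }
  v <- obj[[field]]
  if (!is_json_string(v)) {
    fc$add("type-mismatch", paste0(path, "/", field),
           sprintf("field '%s' must be a string", field))
    return(invisible(FALSE))
  }
  if (!is.null(pattern) && !grepl(pattern, v)) {
    fc$add(patternRule %||% "pattern-mismatch", paste0(path, "/", field),
           patternMsg %||% sprintf("field '%s' does not match its required pattern", field))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

req_array <- function(fc, obj, field, path, min_items = 1L) {
  if (!field %in% names(obj) || is.null(obj[[field]])) {
    fc$add("required-missing", paste0(path, "/", field),
           sprintf("required field '%s' is missing", field))
    return(NULL)
  }
  v <- obj[[field]]
  if (!is_json_array(v)) {
    fc$add("type-mismatch", paste0(path, "/", field),
           sprintf("field '%s' must be an array", field))
    return(NULL)
  }
  if (length(v) < min_items) {
    fc$add("empty-list", paste0(path, "/", field),
           sprintf("field '%s' must hold at least %d item(s)", field, min_items))
    return(NULL)
  }
  v
}

check_syntax_cv_param <- function(fc, p, path) {
  if (!is_json_object(p)) {
    fc$add("type-mismatch", path, "cvParameter must be an object")
    return(invisible(NULL))
  }
  req_string(fc, p, "accession", path, MZQC_ACCESSION_PATTERN,
             "invalid-accession", "accession must match PREFIX:digits")
  req_string(fc, p, "name", path)
  invisible(NULL)
}

check_syntax_value <- function(fc, m, path) {
  if (!"value" %in% names(m) || is.null(m$value)) {
    fc$add("required-missing", paste0(path, "/value"),
           "metric value is missing or null")
    return(invisible(NULL))
  }
  v <- m$value
  if (is_json_object(v)) {
    if (length(v) == 0L) {
      fc$add("empty-list", paste0(path, "/value"), "table has no columns")
      return(invisible(NULL))
    }
    lens <- vapply(v, function(col) if (is_json_array(col)) length(col) else 1L,
                   integer(1))
    if (any(lens < 1L) || length(unique(lens)) != 1L) {
      fc$add("ragged-table", paste0(path, "/value"),
             sprintf("table columns have unequal lengths (%s)",
                     paste(lens, collapse = ", ")))
    }
  } else if (is_json_array(v) && length(v) == 0L) {
    fc$add("empty-list", paste0(path, "/value"), "tuple must have length >= 1")
  }
  invisible(NULL)
}

check_syntax_metric <- function(fc, m, path) {
  if (!is_json_object(m)) {
    fc$add("type-mismatch", path, "qualityMetric must be an object")
    return(invisible(NULL))
  }
  req_string(fc, m, "accession", path, MZQC_ACCESSION_PATTERN,
             "invalid-accession", "metric accession must match PREFIX:digits")
  req_string(fc, m, "name", path)
  check_syntax_value(fc, m, path)
  invisible(NULL)
}

check_syntax_metadata <- function(fc, md, path, min_input_files) {
  if (!is_json_object(md)) {
    fc$add("type-mismatch", path, "metadata must be an object")
    return(invisible(NULL))
  }
  files <- req_array(fc, md, "inputFiles", path, min_items = min_input_files)
  for (i in seq_along(files)) {
    fp <- sprintf("%s/inputFiles/%d", path, i - 1L)
    if (!is_json_object(files[[i]])) {
      fc$add("type-mismatch", fp, "inputFile must be an object")
      next
    }
    req_string(fc, files[[i]], "name", fp)
    req_string(fc, files[[i]], "location", fp)
  }
  sw <- req_array(fc, md, "analysisSoftware", path, min_items = 1L)
  for (i in seq_along(sw)) {
    sp <- sprintf("%s/analysisSoftware/%d", path, i - 1L)
    if (!is_json_object(sw[[i]])) {
      fc$add("type-mismatch", sp, "analysisSoftware entry must be an object")
      next
    }
    req_string(fc, sw[[i]], "accession", sp, MZQC_ACCESSION_PATTERN,
               "invalid-accession", "software accession must match PREFIX:digits")
    req_string(fc, sw[[i]], "name", sp)
    req_string(fc, sw[[i]], "version", sp)
  }
  invisible(NULL)
}

check_syntax_element <- function(fc, el, path, kind) {
  if (!is_json_object(el)) {
    fc$add("type-mismatch", path, "quality element must be an object")
    return(invisible(NULL))
  }
  if (!"metadata" %in% names(el) || is.null(el$metadata)) {
    fc$add("required-missing", paste0(path, "/metadata"),
           "required field 'metadata' is missing")
  } else {
    check_syntax_metadata(fc, el$metadata, paste0(path, "/metadata"),
                          min_input_files = if (kind == "set") 2L else 1L)
  }
  metrics <- el$qualityMetrics
  if (!"qualityMetrics" %in% names(el) || is.null(metrics)) {
    fc$add("required-missing", paste0(path, "/qualityMetrics"),
           "required field 'qualityMetrics' is missing")
    return(invisible(NULL))
  }
  if (!is_json_array(metrics)) {
    fc$add("type-mismatch", paste0(path, "/qualityMetrics"),
           "qualityMetrics must be an array")
    return(invisible(NULL))
  }
  if (length(metrics) == 0L) {
    fc$add("empty-metrics", paste0(path, "/qualityMetrics"),
           "qualityMetrics must hold at least one metric")
    return(invisible(NULL))
  }
  for (i in seq_along(metrics)) {
    check_syntax_metric(fc, metrics[[i]], sprintf("%s/qualityMetrics/%d", path, i - 1L))
  }
  accs <- vapply(metrics, function(m)
    if (is_json_object(m) && is_json_string(m$accession)) m$accession else NA_character_,
    character(1))
  dup <- unique(accs[!is.na(accs) & duplicated(accs)])
  for (d in dup) {
    fc$add("duplicate-metric", paste0(path, "/qualityMetrics"),
           sprintf("metric accession '%s' appears more than once in this element", d))
  }
  invisible(NULL)
}

#' Syntactic validation of mzQC text
#'
#' Checks that a JSON string conforms to the format's structural rules: JSON
#' well-formedness, the `"mzQC"` root key, required fields and their types,
#' the version / timestamp / accession patterns, non-empty metric and CV
#' lists, equal-length table columns, and metric-accession uniqueness per
#' element. All problems are collected into findings with stable rule ids;
#' the function never throws.
#'
#' @param text JSON string (possibly malformed).
#' @return An `mzqc_validation_report`: a list with a `findings` tibble
#'   (`ruleId`, `severity`, `path`, `message`) and a `valid` flag that is
#'   `TRUE` iff there are no error-severity findings.
#' @examples
#' validate_mzqc_syntax('{"notMzQC": {}}')
#' @export
validate_mzqc_syntax <- function(text) {
  fc <- finding_collector()
  text <- paste(text, collapse = "\n")
  parsed <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                     error = function(e) e)
  if (inherits(parsed, "error")) {
    fc$add("not-json", "mzQC", paste0("input is not valid JSON: ",
                                      conditionMessage(parsed)))
    return(fc$report())
  }
  if (!is_json_object(parsed) || !"mzQC" %in% names(parsed)) {
    fc$add("missing-root", "mzQC", "missing mzQC root key")
    return(fc$report())
  }
  body <- parsed$mzQC
  if (!is_json_object(body)) {
    fc$add("type-mismatch", "mzQC", "mzQC root must be an object")
    return(fc$report())
  }
  req_string(fc, body, "version", "mzQC", "^1\\.0\\.0$", "invalid-version",
             "version must be '1.0.0' (digits.digits.digits, supported release)")
  req_string(fc, body, "creationDate", "mzQC", MZQC_TIMESTAMP_PATTERN,
             "invalid-timestamp",
             "creationDate must be an ISO-8601 date-time at seconds precision")
  cvs <- req_array(fc, body, "controlledVocabularies", "mzQC", min_items = 1L)
  for (i in seq_along(cvs)) {
    cp <- sprintf("mzQC/controlledVocabularies/%d", i - 1L)
    if (!is_json_object(cvs[[i]])) {
      fc$add("type-mismatch", cp, "controlled vocabulary reference must be an object")
      next
    }
    req_string(fc, cvs[[i]], "name", cp)
    req_string(fc, cvs[[i]], "uri", cp)
  }
  rq <- body$runQualities
  sq <- body$setQualities
  bad_rq <- !is.null(rq) && !is_json_array(rq)
  bad_sq <- !is.null(sq) && !is_json_array(sq)
  if (bad_rq) fc$add("type-mismatch", "mzQC/runQualities", "runQualities must be an array")
  if (bad_sq) fc$add("type-mismatch", "mzQC/setQualities", "setQualities must be an array")
  n_elements <- (if (bad_rq) 0L else length(rq)) + (if (bad_sq) 0L else length(sq))
  if (n_elements == 0L) {
    fc$add("no-quality-elements", "mzQC",
           "document has neither runQualities nor setQualities entries")
  }
  if (!bad_rq) {
    for (i in seq_along(rq)) {
      check_syntax_element(fc, rq[[i]], sprintf("mzQC/runQualities/%d", i - 1L), "run")
    }
  }
  if (!bad_sq) {
    for (i in seq_along(sq)) {
      check_syntax_element(fc, sq[[i]], sprintf("mzQC/setQualities/%d", i - 1L), "set")
    }
  }
  fc$report()
}

#' @export
print.mzqc_validation_report <- function(x, ...) {
  cat(sprintf("<mzQC validation report: %s, %d finding(s)>\n",
              if (x$valid) "VALID" else "INVALID", nrow(x$findings)))
  if (nrow(x$findings)) print(x$findings, ...)
  invisible(x)
}

#' Findings of a validation report as a tibble
#'
#' @param x An `mzqc_validation_report`.
#' @param ... Unused.
#' @return The findings tibble (`ruleId`, `severity`, `path`, `message`).
#' @exportS3Method generics::tidy
tidy.mzqc_validation_report <- function(x, ...) x$findings

#' One-row summary of a validation report
#'
#' @param x An `mzqc_validation_report`.
#' @param ... Unused.
#' @return Tibble with `valid`, `n_errors`, `n_warnings`.
#' @exportS3Method generics::glance
glance.mzqc_validation_report <- function(x, ...) {
  tibble::tibble(valid = x$valid,
                 n_errors = sum(x$findings$severity == "error"),
                 n_warnings = sum(x$findings$severity == "warning"))
}

#' Serialize a validation report to JSON
#'
#' Machine-readable form for CI integration: an object with the verdict and
#' the findings array.
#'
#' @param report An `mzqc_validation_report`.
#' @return JSON string.
#' @export
report_to_json <- function(report) {
  as.character(jsonlite::toJSON(
    list(valid = jsonlite::unbox(report$valid), findings = report$findings),
    dataframe = "rows", auto_unbox = FALSE, pretty = TRUE))
}
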