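# Semantic validation: CV-aware content checking of a (syntactically valid)
# document against a controlled-vocabulary store. Findings only, never
# exceptions. Severity policy: a term that cannot be resolved or whose value
# shape contradicts its CV declaration is an error; name mismatches, obsolete
# terms and unlisted CV prefixes are warnings, because the accession is the
# identity carrier.

semantic_check_accession <- function(fc, store, accession, name, path,
                                     check_name = TRUE) {
  term <- cv_lookup(store, accession)
  if (is.null(term)) {
    fc$add("unknown-accession", path,
           sprintf("accession '%s' does not resolve in the controlled vocabulary",
                   accession))
    return(invisible(NULL))
  }
  if (check_name && !is.na(term$name) && !is.null(name) &&
      !identical(trimws(name), trimws(term$name))) {
    fc$add("name-mismatch", path,
           sprintf("name '%s' does not match the CV term name (expected '%s')",
                   name, term$name),
           severity = "warning")
  }
  if (isTRUE(term$is_obsolete)) {
    fc$add("obsolete-term", path,
           sprintf("term '%s' (%s) is obsolete", accession, term$name),
           severity = "warning")
  }
  invisible(term)
}

semantic_check_value <- function(fc, term, value, path) {
  if (is.null(term) || term$value_type == "unspecified") return(invisible(NULL))
  kind <- value$kind
  declared <- term$value_type
  declared_kind <- switch(declared,
                          "scalar-number" = , "scalar-text" = "scalar",
                          declared)
  if (!identical(kind, declared_kind)) {
    fc$add("value-type-mismatch", path,
           sprintf("CV declares value type '%s' but the value is a %s",
                   declared, kind))
    return(invisible(NULL))
  }
  if (declared == "scalar-number" && !is.numeric(value$data)) {
    fc$add("value-type-mismatch", path,
           sprintf("CV declares a numeric scalar but the value is %s",
                   typeof(value$data)))
  }
  if (declared == "table" && length(term$required_columns)) {
    missing_cols <- setdiff(term$required_columns, names(value$data))
    if (length(missing_cols)) {
      fc$add("value-type-mismatch", path,
             sprintf("table is missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")))
    }
  }
  invisible(NULL)
}

semantic_check_cv_param <- function(fc, store, p, path) {
  if (is.null(p)) return(invisible(NULL))
  semantic_check_accession(fc, store, p$accession, p$name, path)
  invisible(NULL)
}

semantic_check_element <- function(fc, store, el, path) {
  md <- el$metadata
  file_names <- vapply(md$inputFiles, function(f) f$name, character(1))
  dup <- unique(file_names[duplicated(file_names)])
  for (d in dup) {
    fc$add("duplicate-input-file", paste0(path, "/metadata/inputFiles"),
           sprintf("input file name '%s' appears more than once", d))
  }
  for (i in seq_along(md$inputFiles)) {
    f <- md$inputFiles[[i]]
    if (!is.null(f$fileFormat)) {
      semantic_check_cv_param(fc, store, f$fileFormat,
                              sprintf("%s/metadata/inputFiles/%d/fileFormat", path, i - 1L))
    }
    for (j in seq_along(f$fileProperties)) {
      semantic_check_cv_param(fc, store, f$fileProperties[[j]],
                              sprintf("%s/metadata/inputFiles/%d/fileProperties/%d",
                                      path, i - 1L, j - 1L))
    }
  }
  for (i in seq_along(md$analysisSoftware)) {
    sw <- md$analysisSoftware[[i]]
    semantic_check_accession(fc, store, sw$accession, sw$name,
                             sprintf("%s/metadata/analysisSoftware/%d", path, i - 1L))
  }
  for (i in seq_along(md$cvParameters)) {
    semantic_check_cv_param(fc, store, md$cvParameters[[i]],
                            sprintf("%s/metadata/cvParameters/%d", path, i - 1L))
  }
  accs <- vapply(el$qualityMetrics, function(m) m$accession, character(1))
  dup <- unique(accs[duplicated(accs)])
  for (d in dup) {
    fc$add("duplicate-metric", paste0(path, "/qualityMetrics"),
           sprintf("metric accession '%s' appears more than once in this element", d))
  }
  for (i in seq_along(el$qualityMetrics)) {
    m <- el$qualityMetrics[[i]]
    mp <- sprintf("%s/qualityMetrics/%d", path, i - 1L)
    term <- semantic_check_accession(fc, store, m$accession, m$name, mp)
    semantic_check_value(fc, term, m$value, paste0(mp, "/value"))
    if (!is.null(m$unit)) {
      units <- if (inherits(m$unit, "mzqc_cv_param")) list(m$unit) else m$unit
      for (j in seq_along(units)) {
        semantic_check_cv_param(fc, store, units[[j]],
                                sprintf("%s/unit/%d", mp, j - 1L))
      }
    }
  }
  invisible(NULL)
}

collect_document_accessions <- function(doc) {
  acc <- character()
  for (el in c(doc$runQualities, doc$setQualities)) {
    md <- el$metadata
    for (f in md$inputFiles) {
      if (!is.null(f$fileFormat)) acc <- c(acc, f$fileFormat$accession)
      for (p in f$fileProperties) acc <- c(acc, p$accession)
    }
    for (sw in md$analysisSoftware) acc <- c(acc, sw$accession)
    for (p in md$cvParameters) acc <- c(acc, p$accession)
    for (m in el$qualityMetrics) {
      acc <- c(acc, m$accession)
      units <- if (inherits(m$unit, "mzqc_cv_param")) list(m$unit) else m$unit
      for (u in units) acc <- c(acc, u$accession)
    }
  }
  unique(acc[!is.na(acc)])
}

#' Semantic validation of an mzQC document against a CV store
#'
#' Verifies CV-anchored content: every accession used by metrics, software
#' references, units and CV parameters resolves in the store (error); names
#' match the CV term names (warning, expected name in the message); metric
#' value kinds match the term's declared value type, including required table
#' columns (error); obsolete terms (warning); metric-accession uniqueness per
#' element and input-file-name uniqueness per metadata (errors); and every CV
#' prefix used in the document appears in `controlledVocabularies` (warning —
#' a prefix counts as listed when it occurs as a word in a reference's name
#' or uri, since the format's CV reference carries no prefix field).
#'
#' @param doc An `mzqc_document`; expected to have passed
#'   [validate_mzqc_syntax()]. Use `read_mzqc(text, strict = FALSE)` to parse
#'   documents that violate model invariants on purpose.
#' @param store An `mzqc_cv_store` from [load_obo()] / [read_obo()].
#' @return An `mzqc_validation_report`; the verdict is `valid` iff there are
#'   no error-severity findings (warnings do not block).
#' @export
validate_mzqc_semantics <- function(doc, store) {
  stopifnot(inherits(doc, "mzqc_document"), inherits(store, "mzqc_cv_store"))
  fc <- finding_collector()
  for (i in seq_along(doc$runQualities)) {
    semantic_check_element(fc, store, doc$runQualities[[i]],
                           sprintf("mzQC/runQualities/%d", i - 1L))
  }
  for (i in seq_along(doc$setQualities)) {
    semantic_check_element(fc, store, doc$setQualities[[i]],
                           sprintf("mzQC/setQualities/%d", i - 1L))
  }
  prefixes <- unique(accession_prefix(collect_document_accessions(doc)))
  listed_text <- tolower(paste(
    vapply(doc$controlledVocabularies, function(r)
      paste(r$name, r$uri, r$version %||% ""), character(1)),
    collapse = " "))
  for (p in prefixes) {
    if (!grepl(paste0("\\b", tolower(p), "\\b"), listed_text)) {
      fc$add("unlisted-cv-prefix", "mzQC/controlledVocabularies",
             sprintf("CV prefix '%s' has no matching controlledVocabularies entry", p),
             severity = "warning")
    }
  }
  fc$report()
}

#' Validate an mzQC file syntactically and optionally semantically
#'
#' Convenience wrapper used by the command-line interface: reads the file,
#' runs [validate_mzqc_syntax()], and, when a CV store is supplied and the
#' syntax verdict allows parsing, also [validate_mzqc_semantics()]; the two
#' reports' findings are concatenated.
#'
#' @param path Path to an mzQC file.
#' @param store Optional `mzqc_cv_store` enabling the semantic stage.
#' @return An `mzqc_validation_report`.
#' @export
validate_mzqc_file <- function(path, store = NULL) {
  if (!file.exists(path) || dir.exists(path)) {
    mzqc_abort(sprintf("cannot read mzQC file '%s'", path), class = "mzqc_io_error")
  }
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  rep_syn <- validate_mzqc_syntax(text)
  if (is.null(store)) return(rep_syn)
  doc <- tryCatch(read_mzqc(text, strict = FALSE), error = function(e) NULL)
  if (is.null(doc)) return(rep_syn)
  rep_sem <- validate_mzqc_semantics(doc, store)
  new_report(dplyr::bind_rows(rep_syn$findings, rep_sem$findings))
}
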