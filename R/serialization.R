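# JSON (de)serialization of mzQC documents.
#
# The writer emits the document under the root key "mzQC", omits absent
# optional fields, serializes numbers at 17 significant digits (full double
# precision, so read(write(doc)) is numerically exact), and re-emits any
# unknown members preserved by the reader. The reader is tolerant: unknown
# members are kept verbatim in each record's `extras`.

DOCUMENT_FIELDS <- c("version", "creationDate", "contactName", "contactAddress",
                     "description", "controlledVocabularies", "runQualities",
                     "setQualities")
ELEMENT_FIELDS <- c("metadata", "qualityMetrics")
METADATA_FIELDS <- c("inputFiles", "analysisSoftware", "label", "cvParameters")
INPUT_FILE_FIELDS <- c("name", "location", "fileFormat", "fileProperties")
SOFTWARE_FIELDS <- c("accession", "name", "version", "uri")
CV_REF_FIELDS <- c("name", "uri", "version")
METRIC_FIELDS <- c("accession", "name", "description", "value", "unit")
CV_PARAM_FIELDS <- c("accession", "name", "value")

compact <- function(x) x[!vapply(x, is.null, logical(1))]

with_extras <- function(fields, extras) {
  if (length(extras)) c(fields, extras) else fields
}

value_to_json_list <- function(v) {
  switch(v$kind,
    scalar = jsonlite::unbox(v$data),
    tuple = if (is.list(v$data)) v$data else I(v$data),
    table = lapply(as.list(v$data), I)
  )
}

cv_param_to_list <- function(p) {
  with_extras(compact(list(accession = p$accession, name = p$name,
                           value = if (is.null(p$value)) NULL else jsonlite::unbox(p$value))),
              p$extras %||% list())
}

unit_to_list <- function(u) {
  if (is.null(u)) return(NULL)
  if (inherits(u, "mzqc_cv_param")) return(cv_param_to_list(u))
  lapply(u, cv_param_to_list)
}

metric_to_list <- function(m) {
  with_extras(compact(list(
    accession = m$accession, name = m$name, description = m$description,
    value = value_to_json_list(m$value), unit = unit_to_list(m$unit)
  )), m$extras %||% list())
}

input_file_to_list <- function(f) {
  with_extras(compact(list(
    name = f$name, location = f$location,
    fileFormat = if (is.null(f$fileFormat)) NULL else cv_param_to_list(f$fileFormat),
    fileProperties = if (is.null(f$fileProperties)) NULL else
      lapply(f$fileProperties, cv_param_to_list)
  )), f$extras %||% list())
}

software_to_list <- function(s) {
  with_extras(compact(list(accession = s$accession, name = s$name,
                           version = s$version, uri = s$uri)),
              s$extras %||% list())
}

metadata_to_list <- function(md) {
  with_extras(compact(list(
    inputFiles = lapply(md$inputFiles, input_file_to_list),
    analysisSoftware = lapply(md$analysisSoftware, software_to_list),
    label = md$label,
    cvParameters = if (is.null(md$cvParameters)) NULL else
      lapply(md$cvParameters, cv_param_to_list)
  )), md$extras %||% list())
}

element_to_list <- function(el) {
  with_extras(list(metadata = metadata_to_list(el$metadata),
                   qualityMetrics = lapply(el$qualityMetrics, metric_to_list)),
              el$extras %||% list())
}

cv_ref_to_list <- function(r) {
  with_extras(compact(list(name = r$name, uri = r$uri, version = r$version)),
              r$extras %||% list())
}

#' Serialize an mzQC document to a JSON string
#'
#' The document is re-validated against the model invariants first; an
#' invariant-violating document is refused. Absent optional fields are
#' omitted (never emitted as `null`), table metrics are emitted as mappings
#' of equal-length arrays, and numbers carry 17 significant digits so that a
#' re-read reproduces them exactly.
#'
#' @param doc An `mzqc_document`.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string with root key `"mzQC"`.
#' @seealso [read_mzqc()], [write_mzqc_file()]
#' @export
write_mzqc <- function(doc, pretty = TRUE) {
  validate_mzqc_model(doc)
  body <- compact(list(
    version = doc$version, creationDate = doc$creationDate,
    contactName = doc$contactName, contactAddress = doc$contactAddress,
    description = doc$description,
    controlledVocabularies = lapply(doc$controlledVocabularies, cv_ref_to_list),
    runQualities = if (length(doc$runQualities))
      lapply(doc$runQualities, element_to_list) else NULL,
    setQualities = if (length(doc$setQualities))
      lapply(doc$setQualities, element_to_list) else NULL
  ))
  body <- with_extras(body, doc$extras %||% list())
  as.character(jsonlite::toJSON(list(mzQC = body), auto_unbox = TRUE,
                                digits = I(17), null = "null", pretty = pretty))
}

#' Write an mzQC document to a file
#'
#' @inheritParams write_mzqc
#' @param path Output path (conventional extension `.mzqc`/`.mzQC`).
#' @return `path`, invisibly.
#' @export
write_mzqc_file <- function(doc, path, pretty = TRUE) {
  writeLines(write_mzqc(doc, pretty = pretty), path, useBytes = TRUE)
  invisible(path)
}

take_extras <- function(lst, known) {
  lst[setdiff(names(lst), known)]
}

scalar_from_json <- function(x, path) {
  if (is.null(x)) mzqc_abort(sprintf("null value (at %s)", path),
                             class = "mzqc_parse_error")
  if (is.list(x) || length(x) != 1L) {
    mzqc_abort(sprintf("expected a scalar (at %s)", path), class = "mzqc_parse_error")
  }
  x
}

parse_value <- function(v, path) {
  if (is.null(v)) {
    mzqc_abort(sprintf("metric value must not be null (at %s)", path),
               class = "mzqc_parse_error")
  }
  if (is.list(v) && !is.null(names(v)) && all(nzchar(names(v)))) {
    cols <- lapply(v, function(col) if (is.list(col)) col else list(col))
    lens <- vapply(cols, length, integer(1))
    if (length(unique(lens)) != 1L || any(lens < 1L)) {
      mzqc_abort(sprintf("ragged table (at %s)", path),
                 class = "mzqc_ragged_table_error")
    }
    cols <- lapply(cols, function(col) unlist(col, use.names = FALSE))
    return(mzqc_value(tibble::as_tibble(cols)))
  }
  if (is.list(v)) {
    if (length(v) < 1L) {
      mzqc_abort(sprintf("empty tuple (at %s)", path), class = "mzqc_parse_error")
    }
    elems <- lapply(seq_along(v), function(i) scalar_from_json(v[[i]], sprintf("%s/%d", path, i - 1L)))
    types <- vapply(elems, function(e) typeof(e), character(1))
    types[types == "integer"] <- "double"
    data <- if (length(unique(types)) == 1L) unlist(elems, use.names = FALSE) else elems
    return(mzqc_value(if (length(elems) == 1L) as.list(data) else data, kind = "tuple"))
  }
  mzqc_value(scalar_from_json(v, path))
}

parse_cv_param <- function(p, path, strict) {
  fields <- list(accession = p$accession %||% NA_character_,
                 name = p$name %||% NA_character_,
                 value = p$value,
                 extras = take_extras(p, CV_PARAM_FIELDS))
  if (strict) do.call(mzqc_cv_param, fields)
  else structure(fields, class = "mzqc_cv_param")
}

parse_unit <- function(u, path, strict) {
  if (is.null(u)) return(NULL)
  if (is.list(u) && is.null(names(u))) {
    return(lapply(seq_along(u), function(i)
      parse_cv_param(u[[i]], sprintf("%s/%d", path, i - 1L), strict)))
  }
  parse_cv_param(u, path, strict)
}

parse_metric <- function(m, path, strict) {
  fields <- list(accession = m$accession %||% NA_character_,
                 name = m$name %||% NA_character_,
                 value = parse_value(m$value, paste0(path, "/value")),
                 unit = parse_unit(m$unit, paste0(path, "/unit"), strict),
                 description = m$description,
                 extras = take_extras(m, METRIC_FIELDS))
  if (strict) do.call(mzqc_metric, fields)
  else structure(fields[c("accession", "name", "description", "value", "unit", "extras")],
                 class = "mzqc_metric")
}

parse_input_file <- function(f, path, strict) {
  fields <- list(name = f$name %||% NA_character_,
                 location = f$location %||% NA_character_,
                 fileFormat = if (is.null(f$fileFormat)) NULL else
                   parse_cv_param(f$fileFormat, paste0(path, "/fileFormat"), strict),
                 fileProperties = if (is.null(f$fileProperties)) NULL else
                   lapply(seq_along(f$fileProperties), function(i)
                     parse_cv_param(f$fileProperties[[i]],
                                    sprintf("%s/fileProperties/%d", path, i - 1L), strict)),
                 extras = take_extras(f, INPUT_FILE_FIELDS))
  if (strict) do.call(mzqc_input_file, fields)
  else structure(fields, class = "mzqc_input_file")
}

parse_software <- function(s, path, strict) {
  fields <- list(accession = s$accession %||% NA_character_,
                 name = s$name %||% NA_character_,
                 version = s$version %||% NA_character_,
                 uri = s$uri,
                 extras = take_extras(s, SOFTWARE_FIELDS))
  if (strict) do.call(mzqc_analysis_software, fields)
  else structure(fields, class = "mzqc_analysis_software")
}

parse_metadata <- function(md, path, strict) {
  fields <- list(
    inputFiles = lapply(seq_along(md$inputFiles), function(i)
      parse_input_file(md$inputFiles[[i]], sprintf("%s/inputFiles/%d", path, i - 1L), strict)),
    analysisSoftware = lapply(seq_along(md$analysisSoftware), function(i)
      parse_software(md$analysisSoftware[[i]],
                     sprintf("%s/analysisSoftware/%d", path, i - 1L), strict)),
    label = md$label,
    cvParameters = if (is.null(md$cvParameters)) NULL else
      lapply(seq_along(md$cvParameters), function(i)
        parse_cv_param(md$cvParameters[[i]],
                       sprintf("%s/cvParameters/%d", path, i - 1L), strict)),
    extras = take_extras(md, METADATA_FIELDS))
  if (strict) do.call(mzqc_metadata, fields)
  else structure(fields, class = "mzqc_metadata")
}

parse_element <- function(el, kind, path, strict) {
  md <- parse_metadata(el$metadata %||% list(), paste0(path, "/metadata"), strict)
  metrics <- lapply(seq_along(el$qualityMetrics), function(i)
    parse_metric(el$qualityMetrics[[i]],
                 sprintf("%s/qualityMetrics/%d", path, i - 1L), strict))
  if (strict) new_quality_element(md, metrics, kind, take_extras(el, ELEMENT_FIELDS))
  else structure(list(metadata = md, qualityMetrics = metrics, kind = kind,
                      extras = take_extras(el, ELEMENT_FIELDS)),
                 class = "mzqc_quality_element")
}

parse_cv_ref <- function(r, path, strict) {
  fields <- list(name = r$name %||% NA_character_, uri = r$uri %||% NA_character_,
                 version = r$version, extras = take_extras(r, CV_REF_FIELDS))
  if (strict) do.call(mzqc_cv_reference, fields)
  else structure(fields, class = "mzqc_cv_reference")
}

#' Deserialize an mzQC document from a JSON string
#'
#' Parses the JSON, requires the root key `"mzQC"`, maps table-valued metrics
#' to tibbles and tuple values to vectors, preserves unknown members, and (by
#' default) enforces all model invariants with the document path of any
#' violation in the error message.
#'
#' @param text A JSON string.
#' @param strict Enforce model invariants (default). `strict = FALSE` parses
#'   structure-only, which lets the validators inspect documents that violate
#'   invariants (e.g. duplicate metric accessions).
#' @return An `mzqc_document`.
#' @seealso [write_mzqc()], [read_mzqc_file()]
#' @export
read_mzqc <- function(text, strict = TRUE) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  parsed <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                     error = function(e) {
                       mzqc_abort(paste0("not valid JSON: ", conditionMessage(e)),
                                  class = "mzqc_parse_error")
                     })
  if (!is.list(parsed) || is.null(parsed$mzQC)) {
    mzqc_abort("missing mzQC root key", class = "mzqc_format_error")
  }
  body <- parsed$mzQC
  # parse structure-only first; strict mode re-validates afterwards so that
  # invariant errors carry their document path
  cvs <- lapply(seq_along(body$controlledVocabularies), function(i)
    parse_cv_ref(body$controlledVocabularies[[i]],
                 sprintf("mzQC/controlledVocabularies/%d", i - 1L), FALSE))
  rq <- lapply(seq_along(body$runQualities), function(i)
    parse_element(body$runQualities[[i]], "run",
                  sprintf("mzQC/runQualities/%d", i - 1L), FALSE))
  sq <- lapply(seq_along(body$setQualities), function(i)
    parse_element(body$setQualities[[i]], "set",
                  sprintf("mzQC/setQualities/%d", i - 1L), FALSE))
  doc <- structure(
    list(version = body$version %||% NA_character_,
         creationDate = body$creationDate %||% NA_character_,
         description = body$description, contactName = body$contactName,
         contactAddress = body$contactAddress,
         controlledVocabularies = cvs, runQualities = rq, setQualities = sq,
         extras = take_extras(body, DOCUMENT_FIELDS)),
    class = "mzqc_document")
  if (strict) validate_mzqc_model(doc)
  doc
}

#' Read an mzQC document from a local file
#'
#' Equivalent to [read_mzqc()] on the file's contents. Remote locations are
#' deliberately not fetched; retrieve the text yourself and use [read_mzqc()].
#'
#' @param path Path to an existing, readable `.mzqc` file.
#' @inheritParams read_mzqc
#' @return An `mzqc_document`.
#' @export
read_mzqc_file <- function(path, strict = TRUE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path) ||
      dir.exists(path)) {
    mzqc_abort(sprintf("cannot read mzQC file '%s': no such file", path),
               class = "mzqc_io_error")
  }
  read_mzqc(readLines(path, warn = FALSE, encoding = "UTF-8"), strict = strict)
}

# ---- structural equality ----------------------------------------------------

canon_scalarish <- function(x) {
  if (is.numeric(x)) as.double(x) else x
}

canon_value <- function(v) {
  data <- switch(v$kind,
    scalar = canon_scalarish(v$data),
    tuple = lapply(as.list(v$data), canon_scalarish),
    table = lapply(as.list(v$data), function(col) canon_scalarish(unname(col)))
  )
  list(kind = v$kind, data = data)
}

canon_extras <- function(e) {
  e <- e %||% list()
  if (!length(e)) return(NULL)
  e[order(names(e))]
}

canon_record <- function(x, fields, sub = list()) {
  out <- list()
  for (f in fields) {
    val <- x[[f]]
    if (is.null(val)) next
    out[[f]] <- if (!is.null(sub[[f]])) sub[[f]](val) else canon_scalarish(val)
  }
  out$extras <- canon_extras(x$extras)
  compact(out)
}

canon_cv_param <- function(p) canon_record(p, CV_PARAM_FIELDS)
canon_unit <- function(u) {
  if (is.null(u)) return(NULL)
  if (inherits(u, "mzqc_cv_param")) canon_cv_param(u) else lapply(u, canon_cv_param)
}

canon_metric <- function(m) {
  canon_record(m, METRIC_FIELDS,
               sub = list(value = canon_value, unit = canon_unit))
}

canon_input_file <- function(f) {
  canon_record(f, INPUT_FILE_FIELDS,
               sub = list(fileFormat = canon_cv_param,
                          fileProperties = function(x) lapply(x, canon_cv_param)))
}

canon_element <- function(el) {
  list(
    metadata = canon_record(el$metadata, METADATA_FIELDS, sub = list(
      inputFiles = function(x) lapply(x, canon_input_file),
      analysisSoftware = function(x) lapply(x, function(s)
        canon_record(s, SOFTWARE_FIELDS)),
      cvParameters = function(x) lapply(x, canon_cv_param))),
    qualityMetrics = lapply(el$qualityMetrics, canon_metric),
    extras = canon_extras(el$extras)
  )
}

#' Canonical plain-list form of an mzQC document
#'
#' Normalizes a document for structural comparison: optional absent fields
#' dropped, numerics coerced to double, tables to named column lists, extras
#' sorted by name. Two documents are structurally equal iff their canonical
#' forms are `identical()`.
#'
#' @param doc An `mzqc_document`.
#' @return A plain nested list.
#' @export
mzqc_canonical <- function(doc) {
  compact(list(
    version = doc$version, creationDate = doc$creationDate,
    description = doc$description, contactName = doc$contactName,
    contactAddress = doc$contactAddress,
    controlledVocabularies = lapply(doc$controlledVocabularies, function(r)
      canon_record(r, CV_REF_FIELDS)),
    runQualities = lapply(doc$runQualities, canon_element),
    setQualities = lapply(doc$setQualities, canon_element),
    extras = canon_extras(doc$extras)
  ))
}

#' Structural equality of two mzQC documents
#'
#' Field-by-field comparison that ignores representation details (key order,
#' integer vs double storage) but is order-sensitive for lists, as the format
#' requires.
#'
#' @param a,b `mzqc_document` objects.
#' @return `TRUE` or `FALSE`.
#' @export
mzqc_equal <- function(a, b) {
  identical(mzqc_canonical(a), mzqc_canonical(b))
}
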