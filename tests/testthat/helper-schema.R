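# Generic keyword-driven JSON-Schema interpreter used as the independent
# oracle for the syntactic validator. It contains no format-specific logic:
# everything it enforces comes from the schema document it is given
# (inst/extdata/mzqc_schema_synthetic.json), including the two extension
# keywords x-equal-length-arrays and x-unique-by declared there.

schema_json_type <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (length(x) == 0L) return(c("object", "array")) # {} and [] both parse to list()
    if (is.null(names(x))) return("array")
    return("object")
  }
  if (is.character(x)) return("string")
  if (is.logical(x)) return("boolean")
  if (is.numeric(x)) return("number")
  "unknown"
}

schema_check <- function(inst, node, root) {
  if (!is.null(node[["$ref"]])) {
    ref <- sub("^#/definitions/", "", node[["$ref"]])
    return(schema_check(inst, root$definitions[[ref]], root))
  }
  if (!is.null(node$type)) {
    allowed <- unlist(node$type)
    if (!any(schema_json_type(inst) %in% allowed)) return(FALSE)
  }
  if (!is.null(node$pattern)) {
    if (!is.character(inst) || length(inst) != 1L ||
        !grepl(node$pattern, inst, perl = TRUE)) return(FALSE)
  }
  if (!is.null(node$minLength)) {
    if (!is.character(inst) || nchar(inst) < node$minLength) return(FALSE)
  }
  if (!is.null(node$required)) {
    if (!"object" %in% schema_json_type(inst)) return(FALSE)
    if (!all(unlist(node$required) %in% names(inst))) return(FALSE)
  }
  if (!is.null(node$minItems)) {
    if (!"array" %in% schema_json_type(inst) || length(inst) < node$minItems) {
      return(FALSE)
    }
  }
  if (!is.null(node$minProperties)) {
    if (!"object" %in% schema_json_type(inst) || length(inst) < node$minProperties) {
      return(FALSE)
    }
  }
  if (!is.null(node$properties) && "object" %in% schema_json_type(inst)) {
    for (prop in names(node$properties)) {
      if (prop %in% names(inst) && !is.null(inst[[prop]])) {
        if (!schema_check(inst[[prop]], node$properties[[prop]], root)) {
          return(FALSE)
        }
      }
    }
  }
  if (!is.null(node$items) && "array" %in% schema_json_type(inst)) {
    for (el in inst) {
      if (!schema_check(el, node$items, root)) return(FALSE)
    }
  }
  if (!is.null(node$anyOf)) {
    ok <- any(vapply(node$anyOf, function(sub)
      schema_check(inst, sub, root), logical(1)))
    if (!ok) return(FALSE)
  }
  if (!is.null(node$not)) {
    if (schema_check(inst, node$not, root)) return(FALSE)
  }
  if (isTRUE(node[["x-equal-length-arrays"]]) &&
      identical(schema_json_type(inst), "object")) {
    lens <- vapply(inst, function(col)
      if (identical(schema_json_type(col), "array")) length(col) else 1L,
      integer(1))
    if (length(lens) && (any(lens < 1L) || length(unique(lens)) != 1L)) {
      return(FALSE)
    }
  }
  if (!is.null(node[["x-unique-by"]]) && "array" %in% schema_json_type(inst)) {
    field <- node[["x-unique-by"]]
    keys <- vapply(inst, function(el)
      if (is.list(el) && !is.null(el[[field]]) && is.character(el[[field]]))
        el[[field]] else NA_character_, character(1))
    keys <- keys[!is.na(keys)]
    if (anyDuplicated(keys)) return(FALSE)
  }
  TRUE
}

#' Validate JSON text against a schema file; TRUE iff valid (unparseable
#' JSON is invalid, mirroring a validator that reports rather than throws).
schema_oracle_valid <- function(text, schema_path = NULL) {
  schema_path <- schema_path %||% system.file(
    "extdata", "mzqc_schema_synthetic.json", package = "mzqckit")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  inst <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                   error = function(e) NULL)
  if (is.null(inst)) return(FALSE)
  schema_check(inst, schema, schema)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
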