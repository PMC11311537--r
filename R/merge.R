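# Merging partial mzQC documents into one report. Run identity is the
# location of the element's first input file (falling back to its name);
# elements describing the same run are coalesced into one runQuality holding
# the union of their metrics.

element_run_key <- function(el) {
  f1 <- el$metadata$inputFiles[[1]]
  if (!is.null(f1$location) && nzchar(f1$location)) f1$location else f1$name
}

cv_ref_key <- function(r) paste(r$name, r$uri, r$version %||% "", sep = "\r")
software_key <- function(s) paste(s$accession, s$name, s$version, sep = "\r")
input_file_key <- function(f) paste(f$name, f$location, sep = "\r")

union_by_key <- function(lists, key_fun) {
  out <- list()
  seen <- character()
  for (item in lists) {
    k <- key_fun(item)
    if (!k %in% seen) {
      seen <- c(seen, k)
      out <- c(out, list(item))
    }
  }
  out
}

merge_two_elements <- function(a, b, on_conflict, run_key) {
  md <- mzqc_metadata(
    inputFiles = union_by_key(c(a$metadata$inputFiles, b$metadata$inputFiles),
                              input_file_key),
    analysisSoftware = union_by_key(c(a$metadata$analysisSoftware,
                                      b$metadata$analysisSoftware),
                                    software_key),
    label = a$metadata$label %||% b$metadata$label,
    cvParameters = if (is.null(a$metadata$cvParameters) &&
                       is.null(b$metadata$cvParameters)) NULL else
      union_by_key(c(a$metadata$cvParameters %||% list(),
                     b$metadata$cvParameters %||% list()),
                   function(p) p$accession))
  metrics <- a$qualityMetrics
  have <- vapply(metrics, function(m) m$accession, character(1))
  for (m in b$qualityMetrics) {
    i <- match(m$accession, have)
    if (is.na(i)) {
      metrics <- c(metrics, list(m))
      have <- c(have, m$accession)
    } else if (!identical(canon_metric(metrics[[i]]), canon_metric(m))) {
      if (on_conflict == "error") {
        mzqc_abort(sprintf(
          "metric conflict: run '%s', accession '%s' has unequal values",
          run_key, m$accession), class = "mzqc_merge_conflict_error")
      }
      rlang::warn(sprintf(
        "metric conflict for run '%s', accession '%s': keeping the first value",
        run_key, m$accession))
    }
  }
  mzqc_run_quality(md, metrics)
}

#' Merge mzQC documents into one report
#'
#' runQualities that describe the same run — matched by the location of their
#' first input file, falling back to its name — are coalesced into a single
#' element holding the union of their metrics; metadata software lists and
#' input files are unioned, controlled vocabularies are deduplicated by
#' (name, uri, version), setQualities are concatenated, and the creation
#' date is set to the merge time. The merge is idempotent and, for
#' conflict-free inputs, insensitive to document order up to list ordering.
#'
#' @param docs List of `mzqc_document` objects (at least one), each
#'   syntactically valid.
#' @param on_conflict What to do when the same run carries the same metric
#'   accession with unequal values: `"error"` (default, trustworthy reports)
#'   or `"keep-first"` (warning).
#' @param creation_date Timestamp for the merged document.
#' @return A single `mzqc_document`.
#' @export
merge_mzqc <- function(docs, on_conflict = c("error", "keep-first"),
                       creation_date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  on_conflict <- match.arg(on_conflict)
  if (inherits(docs, "mzqc_document")) docs <- list(docs)
  if (!length(docs)) mzqc_abort("merge requires at least one document")
  for (d in docs) validate_mzqc_model(d)

  runs <- list() # run key -> coalesced element
  run_order <- character()
  for (d in docs) {
    for (el in d$runQualities) {
      k <- element_run_key(el)
      if (is.null(runs[[k]])) {
        runs[[k]] <- el
        run_order <- c(run_order, k)
      } else {
        runs[[k]] <- merge_two_elements(runs[[k]], el, on_conflict, k)
      }
    }
  }
  cvs <- union_by_key(unlist(lapply(docs, function(d) d$controlledVocabularies),
                             recursive = FALSE), cv_ref_key)
  sets <- unlist(lapply(docs, function(d) d$setQualities), recursive = FALSE) %||% list()
  desc <- Filter(Negate(is.null), lapply(docs, function(d) d$description))
  mzqc_document(
    controlledVocabularies = cvs,
    runQualities = unname(runs[run_order]),
    setQualities = sets,
    creationDate = creation_date,
    description = if (length(desc)) desc[[1]] else NULL)
}
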