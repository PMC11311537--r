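# Controlled-vocabulary support: a small OBO 1.2/1.4 [Term]-stanza parser and
# the term queries the semantic validator needs. Only `is_a` parent links are
# interpreted; [Typedef] and other stanzas are skipped. Value-type
# declarations are read from xref lines of the forms
#   xref: value-type:scalar-number        (also scalar-text, tuple, table)
#   xref: required-column:RT              (repeatable, for table terms)
# Terms without a value-type declaration get "unspecified" and are exempt
# from value-type checking.

new_cv_term <- function(accession, name = NA_character_, definition = NULL,
                        parents = character(), value_type = "unspecified",
                        required_columns = character(), is_obsolete = FALSE) {
  structure(list(accession = accession, name = name, definition = definition,
                 parents = parents, value_type = value_type,
                 required_columns = required_columns,
                 is_obsolete = is_obsolete),
            class = "mzqc_cv_term")
}

#' Parse a controlled vocabulary from OBO text
#'
#' Reads `[Term]` stanzas (id, name, def, is_a, is_obsolete, and the value
#' type xref annotations described above) into a queryable store. Parsing is
#' deterministic and stanza-order-insensitive for lookups; a stanza without
#' an `id`, a duplicate id, or a cyclic `is_a` closure is a parse error.
#'
#' @param text OBO flat-file content as a character vector of lines or a
#'   single string.
#' @return An `mzqc_cv_store`: terms indexed by accession plus source
#'   name/version provenance and any dangling parent accessions.
#' @seealso [read_obo()], [cv_lookup()], [cv_is_descendant()]
#' @export
load_obo <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("\r$", "", lines)
  source_name <- NA_character_
  source_version <- NA_character_
  terms <- list()
  cur <- NULL
  cur_start <- NA_integer_
  in_term <- FALSE

  flush_term <- function() {
    if (is.null(cur)) return(invisible(NULL))
    if (is.na(cur$accession) || !nzchar(cur$accession)) {
      mzqc_abort(sprintf("OBO [Term] stanza starting at line %d has no id", cur_start),
                 class = "mzqc_obo_error")
    }
    if (!is.null(terms[[cur$accession]])) {
      mzqc_abort(sprintf("duplicate OBO term id '%s' (stanza at line %d)",
                         cur$accession, cur_start),
                 class = "mzqc_obo_error")
    }
    terms[[cur$accession]] <<- do.call(new_cv_term, cur)
    cur <<- NULL
    invisible(NULL)
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      flush_term()
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(accession = NA_character_, name = NA_character_,
                    definition = NULL, parents = character(),
                    value_type = "unspecified",
                    required_columns = character(), is_obsolete = FALSE)
        cur_start <- i
      }
      next
    }
    kv <- regmatches(line, regexec("^([A-Za-z_-]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) next
    key <- kv[2]
    val <- sub("\\s*!.*$", "", kv[3]) # strip trailing OBO comments
    if (!in_term || is.null(cur)) {
      if (key == "ontology") source_name <- val
      if (key == "data-version") source_version <- val
      next
    }
    if (key == "id") {
      cur$accession <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "def") {
      cur$definition <- gsub('^"|"\\s*\\[.*$', "", val)
    } else if (key == "is_a") {
      cur$parents <- c(cur$parents, trimws(val))
    } else if (key == "is_obsolete") {
      cur$is_obsolete <- identical(trimws(val), "true")
    } else if (key == "xref") {
      v <- trimws(val)
      if (grepl("^value-type:", v)) {
        cur$value_type <- sub("^value-type:", "", v)
      } else if (grepl("^required-column:", v)) {
        cur$required_columns <- c(cur$required_columns,
                                  sub("^required-column:", "", v))
      }
    }
  }
  flush_term()

  all_parents <- unique(unlist(lapply(terms, function(t) t$parents)))
  dangling <- setdiff(all_parents, names(terms))
  store <- structure(list(terms = terms, source_name = source_name,
                          source_version = source_version, dangling = dangling),
                     class = "mzqc_cv_store")
  check_acyclic(store)
  store
}

#' Read a controlled vocabulary from an OBO file
#'
#' @param path Path to a local OBO file (UTF-8). The CV is offline-first: no
#'   network fetch happens in library code.
#' @return An `mzqc_cv_store`; see [load_obo()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path) || dir.exists(path)) {
    mzqc_abort(sprintf("cannot read OBO file '%s'", path), class = "mzqc_io_error")
  }
  load_obo(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

check_acyclic <- function(store) {
  color <- new.env(parent = emptyenv())
  visit <- function(acc) {
    state <- color[[acc]] %||% "white"
    if (state == "grey") {
      mzqc_abort(sprintf("cycle in is_a hierarchy involving '%s'", acc),
                 class = "mzqc_obo_error")
    }
    if (state == "black") return(invisible(NULL))
    color[[acc]] <- "grey"
    for (p in store$terms[[acc]]$parents) {
      if (!is.null(store$terms[[p]])) visit(p)
    }
    color[[acc]] <- "black"
    invisible(NULL)
  }
  for (acc in names(store$terms)) visit(acc)
  invisible(store)
}

#' Look up a CV term by accession
#'
#' @param store An `mzqc_cv_store`.
#' @param accession Accession string.
#' @return The `mzqc_cv_term`, or `NULL` for an unknown accession.
#' @export
cv_lookup <- function(store, accession) {
  stopifnot(inherits(store, "mzqc_cv_store"))
  store$terms[[accession]]
}

#' Is one term a descendant of another?
#'
#' Reachability through the `is_a` closure; reflexive (every term is its own
#' descendant).
#'
#' @param store An `mzqc_cv_store`.
#' @param accession Candidate descendant accession.
#' @param ancestor Candidate ancestor accession.
#' @return `TRUE`/`FALSE`; unresolvable accessions are an error.
#' @export
cv_is_descendant <- function(store, accession, ancestor) {
  stopifnot(inherits(store, "mzqc_cv_store"))
  for (a in c(accession, ancestor)) {
    if (is.null(store$terms[[a]])) {
      mzqc_abort(sprintf("accession '%s' does not resolve in the CV store", a),
                 class = "mzqc_cv_error")
    }
  }
  if (accession == ancestor) return(TRUE)
  seen <- character()
  frontier <- accession
  while (length(frontier)) {
    nxt <- character()
    for (acc in frontier) {
      term <- store$terms[[acc]]
      if (is.null(term)) next
      for (p in term$parents) {
        if (p == ancestor) return(TRUE)
        if (!p %in% seen) {
          seen <- c(seen, p)
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- nxt
  }
  FALSE
}

#' @export
print.mzqc_cv_store <- function(x, ...) {
  cat(sprintf("<CV store '%s' (%s): %d term(s), %d dangling parent(s)>\n",
              x$source_name, x$source_version, length(x$terms),
              length(x$dangling)))
  invisible(x)
}

#' Terms of a CV store as a tibble
#'
#' @param x An `mzqc_cv_store`.
#' @param ... Unused.
#' @return One row per term: accession, name, value type, required columns
#'   (comma-joined), obsolescence flag, parent accessions (comma-joined).
#' @exportS3Method generics::tidy
tidy.mzqc_cv_store <- function(x, ...) {
  purrr::map_dfr(x$terms, function(t) {
    tibble::tibble(accession = t$accession, name = t$name,
                   value_type = t$value_type,
                   required_columns = paste(t$required_columns, collapse = ","),
                   is_obsolete = t$is_obsolete,
                   parents = paste(t$parents, collapse = ","))
  })
}
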