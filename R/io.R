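# Tabular and run-level I/O: the bespoke PSM TSV interface and a plain JSON
# representation of in-memory runs (so pipelines can pass runs between
# processes without raw-data dependencies).

PSM_COLUMNS <- c("spectrum_id", "rt_seconds", "observed_mz", "charge",
                 "peptide", "proteins", "q_value")

#' Read a peptide-spectrum-match table from TSV
#'
#' The expected format is tab-delimited UTF-8 with a header row and columns
#' `spectrum_id, rt_seconds, observed_mz, charge, peptide, proteins, q_value`;
#' `proteins` is semicolon-delimited and becomes a list-column.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per PSM; `q_value` is checked to lie in
#'   \[0, 1\] and `charge` to be >= 1.
#' @export
read_psm_tsv <- function(path) {
  if (!file.exists(path) || dir.exists(path)) {
    mzqc_abort(sprintf("cannot read PSM table '%s'", path), class = "mzqc_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    spectrum_id = readr::col_character(), rt_seconds = readr::col_double(),
    observed_mz = readr::col_double(), charge = readr::col_integer(),
    peptide = readr::col_character(), proteins = readr::col_character(),
    q_value = readr::col_double()), progress = FALSE)
  missing_cols <- setdiff(PSM_COLUMNS, names(df))
  if (length(missing_cols)) {
    mzqc_abort(sprintf("PSM table lacks column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  validate_psm_table(dplyr::mutate(df, proteins = strsplit(.data$proteins, ";", fixed = TRUE)))
}

validate_psm_table <- function(df) {
  if (any(!nzchar(df$peptide))) mzqc_abort("PSM table contains an empty peptide")
  if (any(df$charge < 1L)) mzqc_abort("PSM charge must be >= 1")
  if (any(df$q_value < 0 | df$q_value > 1)) mzqc_abort("q_value must lie in [0, 1]")
  df
}

#' Write a PSM tibble to TSV
#'
#' Inverse of [read_psm_tsv()]: the `proteins` list-column is joined with
#' semicolons.
#'
#' @param psms PSM tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_tsv <- function(psms, path) {
  out <- dplyr::mutate(psms, proteins = vapply(.data$proteins, paste,
                                               character(1), collapse = ";"))
  readr::write_tsv(out[, PSM_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Write an in-memory run to a JSON file
#'
#' A plain JSON encoding of the package's run representation (name, source
#' location, chromatogram count, spectra with peak arrays). Numbers are kept
#' at full double precision.
#'
#' @param run An [ms_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_json <- function(run, path) {
  stopifnot(inherits(run, "mzqc_run"))
  spectra <- lapply(run$spectra, function(s) {
    compact(list(
      native_id = jsonlite::unbox(s$native_id),
      ms_level = jsonlite::unbox(s$ms_level),
      rt_seconds = jsonlite::unbox(s$rt_seconds),
      mz = I(s$mz), intensity = I(s$intensity),
      precursor_mz = if (is.null(s$precursor_mz)) NULL else jsonlite::unbox(s$precursor_mz),
      precursor_charge = if (is.null(s$precursor_charge)) NULL else
        jsonlite::unbox(s$precursor_charge),
      injection_time_ms = if (is.null(s$injection_time_ms)) NULL else
        jsonlite::unbox(s$injection_time_ms)))
  })
  body <- list(run_name = jsonlite::unbox(run$run_name),
               source_location = jsonlite::unbox(run$source_location),
               chromatogram_count = jsonlite::unbox(run$chromatogram_count),
               spectra = spectra)
  writeLines(as.character(jsonlite::toJSON(body, digits = I(17))), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read an in-memory run from a JSON file written by [write_run_json()]
#'
#' @param path Path to the run JSON file.
#' @return An [ms_run()].
#' @export
read_run_json <- function(path) {
  if (!file.exists(path) || dir.exists(path)) {
    mzqc_abort(sprintf("cannot read run file '%s'", path), class = "mzqc_io_error")
  }
  body <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  spectra <- lapply(body$spectra, function(s) {
    spectrum(native_id = s$native_id, ms_level = s$ms_level,
             rt_seconds = s$rt_seconds,
             mz = unlist(s$mz) %||% numeric(),
             intensity = unlist(s$intensity) %||% numeric(),
             precursor_mz = s$precursor_mz,
             precursor_charge = s$precursor_charge,
             injection_time_ms = s$injection_time_ms)
  })
  ms_run(body$run_name, body$source_location, spectra, body$chromatogram_count)
}
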