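# QC metric computation from in-memory MS runs and peptide-spectrum-match
# (PSM) tables. Retention times are seconds everywhere; m/z in Thomson;
# injection times in milliseconds. Metrics are returned as CV-anchored
# mzqc_metric objects using the toy QC vocabulary shipped with the package
# (see qc_metric_catalog()); swapping in real PSI-MS accessions is a matter
# of editing that catalog.

#' Monoisotopic mass tables
#'
#' Monoisotopic residue masses (Da) for the 20 standard amino acids, the mass
#' of water, and the proton mass, kept in one place for auditability.
#'
#' @return A list with elements `residues` (named numeric vector), `water`
#'   and `proton` (Da).
#' @export
monoisotopic_mass_tables <- function() {
  list(
    residues = c(
      G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
      V = 99.06841391, T = 101.04767847, C = 103.00918496, L = 113.08406398,
      I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
      K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
      F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
    ),
    water = 18.0105646863,
    proton = 1.00727646688
  )
}

#' Strip bracketed modification offsets from a peptide string
#'
#' @param peptide Character vector of peptide strings such as
#'   `"PEPTM[+15.9949]IDE"`.
#' @return The bare residue sequences.
#' @export
strip_modifications <- function(peptide) {
  gsub("\\[[^]\\[]*\\]", "", peptide)
}

peptide_offsets <- function(peptide) {
  vapply(peptide, function(p) {
    m <- regmatches(p, gregexpr("\\[([+-]?[0-9]*\\.?[0-9]+)\\]", p))[[1]]
    if (!length(m)) return(0)
    sum(as.numeric(gsub("\\[|\\]", "", m)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus water plus any bracketed mass offsets.
#'
#' @param peptide Character vector of peptide strings (standard one-letter
#'   residues, optional bracketed signed decimal offsets).
#' @param tables Mass tables, see [monoisotopic_mass_tables()].
#' @return Numeric vector of masses in Da; an unknown residue letter is an
#'   error naming its position.
#' @examples
#' peptide_monoisotopic_mass("G") # 75.03203
#' @export
peptide_monoisotopic_mass <- function(peptide, tables = monoisotopic_mass_tables()) {
  bare <- strip_modifications(peptide)
  offs <- peptide_offsets(peptide)
  vapply(seq_along(bare), function(i) {
    s <- bare[i]
    if (!nzchar(s)) mzqc_abort("empty peptide sequence")
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    masses <- tables$residues[res]
    if (anyNA(masses)) {
      bad <- which(is.na(masses))[1]
      mzqc_abort(sprintf("unknown residue '%s' at position %d in '%s'",
                         res[bad], bad, s))
    }
    sum(masses) + tables$water + offs[i]
  }, numeric(1))
}

#' Theoretical m/z of a peptide at a given charge
#'
#' @inheritParams peptide_monoisotopic_mass
#' @param charge Positive integer charge state(s).
#' @return `(monoisotopic mass + charge * proton) / charge` in Th.
#' @export
theoretical_mz <- function(peptide, charge, tables = monoisotopic_mass_tables()) {
  if (any(charge < 1)) mzqc_abort("charge must be >= 1")
  (peptide_monoisotopic_mass(peptide, tables) + charge * tables$proton) / charge
}

#' Signed precursor mass error in parts per million
#'
#' @param observed_mz,theoretical_mz Observed and theoretical m/z (Th);
#'   vectors recycle.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) mzqc_abort("theoretical m/z must be > 0")
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

#' Count missed tryptic cleavage sites in a peptide
#'
#' Number of internal positions where a residue is K or R and the following
#' residue is not P (trypsin cuts after K/R except before proline). The
#' C-terminal residue is not an internal site; bracketed modification offsets
#' are ignored.
#'
#' @param peptide Character vector of peptide strings.
#' @param cut_after,no_cut_before Cleavage rule; defaults encode trypsin.
#' @return Integer vector of missed-cleavage counts.
#' @examples
#' count_missed_cleavages(c("PEPTIDE", "ALKGR", "AKPGR"))
#' @export
count_missed_cleavages <- function(peptide, cut_after = c("K", "R"),
                                   no_cut_before = "P") {
  bare <- strip_modifications(peptide)
  pat <- sprintf("[%s](?=[^%s])", paste(cut_after, collapse = ""),
                 paste(no_cut_before, collapse = ""))
  vapply(bare, function(s) {
    if (!nzchar(s)) mzqc_abort("empty peptide sequence")
    hits <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }, integer(1), USE.NAMES = FALSE)
}

# ---- run representation -----------------------------------------------------

#' Construct an in-memory mass spectrum
#'
#' @param native_id Spectrum identifier text (e.g. `"scan=17"`).
#' @param ms_level 1 or 2.
#' @param rt_seconds Retention time in seconds (>= 0).
#' @param mz,intensity Equal-length peak arrays (m/z in Th).
#' @param precursor_mz Precursor m/z (required for MS2).
#' @param precursor_charge Optional precursor charge (MS2).
#' @param injection_time_ms Optional ion injection time in milliseconds.
#' @return An `mzqc_spectrum`.
#' @export
spectrum <- function(native_id, ms_level, rt_seconds, mz, intensity,
                     precursor_mz = NULL, precursor_charge = NULL,
                     injection_time_ms = NULL) {
  if (length(mz) != length(intensity)) {
    mzqc_abort("mz and intensity arrays must have equal length")
  }
  if (!ms_level %in% c(1L, 2L)) mzqc_abort("ms_level must be 1 or 2")
  if (rt_seconds < 0) mzqc_abort("rt_seconds must be >= 0")
  if (ms_level == 2L && is.null(precursor_mz)) {
    mzqc_abort("an MS2 spectrum requires precursor_mz")
  }
  structure(list(native_id = native_id, ms_level = as.integer(ms_level),
                 rt_seconds = as.numeric(rt_seconds),
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 precursor_mz = precursor_mz,
                 precursor_charge = precursor_charge,
                 injection_time_ms = injection_time_ms),
            class = "mzqc_spectrum")
}

#' Construct an in-memory MS run
#'
#' Spectra are stably sorted by retention time on construction.
#'
#' @param run_name Run label.
#' @param source_location Origin of the run (file path or URI).
#' @param spectra List of [spectrum()] objects.
#' @param chromatogram_count Number of chromatograms recorded with the run.
#' @return An `mzqc_run`.
#' @export
ms_run <- function(run_name, source_location, spectra, chromatogram_count = 0L) {
  stopifnot(is.list(spectra))
  if (chromatogram_count < 0) mzqc_abort("chromatogram_count must be >= 0")
  rts <- vapply(spectra, function(s) s$rt_seconds, numeric(1))
  spectra <- spectra[order(rts)] # order() is stable
  structure(list(run_name = run_name, source_location = source_location,
                 spectra = spectra,
                 chromatogram_count = as.integer(chromatogram_count)),
            class = "mzqc_run")
}

#' @export
print.mzqc_run <- function(x, ...) {
  lv <- vapply(x$spectra, function(s) s$ms_level, integer(1))
  cat(sprintf("<MS run '%s': %d MS1 + %d MS2 spectra, %d chromatogram(s)>\n",
              x$run_name, sum(lv == 1L), sum(lv == 2L), x$chromatogram_count))
  invisible(x)
}

# ---- metric packaging -------------------------------------------------------

#' Catalog of the QC metrics this package computes
#'
#' One row per metric with its toy-CV accession, name, declared value type
#' and (for tables) required column names. The toy CV shipped by the fixtures
#' module is generated from this catalog, so metric emission and semantic
#' validation cannot drift apart.
#'
#' @return A tibble with columns `accession`, `name`, `value_type`,
#'   `columns`, `unit_accession`.
#' @export
qc_metric_catalog <- function() {
  tibble::tribble(
    ~accession,    ~name,                               ~value_type,     ~columns,                   ~unit_accession,
    "QCX:0000001", "chromatogram count",                "scalar-number", "",                         NA,
    "QCX:0000002", "m/z acquisition range",             "tuple",         "",                         "QCX:1000006",
    "QCX:0000003", "retention time acquisition range",  "tuple",         "",                         "QCX:1000005",
    "QCX:0000004", "total ion chromatogram",            "table",         "rt,intensity",             NA,
    "QCX:0000005", "base peak chromatogram",            "table",         "rt,intensity",             NA,
    "QCX:0000010", "MS1 injection time summary",        "tuple",         "",                         "QCX:1000003",
    "QCX:0000011", "MS2 injection time summary",        "tuple",         "",                         "QCX:1000003",
    "QCX:0000020", "MS/MS spectrum count",              "scalar-number", "",                         NA,
    "QCX:0000021", "identified MS/MS spectrum count",   "scalar-number", "",                         NA,
    "QCX:0000022", "identified peptide count",          "scalar-number", "",                         NA,
    "QCX:0000023", "identified protein count",          "scalar-number", "",                         NA,
    "QCX:0000024", "precursor mass error distribution", "table",         "ppm",                      "QCX:1000004",
    "QCX:0000025", "precursor mass error summary",      "tuple",         "",                         "QCX:1000004",
    "QCX:0000026", "missed cleavage histogram",         "table",         "missed_cleavages,count",   NA,
    "QCX:0000027", "identified retention time range",   "tuple",         "",                         "QCX:1000005"
  )
}

qc_unit_catalog <- function() {
  tibble::tribble(
    ~accession,    ~name,
    "QCX:1000003", "millisecond",
    "QCX:1000004", "parts per million",
    "QCX:1000005", "second",
    "QCX:1000006", "Thomson"
  )
}

qc_metric <- function(accession, value) {
  catalog <- qc_metric_catalog()
  cat_row <- catalog[catalog$accession == accession, ]
  if (nrow(cat_row) != 1L) {
    mzqc_abort(sprintf("accession '%s' is not in the metric catalog", accession))
  }
  unit <- NULL
  if (!is.na(cat_row$unit_accession)) {
    units <- qc_unit_catalog()
    u <- units[units$accession == cat_row$unit_accession, ]
    unit <- mzqc_cv_param(u$accession, u$name)
  }
  kind <- switch(cat_row$value_type, "scalar-number" = , "scalar-text" = "scalar",
                 cat_row$value_type)
  mzqc_metric(accession, cat_row$name, mzqc_value(value, kind = kind), unit = unit)
}

#' Basic acquisition metrics of an MS run
#'
#' Emits the chromatogram count (scalar), the m/z range of all acquired peaks
#' and the retention-time range of all spectra (tuples `[min, max]`), the
#' total ion chromatogram (table of per-spectrum retention time and summed
#' peak intensity), and the base peak chromatogram (table of per-spectrum
#' retention time and maximum peak intensity).
#'
#' @param run An [ms_run()] with at least one spectrum.
#' @return List of `mzqc_metric` objects.
#' @export
run_basic_metrics <- function(run) {
  stopifnot(inherits(run, "mzqc_run"))
  if (length(run$spectra) == 0L) mzqc_abort("empty run")
  rts <- vapply(run$spectra, function(s) s$rt_seconds, numeric(1))
  npk <- vapply(run$spectra, function(s) length(s$mz), integer(1))
  tic <- vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
  metrics <- list(
    qc_metric("QCX:0000001", run$chromatogram_count),
    qc_metric("QCX:0000003", c(min(rts), max(rts))),
    qc_metric("QCX:0000004", tibble::tibble(rt = rts, intensity = tic))
  )
  if (any(npk > 0L)) {
    all_mz <- unlist(lapply(run$spectra, function(s) s$mz), use.names = FALSE)
    metrics <- c(metrics, list(qc_metric("QCX:0000002", c(min(all_mz), max(all_mz)))))
    has_pk <- npk > 0L
    bp <- vapply(run$spectra[has_pk], function(s) max(s$intensity), numeric(1))
    metrics <- c(metrics, list(
      qc_metric("QCX:0000005", tibble::tibble(rt = rts[has_pk], intensity = bp))))
  }
  metrics
}

#' Ion injection time statistics per MS level
#'
#' For MS1 and MS2 separately, the minimum, maximum, arithmetic mean and
#' median of the ion injection time (ms) over the spectra that carry one,
#' emitted as a tuple `[min, max, mean, median]` per level. A level with no
#' injection times yields no metric (omitted, not zero).
#'
#' @param run An [ms_run()] with at least one spectrum.
#' @return List of `mzqc_metric` objects (possibly shorter than two).
#' @export
injection_time_stats <- function(run) {
  stopifnot(inherits(run, "mzqc_run"))
  if (length(run$spectra) == 0L) mzqc_abort("empty run")
  out <- list()
  for (lvl in c(1L, 2L)) {
    it <- unlist(lapply(run$spectra, function(s) {
      if (s$ms_level == lvl && !is.null(s$injection_time_ms)) s$injection_time_ms
    }), use.names = FALSE)
    if (is.null(it) || !length(it)) next
    acc <- if (lvl == 1L) "QCX:0000010" else "QCX:0000011"
    out <- c(out, list(qc_metric(acc, c(min(it), max(it), mean(it),
                                        stats::median(it)))))
  }
  out
}

#' Identification-based QC metrics for one run
#'
#' Filters the PSM table at `q_value <= q_threshold` and emits: the MS/MS
#' spectrum count of the run; the identified MS/MS spectrum count (distinct
#' spectrum ids); the identified peptide count (distinct
#' modification-stripped sequences); the identified protein count (distinct
#' protein accessions); the precursor mass-error distribution (table with a
#' `ppm` column, one row per accepted PSM, plus a `[mean, sd, median]`
#' summary tuple); the missed-cleavage histogram (table over 0..max observed
#' count); and the identified retention-time range. With zero accepted PSMs
#' the count metrics are 0 and the distribution metrics are omitted.
#'
#' @param run An [ms_run()].
#' @param psms PSM tibble as returned by [read_psm_tsv()] (columns
#'   `spectrum_id`, `rt_seconds`, `observed_mz`, `charge`, `peptide`,
#'   `proteins` (list-column), `q_value`); every `spectrum_id` must exist in
#'   the run.
#' @param q_threshold Acceptance threshold on the table's q-value column
#'   (default 0.01, i.e. 1% FDR filtering upstream).
#' @param tables Mass tables for the theoretical m/z.
#' @return List of `mzqc_metric` objects.
#' @export
identification_metrics <- function(run, psms, q_threshold = 0.01,
                                   tables = monoisotopic_mass_tables()) {
  stopifnot(inherits(run, "mzqc_run"), is.data.frame(psms))
  if (q_threshold <= 0 || q_threshold > 1) {
    mzqc_abort("q_threshold must be in (0, 1]")
  }
  spec_ids <- vapply(run$spectra, function(s) s$native_id, character(1))
  unknown <- setdiff(psms$spectrum_id, spec_ids)
  if (length(unknown)) {
    mzqc_abort(sprintf("PSMs reference unknown spectrum ids: %s",
                       paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  n_ms2 <- sum(vapply(run$spectra, function(s) s$ms_level, integer(1)) == 2L)
  acc <- dplyr::filter(psms, .data$q_value <= q_threshold)
  metrics <- list(
    qc_metric("QCX:0000020", n_ms2),
    qc_metric("QCX:0000021", dplyr::n_distinct(acc$spectrum_id)),
    qc_metric("QCX:0000022", dplyr::n_distinct(strip_modifications(acc$peptide))),
    qc_metric("QCX:0000023", dplyr::n_distinct(unlist(acc$proteins)))
  )
  if (nrow(acc) == 0L) return(metrics)
  ppm <- ppm_error(acc$observed_mz, theoretical_mz(acc$peptide, acc$charge, tables))
  mc <- count_missed_cleavages(acc$peptide)
  mc_levels <- 0L:max(mc)
  mc_counts <- vapply(mc_levels, function(k) sum(mc == k), integer(1))
  sd_ppm <- if (length(ppm) > 1L) stats::sd(ppm) else 0
  c(metrics, list(
    qc_metric("QCX:0000024", tibble::tibble(ppm = ppm)),
    qc_metric("QCX:0000025", c(mean(ppm), sd_ppm, stats::median(ppm))),
    qc_metric("QCX:0000026", tibble::tibble(missed_cleavages = mc_levels,
                                            count = mc_counts)),
    qc_metric("QCX:0000027", c(min(acc$rt_seconds), max(acc$rt_seconds)))
  ))
}

#' Package a run's metrics as a runQuality element
#'
#' @param run An [ms_run()].
#' @param metrics List of `mzqc_metric` objects for this run.
#' @param software Optional list of [mzqc_analysis_software()]; defaults to
#'   this package.
#' @return An `mzqc_quality_element` of kind `"run"`.
#' @export
run_quality_from_metrics <- function(run, metrics, software = NULL) {
  software <- software %||% list(default_software())
  md <- mzqc_metadata(
    inputFiles = list(mzqc_input_file(run$run_name, run$source_location)),
    analysisSoftware = software)
  mzqc_run_quality(md, metrics)
}

default_software <- function() {
  mzqc_analysis_software("QCX:1000001", "mzqckit",
                         as.character(utils::packageVersion("mzqckit")))
}

default_cv_references <- function() {
  list(mzqc_cv_reference(
    name = "Toy Quality Control Vocabulary (QCX)",
    uri = "file:///qcx_toy_cv.obo", version = "0.1"))
}
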