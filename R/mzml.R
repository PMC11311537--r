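# Optional mzML support. Reading delegates to the Bioconductor mzR parser
# (Suggests); the package's own run representation stays the primary input.
# A minimal uncompressed mzML writer is provided so reader round-trips can
# be exercised without raw data.

#' Read an MS run from an mzML file
#'
#' Delegates parsing to mzR and maps each spectrum to the package's
#' [spectrum()] representation: MS level, scan start time (converted to
#' seconds), precursor m/z and charge, ion injection time (ms), and the peak
#' arrays; the file's chromatogram count is carried onto the run.
#'
#' @param path Path to an mzML file.
#' @param run_name Run label; defaults to the file name without extension.
#' @return An [ms_run()].
#' @export
read_run_mzml <- function(path, run_name = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    mzqc_abort("reading mzML requires the mzR package")
  }
  if (!file.exists(path)) {
    mzqc_abort(sprintf("cannot read mzML file '%s'", path), class = "mzqc_io_error")
  }
  run_name <- run_name %||% sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hd <- mzR::header(handle)
  n_chrom <- tryCatch(mzR::nChrom(handle), error = function(e) 0L)
  spectra <- lapply(seq_len(nrow(hd)), function(i) {
    pk <- mzR::peaks(handle, i)
    lvl <- hd$msLevel[i]
    inj <- hd$injectionTime[i]
    spectrum(
      native_id = as.character(hd$spectrumId[i]), ms_level = lvl,
      rt_seconds = hd$retentionTime[i], # mzR reports seconds
      mz = pk[, 1], intensity = pk[, 2],
      precursor_mz = if (lvl >= 2L) hd$precursorMZ[i] else NULL,
      precursor_charge = if (lvl >= 2L && !is.na(hd$precursorCharge[i]) &&
                             hd$precursorCharge[i] > 0L)
        hd$precursorCharge[i] else NULL,
      injection_time_ms = if (!is.na(inj) && inj > 0) inj else NULL)
  })
  ms_run(run_name, path, spectra, n_chrom)
}

b64_doubles <- function(x) {
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8L,
                                               endian = "little")), fixed = TRUE)
}

mzml_binary_array <- function(values, array_cv, array_name) {
  enc <- b64_doubles(values)
  paste0(
    '<binaryDataArray encodedLength="', nchar(enc), '">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="MS" accession="', array_cv, '" name="', array_name, '"/>',
    '<binary>', enc, '</binary></binaryDataArray>')
}

mzml_spectrum_xml <- function(s, index) {
  lvl_param <- if (s$ms_level == 1L) {
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum"/>'
  }
  inj <- if (!is.null(s$injection_time_ms)) {
    sprintf(paste0('<cvParam cvRef="MS" accession="MS:1000927" name="ion injection time" ',
                   'value="%.6f" unitCvRef="UO" unitAccession="UO:0000028" ',
                   'unitName="millisecond"/>'), s$injection_time_ms)
  } else ""
  precursor <- ""
  if (s$ms_level == 2L) {
    charge <- if (!is.null(s$precursor_charge)) {
      sprintf('<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
              as.integer(s$precursor_charge))
    } else ""
    precursor <- paste0(
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.8f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
              s$precursor_mz),
      charge,
      '</selectedIon></selectedIonList><activation/></precursor></precursorList>')
  }
  paste0(
    sprintf('<spectrum index="%d" id="%s" defaultArrayLength="%d">',
            index, s$native_id, length(s$mz)),
    lvl_param,
    sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
            s$ms_level),
    '<scanList count="1"><scan>',
    sprintf(paste0('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" ',
                   'value="%.6f" unitCvRef="UO" unitAccession="UO:0000010" ',
                   'unitName="second"/>'), s$rt_seconds),
    inj,
    '</scan></scanList>',
    precursor,
    '<binaryDataArrayList count="2">',
    mzml_binary_array(s$mz, "MS:1000514", "m/z array"),
    mzml_binary_array(s$intensity, "MS:1000515", "intensity array"),
    '</binaryDataArrayList></spectrum>')
}

#' Write a minimal mzML file from an in-memory run
#'
#' Uncompressed 64-bit peak arrays, scan start times in seconds, ion
#' injection times, and MS2 precursor information — just enough of the
#' standard to exercise [read_run_mzml()] round-trips. Not a general-purpose
#' mzML exporter.
#'
#' @param run An [ms_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_minimal_mzml <- function(run, path) {
  stopifnot(inherits(run, "mzqc_run"))
  spectra_xml <- vapply(seq_along(run$spectra), function(i)
    mzml_spectrum_xml(run$spectra[[i]], i - 1L), character(1))
  xml <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UO" URI="http://ontologies.berkeleybop.org/uo.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="mzqckit" version="0.1.0"/></softwareList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="mzqckit">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC1">', run$run_name),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">',
            length(run$spectra)),
    spectra_xml,
    '</spectrumList></run></mzML>')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}
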