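# Metric computation: peptide math, cleavage counting, run metrics,
# identification metrics. Oracles are deliberately written as plain loops.

metric_by_accession <- function(metrics, accession) {
  for (m in metrics) if (m$accession == accession) return(m$value$data)
  NULL
}

test_that("peptide monoisotopic masses follow the residue tables", {
  tables <- monoisotopic_mass_tables()
  expect_equal(peptide_monoisotopic_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(peptide_monoisotopic_mass("GG") - peptide_monoisotopic_mass("G"),
               tables$residues[["G"]], tolerance = 1e-9)
  expect_equal(peptide_monoisotopic_mass("PEPTM[+15.9949]IDE"),
               peptide_monoisotopic_mass("PEPTMIDE") + 15.9949,
               tolerance = 1e-9)
  expect_error(peptide_monoisotopic_mass(""), "empty peptide")
  expect_error(peptide_monoisotopic_mass("PEZTIDE"), "position 3")
})

test_that("theoretical m/z follows the charge formula and is monotone", {
  tables <- monoisotopic_mass_tables()
  M <- peptide_monoisotopic_mass("PEPTIDEK")
  expect_equal(theoretical_mz("PEPTIDEK", 1), M + 1.00728, tolerance = 1e-5)
  expect_equal(theoretical_mz("PEPTIDEK", 2), (M + 2 * tables$proton) / 2,
               tolerance = 1e-12)
  expect_true(theoretical_mz("PEPTIDEK", 1) > theoretical_mz("PEPTIDEK", 2))
  expect_error(theoretical_mz("PEPTIDEK", 0), "charge")
})

test_that("ppm errors are signed relative deviations times 1e6", {
  expect_equal(ppm_error(1000.010, 1000.000), 10, tolerance = 1e-9)
  expect_identical(ppm_error(500, 500), 0)
  d <- 0.037
  expect_equal(ppm_error(1000 - d, 1000), 1e6 * (-d) / 1000, tolerance = 1e-12)
  expect_equal(ppm_error(1000 + d, 1000), 1e6 * d / 1000, tolerance = 1e-12)
  expect_error(ppm_error(500, 0), "> 0")
})

test_that("missed-cleavage counting encodes the trypsin rule", {
  expect_identical(count_missed_cleavages("PEPTIDE"), 0L)
  expect_identical(count_missed_cleavages("ALKGR"), 1L)
  expect_identical(count_missed_cleavages("AKPGR"), 0L) # K before P suppressed
  expect_identical(count_missed_cleavages("KKKK"), 3L)
  expect_identical(count_missed_cleavages("RPRPRP"), 0L)
  expect_identical(count_missed_cleavages("AK[+42.01]GR"), 1L)
})

test_that("missed-cleavage counter agrees with a site-enumeration oracle", {
  oracle <- function(pep) {
    res <- strsplit(pep, "", fixed = TRUE)[[1]]
    n <- length(res)
    hits <- 0L
    for (i in seq_len(max(n - 1L, 0L))) {
      if (res[i] %in% c("K", "R") && res[i + 1L] != "P") hits <- hits + 1L
    }
    hits
  }
  set.seed(77)
  # K, R, P enriched so suppression cases actually occur
  alphabet <- c(names(monoisotopic_mass_tables()$residues), "K", "R", "P", "P")
  peps <- vapply(1:500, function(i)
    paste(sample(alphabet, sample(6:25, 1), replace = TRUE), collapse = ""),
    character(1))
  expect_identical(count_missed_cleavages(peps),
                   vapply(peps, oracle, integer(1), USE.NAMES = FALSE))
})

test_that("basic metrics of a one-peak run match by hand", {
  run <- ms_run("r", "file:///r", list(
    spectrum("scan=1", 1L, 12.5, mz = 500, intensity = 7)),
    chromatogram_count = 0L)
  m <- run_basic_metrics(run)
  expect_identical(metric_by_accession(m, "QCX:0000001"), 0L)
  expect_equal(unlist(metric_by_accession(m, "QCX:0000002")), c(500, 500))
  expect_equal(unlist(metric_by_accession(m, "QCX:0000003")), c(12.5, 12.5))
  expect_equal(metric_by_accession(m, "QCX:0000004")$intensity, 7)
  expect_equal(metric_by_accession(m, "QCX:0000005")$intensity, 7)
  expect_error(run_basic_metrics(ms_run("e", "l", list())), "empty run")
})

test_that("TIC equals a per-spectrum summation oracle, exactly for integers", {
  set.seed(5)
  spectra <- lapply(1:20, function(i) {
    n <- sample(3:12, 1)
    spectrum(sprintf("scan=%d", i), 1L, i * 10,
             mz = sort(runif(n, 100, 1500)),
             intensity = as.numeric(sample(1:1000, n, replace = TRUE)))
  })
  run <- ms_run("r", "file:///r", spectra, 2L)
  tic <- metric_by_accession(run_basic_metrics(run), "QCX:0000004")
  oracle <- vapply(run$spectra, function(s) {
    acc <- 0
    for (v in s$intensity) acc <- acc + v
    acc
  }, numeric(1))
  expect_identical(tic$intensity, oracle)
})

test_that("injection-time summaries are [min, max, mean, median] per level", {
  mk <- function(times, lvl = 2L) {
    lapply(seq_along(times), function(i)
      spectrum(sprintf("s%d", i), lvl, i, mz = 500, intensity = 1,
               precursor_mz = if (lvl == 2L) 500 else NULL,
               injection_time_ms = times[i]))
  }
  run <- ms_run("r", "l", mk(c(10, 20, 30)))
  m <- injection_time_stats(run)
  expect_length(m, 1L) # no MS1 carries an injection time -> omitted
  expect_equal(unlist(metric_by_accession(m, "QCX:0000011")), c(10, 30, 20, 20))
  run2 <- ms_run("r", "l", mk(rep(4.2, 5)))
  expect_equal(unlist(metric_by_accession(injection_time_stats(run2),
                                          "QCX:0000011")), rep(4.2, 4))
})

test_that("injection statistics match a sorting oracle on a seeded run", {
  exp <- small_experiment()
  run <- exp$runs[[2]]
  m <- injection_time_stats(run)
  for (lvl in 1:2) {
    times <- unlist(lapply(run$spectra, function(s)
      if (s$ms_level == lvl) s$injection_time_ms))
    s <- sort(times)
    n <- length(s)
    oracle <- c(s[1], s[n], sum(s) / n, (s[(n + 1) %/% 2] + s[n %/% 2 + 1]) / 2)
    acc <- if (lvl == 1) "QCX:0000010" else "QCX:0000011"
    got <- unlist(metric_by_accession(m, acc))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("identification metrics respect the q-value threshold", {
  run <- ms_run("r", "l", list(
    spectrum("scan=1", 2L, 100, mz = 500, intensity = 1, precursor_mz = 450)))
  psms <- tibble::tibble(
    spectrum_id = "scan=1", rt_seconds = 100,
    observed_mz = theoretical_mz("PEPTIDEK", 2L), charge = 2L,
    peptide = "PEPTIDEK", proteins = list("P1"), q_value = 1.0)
  m <- identification_metrics(run, psms, q_threshold = 0.01)
  expect_identical(metric_by_accession(m, "QCX:0000020"), 1L)
  expect_identical(metric_by_accession(m, "QCX:0000021"), 0L)
  expect_identical(metric_by_accession(m, "QCX:0000022"), 0L)
  expect_null(metric_by_accession(m, "QCX:0000024")) # distributions omitted

  psms$q_value <- 0.001
  m2 <- identification_metrics(run, psms)
  expect_equal(metric_by_accession(m2, "QCX:0000024")$ppm, 0)
  expect_equal(unlist(metric_by_accession(m2, "QCX:0000027")), c(100, 100))

  psms$spectrum_id <- "scan=99"
  expect_error(identification_metrics(run, psms), "unknown spectrum ids")
})

test_that("identification counts satisfy their ordering invariants", {
  exp <- small_experiment()
  for (nm in names(exp$runs)[1:3]) {
    m <- identification_metrics(exp$runs[[nm]], exp$psms[[nm]])
    n_ms2 <- metric_by_accession(m, "QCX:0000020")
    n_id <- metric_by_accession(m, "QCX:0000021")
    n_pep <- metric_by_accession(m, "QCX:0000022")
    expect_lte(n_id, n_ms2)
    expect_lte(n_pep, n_id)
    mc <- metric_by_accession(m, "QCX:0000026")
    expect_identical(sum(mc$count), n_id)
  }
})
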