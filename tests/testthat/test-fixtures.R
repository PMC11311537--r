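# Synthetic-experiment generator and fixture catalog.

test_that("generation is deterministic given the seed", {
  spec <- experiment_spec(n_runs = 2L, conditions = c("DMSO", "SUF"),
                          ms1_per_run = 5L, ms2_per_ms1 = 3L, seed = 9L)
  e1 <- generate_experiment(spec)
  e2 <- generate_experiment(spec)
  expect_identical(e1, e2)
  e3 <- generate_experiment(experiment_spec(
    n_runs = 2L, conditions = c("DMSO", "SUF"), ms1_per_run = 5L,
    ms2_per_ms1 = 3L, seed = 10L))
  expect_false(identical(e1$psms, e3$psms))
})

test_that("id_rate zero yields empty PSM tables", {
  spec <- experiment_spec(n_runs = 1L, conditions = "DMSO", ms1_per_run = 5L,
                          ms2_per_ms1 = 2L, id_rate = 0, decoy_rate = 0,
                          seed = 4L)
  exp <- generate_experiment(spec)
  expect_identical(nrow(exp$psms[[1]]), 0L)
  expect_identical(exp$truth[[1]]$n_identified_msms, 0)
})

test_that("invalid specs are rejected", {
  expect_error(experiment_spec(missed_cleavage_probs = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(experiment_spec(n_runs = 3L), "one label per run")
  expect_error(experiment_spec(ms1_per_run = 0L), "positive")
  expect_error(experiment_spec(id_rate = 1.5), "id_rate")
})

test_that("generated ppm errors recover the generating mean (law of large numbers)", {
  spec <- experiment_spec(n_runs = 1L, conditions = "DMSO",
                          ms1_per_run = 200L, ms2_per_ms1 = 5L,
                          id_rate = 1, decoy_rate = 0, seed = 21L)
  exp <- generate_experiment(spec)
  n <- length(exp$truth[[1]]$ppm_sample)
  expect_identical(n, 1000L)
  expect_lt(abs(mean(exp$truth[[1]]$ppm_sample) - spec$ppm_mu),
            4 * spec$ppm_sigma / sqrt(n))
})

test_that("the fixture catalog has the documented shape", {
  ids <- fixture_case_ids()
  expect_gte(sum(ids$stage == "valid"), 20L)
  expect_gte(sum(ids$stage == "syntax"), 8L)
  expect_gte(sum(ids$stage == "semantic"), 7L)
  expect_error(generate_mzqc_fixture("no-such-case"), "unknown fixture case")
})

test_that("valid fixture cases read back as valid documents", {
  case <- generate_mzqc_fixture("valid-01")
  expect_identical(case$stage, "valid")
  doc <- read_mzqc(case$text)
  expect_s3_class(doc, "mzqc_document")
  expect_true(validate_mzqc_syntax(case$text)$valid)
})

test_that("the PSM TSV and run JSON round-trip through files", {
  exp <- small_experiment()
  psm_path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_tsv(exp$psms[[1]], psm_path)
  back <- read_psm_tsv(psm_path)
  expect_identical(back$peptide, exp$psms[[1]]$peptide)
  expect_identical(back$proteins, exp$psms[[1]]$proteins)
  expect_equal(back$observed_mz, exp$psms[[1]]$observed_mz, tolerance = 1e-12)

  run_path <- withr::local_tempfile(fileext = ".json")
  write_run_json(exp$runs[[1]], run_path)
  run_back <- read_run_json(run_path)
  expect_identical(length(run_back$spectra), length(exp$runs[[1]]$spectra))
  expect_identical(run_back$spectra[[5]]$mz, exp$runs[[1]]$spectra[[5]]$mz)
  expect_identical(run_back$spectra[[5]]$injection_time_ms,
                   exp$runs[[1]]$spectra[[5]]$injection_time_ms)
})

test_that("the written corpus contains runs, PSMs, CV and mzQC cases", {
  dir <- withr::local_tempdir()
  spec <- experiment_spec(n_runs = 2L, conditions = c("DMSO", "SUF"),
                          ms1_per_run = 4L, ms2_per_ms1 = 2L, seed = 2L)
  paths <- write_fixture_corpus(dir, spec)
  expect_length(paths$runs, 2L)
  expect_true(all(file.exists(paths$runs)))
  expect_true(all(file.exists(paths$psms)))
  expect_true(file.exists(paths$cv))
  expect_gte(length(paths$mzqc), 35L)
  store <- read_obo(paths$cv)
  expect_s3_class(store, "mzqc_cv_store")
})
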