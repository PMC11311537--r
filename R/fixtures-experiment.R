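# Seeded generator of a synthetic two-condition DDA experiment with exact
# ground truth: a toy proteome is digested tryptically, runs of MS1/MS2
# spectra are drawn, and PSM tables are emitted whose counts, mass errors,
# and missed-cleavage composition are known by construction. Everything is
# deterministic given the spec's seed; the ground truth is bookkept during
# generation with plain arithmetic, independent of the metrics module.

with_seed_local <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic QC experiment
#'
#' The defaults emulate the shape of an 8-run, two-condition (DMSO control
#' vs sulforaphane) DDA study at desk scale: four replicates per condition,
#' a 7200 s (120 min) gradient, 400 MS1 scans each followed by 5
#' data-dependent MS2 scans, log-normal peak intensities, normally
#' distributed ion injection times per MS level, precursor mass errors drawn
#' from N(mu = 2 ppm, sigma = 3 ppm), tryptic peptides with up to three
#' missed cleavages, and half of the MS2 spectra identified at q <= 0.01.
#'
#' @param n_runs Number of runs.
#' @param conditions Condition label per run.
#' @param ms1_per_run MS1 spectra per run.
#' @param ms2_per_ms1 MS2 spectra triggered per MS1.
#' @param gradient_seconds Gradient length (s).
#' @param peak_count_lambda Poisson mean of (peaks - 1) per spectrum.
#' @param intensity_meanlog,intensity_sdlog Log-normal peak intensity
#'   parameters.
#' @param injection_ms1_mean,injection_ms1_sd,injection_ms2_mean,injection_ms2_sd
#'   Normal injection-time parameters (ms) per MS level.
#' @param ppm_mu,ppm_sigma Normal precursor mass-error parameters (ppm).
#' @param missed_cleavage_probs Probabilities of 0..3 missed cleavages
#'   (must sum to 1).
#' @param id_rate Fraction of MS2 spectra identified (q below threshold).
#' @param decoy_rate Fraction of unidentified MS2 spectra that still yield a
#'   high-q PSM row (exercises q-value filtering).
#' @param mod_prob Probability that an identified peptide carries a
#'   methionine oxidation written as a bracketed mass offset.
#' @param n_proteins,protein_length Toy proteome size.
#' @param seed Integer seed governing every random draw.
#' @return An `mzqc_experiment_spec` list.
#' @export
experiment_spec <- function(n_runs = 8L,
                            conditions = rep(c("DMSO", "SUF"), each = 4L),
                            ms1_per_run = 400L, ms2_per_ms1 = 5L,
                            gradient_seconds = 7200,
                            peak_count_lambda = 40,
                            intensity_meanlog = 12, intensity_sdlog = 1,
                            injection_ms1_mean = 5, injection_ms1_sd = 1,
                            injection_ms2_mean = 25, injection_ms2_sd = 5,
                            ppm_mu = 2, ppm_sigma = 3,
                            missed_cleavage_probs = c(0.7, 0.2, 0.08, 0.02),
                            id_rate = 0.5, decoy_rate = 0.1, mod_prob = 0.15,
                            n_proteins = 50L, protein_length = 200L,
                            seed = 42L) {
  spec <- structure(as.list(environment()), class = "mzqc_experiment_spec")
  if (length(spec$conditions) != spec$n_runs) {
    mzqc_abort("conditions must have one label per run")
  }
  if (abs(sum(spec$missed_cleavage_probs) - 1) > 1e-12) {
    mzqc_abort("missed_cleavage_probs must sum to 1")
  }
  for (f in c("n_runs", "ms1_per_run", "ms2_per_ms1", "gradient_seconds",
              "peak_count_lambda", "n_proteins", "protein_length")) {
    if (spec[[f]] <= 0) mzqc_abort(sprintf("%s must be positive", f))
  }
  if (spec$id_rate < 0 || spec$id_rate > 1) mzqc_abort("id_rate must be in [0, 1]")
  spec
}

# fully tryptic digest of one protein; returns peptides with 0..max_mc
# retained internal sites, length-filtered
digest_tryptic <- function(sequence, max_mc = 3L, min_len = 6L, max_len = 30L) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cuts <- which(res[-n] %in% c("K", "R") & res[-1] != "P")
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  k <- length(starts)
  out_pep <- character()
  out_mc <- integer()
  for (i in seq_len(k)) {
    for (j in i:min(k, i + max_mc)) {
      len <- ends[j] - starts[i] + 1L
      if (len < min_len || len > max_len) next
      out_pep <- c(out_pep, substr(sequence, starts[i], ends[j]))
      out_mc <- c(out_mc, j - i)
    }
  }
  tibble::tibble(peptide = out_pep, n_missed = out_mc)
}

toy_proteome <- function(n_proteins, protein_length) {
  aa <- names(monoisotopic_mass_tables()$residues)
  proteins <- tibble::tibble(
    accession = sprintf("PROT%03d", seq_len(n_proteins)),
    sequence = vapply(seq_len(n_proteins), function(i)
      paste(sample(aa, protein_length, replace = TRUE), collapse = ""),
      character(1)))
  peptides <- purrr::map2_dfr(proteins$accession, proteins$sequence,
                              function(acc, s) {
    dplyr::mutate(digest_tryptic(s), protein = acc)
  })
  peptides <- peptides |>
    dplyr::group_by(.data$peptide, .data$n_missed) |>
    dplyr::summarise(proteins = list(unique(.data$protein)), .groups = "drop")
  list(proteins = proteins, peptides = peptides)
}

sorted_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  (s[(n + 1L) %/% 2L] + s[n %/% 2L + 1L]) / 2
}

generate_one_run <- function(spec, run_idx, peptide_pool, tables) {
  cond <- spec$conditions[run_idx]
  rep_idx <- sum(spec$conditions[seq_len(run_idx)] == cond)
  run_name <- sprintf("Ecoli_%s_rep%d", cond, rep_idx)
  n_ms1 <- spec$ms1_per_run
  k <- spec$ms2_per_ms1
  n_total <- n_ms1 * (1L + k)
  rts <- sort(stats::runif(n_total, 0, spec$gradient_seconds))
  levels <- rep(c(1L, rep(2L, k)), n_ms1)
  ms2_idx <- which(levels == 2L)
  n_ms2 <- length(ms2_idx)

  n_id <- round(spec$id_rate * n_ms2)
  id_slots <- sort(sample(ms2_idx, n_id))

  # peptide draws for identified MS2
  mc_draw <- sample(0:3, n_id, replace = TRUE, prob = spec$missed_cleavage_probs)
  pool_by_mc <- split(seq_len(nrow(peptide_pool)), peptide_pool$n_missed)
  psm_rows <- vector("list", n_id)
  ppm_draw <- stats::rnorm(n_id, spec$ppm_mu, spec$ppm_sigma)
  for (i in seq_len(n_id)) {
    mc <- mc_draw[i]
    while (is.null(pool_by_mc[[as.character(mc)]])) mc <- mc - 1L
    row <- peptide_pool[sample(pool_by_mc[[as.character(mc)]], 1L), ]
    pep <- row$peptide
    if (grepl("M", pep) && stats::runif(1) < spec$mod_prob) {
      pep <- sub("M", "M[+15.9949]", pep)
    }
    z <- sample(2:3, 1L)
    theo <- theoretical_mz(pep, z, tables)
    obs <- theo * (1 + ppm_draw[i] * 1e-6)
    psm_rows[[i]] <- tibble::tibble(
      slot = id_slots[i], peptide = pep, bare = row$peptide,
      proteins = list(row$proteins[[1]]), charge = z, observed_mz = obs,
      n_missed = mc_draw[i], ppm = ppm_draw[i],
      q_value = stats::runif(1, 0, 0.0099))
  }
  id_tbl <- if (n_id) dplyr::bind_rows(psm_rows) else NULL

  # decoy PSMs on unidentified MS2 (filtered out at the default threshold)
  free_ms2 <- setdiff(ms2_idx, id_slots)
  n_decoy <- round(spec$decoy_rate * length(free_ms2))
  decoy_slots <- if (n_decoy) sort(sample(free_ms2, n_decoy)) else integer()

  spectra <- vector("list", n_total)
  tic <- numeric(n_total)
  bp <- numeric(n_total)
  mz_min <- Inf; mz_max <- -Inf
  inj <- list(`1` = numeric(), `2` = numeric())
  precursor <- rep(NA_real_, n_total)
  precursor[id_slots] <- if (n_id) id_tbl$observed_mz else numeric()
  charge_vec <- rep(NA_integer_, n_total)
  charge_vec[id_slots] <- if (n_id) id_tbl$charge else integer()

  for (s in seq_len(n_total)) {
    npk <- stats::rpois(1, spec$peak_count_lambda) + 1L
    mz <- sort(stats::runif(npk, 100, 1500))
    inten <- stats::rlnorm(npk, spec$intensity_meanlog, spec$intensity_sdlog)
    lvl <- levels[s]
    it <- if (lvl == 1L) {
      stats::rnorm(1, spec$injection_ms1_mean, spec$injection_ms1_sd)
    } else {
      stats::rnorm(1, spec$injection_ms2_mean, spec$injection_ms2_sd)
    }
    it <- max(it, 0.1)
    inj[[as.character(lvl)]] <- c(inj[[as.character(lvl)]], it)
    prec <- NULL; prec_z <- NULL
    if (lvl == 2L) {
      prec <- if (!is.na(precursor[s])) precursor[s] else stats::runif(1, 400, 1200)
      prec_z <- if (!is.na(charge_vec[s])) charge_vec[s] else sample(2:3, 1L)
    }
    spectra[[s]] <- spectrum(
      native_id = sprintf("scan=%d", s), ms_level = lvl, rt_seconds = rts[s],
      mz = mz, intensity = inten, precursor_mz = prec,
      precursor_charge = prec_z, injection_time_ms = it)
    tic[s] <- sum(inten)
    bp[s] <- max(inten)
    mz_min <- min(mz_min, mz[1]); mz_max <- max(mz_max, mz[npk])
  }
  chrom_count <- sample(1:3, 1L)
  run <- ms_run(run_name, sprintf("file:///data/%s.mzML", run_name),
                spectra, chrom_count)

  psms <- tibble::tibble(spectrum_id = character(), rt_seconds = numeric(),
                         observed_mz = numeric(), charge = integer(),
                         peptide = character(), proteins = list(),
                         q_value = numeric())
  if (n_id) {
    psms <- tibble::tibble(
      spectrum_id = sprintf("scan=%d", id_tbl$slot),
      rt_seconds = rts[id_tbl$slot], observed_mz = id_tbl$observed_mz,
      charge = id_tbl$charge, peptide = id_tbl$peptide,
      proteins = id_tbl$proteins, q_value = id_tbl$q_value)
  }
  if (length(decoy_slots)) {
    decoy_pep <- peptide_pool$peptide[sample(nrow(peptide_pool),
                                             length(decoy_slots), replace = TRUE)]
    psms <- dplyr::bind_rows(psms, tibble::tibble(
      spectrum_id = sprintf("scan=%d", decoy_slots),
      rt_seconds = rts[decoy_slots],
      observed_mz = vapply(decoy_slots, function(s)
        spectra[[s]]$precursor_mz, numeric(1)),
      charge = vapply(decoy_slots, function(s)
        as.integer(spectra[[s]]$precursor_charge), integer(1)),
      peptide = decoy_pep,
      proteins = lapply(seq_along(decoy_slots), function(i) "DECOY"),
      q_value = stats::runif(length(decoy_slots), 0.2, 1)))
    psms <- psms[order(psms$rt_seconds), ]
  }

  inj_stats <- function(x) {
    if (!length(x)) return(NULL)
    c(min(x), max(x), sum(x) / length(x), sorted_median(x))
  }
  truth <- list(
    run_name = run_name,
    chromatogram_count = chrom_count,
    n_ms2 = n_ms2,
    n_identified_msms = n_id,
    n_peptides = if (n_id) length(unique(id_tbl$bare)) else 0L,
    n_proteins = if (n_id) length(unique(unlist(id_tbl$proteins))) else 0L,
    mz_range = c(mz_min, mz_max),
    rt_range = c(rts[1], rts[n_total]),
    tic = tibble::tibble(rt = rts, intensity = tic),
    base_peak = tibble::tibble(rt = rts, intensity = bp),
    injection_ms1 = inj_stats(inj[["1"]]),
    injection_ms2 = inj_stats(inj[["2"]]),
    ppm_sample = if (n_id) id_tbl$ppm else numeric(),
    mc_hist = if (n_id) {
      lev <- 0L:max(id_tbl$n_missed)
      tibble::tibble(missed_cleavages = lev,
                     count = vapply(lev, function(v) sum(id_tbl$n_missed == v),
                                    integer(1)))
    } else NULL,
    rt_range_identified = if (n_id) range(rts[id_tbl$slot]) else NULL)
  list(run = run, psms = psms, truth = truth, condition = cond)
}

#' Generate a synthetic experiment with ground truth
#'
#' Deterministic given `spec$seed`: re-running with the same spec reproduces
#' identical runs, PSM tables, and ground truth. Every ground-truth quantity
#' is recomputable from the emitted objects by the metrics module — exactly
#' for counts, to floating-point accuracy for continuous summaries.
#'
#' @param spec An [experiment_spec()].
#' @return List with `runs` (named list of [ms_run()]), `psms` (named list
#'   of PSM tibbles), `truth` (named list of per-run ground-truth records),
#'   `conditions` (named character vector run -> condition), and the
#'   `peptide_pool` used for sampling.
#' @export
generate_experiment <- function(spec = experiment_spec()) {
  stopifnot(inherits(spec, "mzqc_experiment_spec"))
  tables <- monoisotopic_mass_tables()
  with_seed_local(spec$seed, {
    pool <- toy_proteome(spec$n_proteins, spec$protein_length)$peptides
    per_run <- lapply(seq_len(spec$n_runs), function(r)
      generate_one_run(spec, r, pool, tables))
    names(per_run) <- vapply(per_run, function(x) x$truth$run_name, character(1))
    list(
      runs = lapply(per_run, function(x) x$run),
      psms = lapply(per_run, function(x) x$psms),
      truth = lapply(per_run, function(x) x$truth),
      conditions = vapply(per_run, function(x) x$condition, character(1)),
      peptide_pool = pool
    )
  })
}
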