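test_that("workflow config files parse with defaults and validation", {
  p <- tempfile()
  writeLines(character(0), p)
  cfg <- load_workflow(p)
  expect_equal(cfg$precursor_tol_ppm, 30)
  expect_equal(cfg$product_tol_ppm, 10)
  expect_equal(cfg$max_glycans, 5)
  expect_equal(cfg$oxonium_min_intensity, 0.05)
  expect_equal(cfg$prob_threshold, 0.75)
  expect_equal(cfg$fdr, 0.01)

  writeLines(c("# comment", "precursor_tol_ppm=20"), p)
  cfg <- load_workflow(p)
  expect_equal(cfg$precursor_tol_ppm, 20)
  expect_equal(cfg$product_tol_ppm, 10)

  writeLines(c("precursor_tol_ppm=20", "precursor_tol_ppm=25"), p)
  expect_error(load_workflow(p), "duplicate")
  writeLines("not_a_key=1", p)
  expect_error(load_workflow(p), "unknown key")
  writeLines("just a line", p)
  expect_error(load_workflow(p), "key=value")
  # CLI-style overrides win over file values
  writeLines("precursor_tol_ppm=20", p)
  cfg <- load_workflow(p, overrides = list(precursor_tol_ppm = 12))
  expect_equal(cfg$precursor_tol_ppm, 12)
})

test_that("missing inputs abort before any compute", {
  cfg <- load_workflow(NULL, overrides = list(
    run_file = tempfile(), fasta = tempfile(), glycan_db = tempfile()))
  expect_error(run_workflow(cfg, verbose = FALSE), "does not exist")
  cfg2 <- load_workflow(NULL)
  expect_error(run_workflow(cfg2, verbose = FALSE), "required")
})

test_that("end-to-end workflow recovers simulated glycopeptides", {
  scfg <- sim_config(seed = 31, n_glycopeptides = 25)
  run_path <- tempfile(fileext = ".mgf")
  sim <- simulate_run(scfg, run_path)
  outdir <- tempfile()
  cfg <- load_workflow(NULL, overrides = list(
    run_file = run_path, fasta = sim$fasta, glycan_db = scfg$glycan_db,
    output_dir = outdir, specificity = "full", max_missed_cleavages = 0,
    min_peptide_length = 7, max_peptide_length = 22, variable_mods = "none",
    max_glycans = 3))
  res <- suppressWarnings(run_workflow(cfg, verbose = FALSE))
  expect_true(file.exists(res$psm_path))
  expect_true(file.exists(res$site_path))
  psms <- read_psm_table(res$psm_path)
  truth <- sim$truth
  m <- match(psms$spectrum_id, truth$hcd_scan)
  matched <- !is.na(m)
  expect_gt(sum(matched), 0.9 * nrow(truth))
  expect_gt(mean(psms$peptide[matched] == truth$peptide[m[matched]]), 0.95)
  # delta mass within precursor tolerance of a box mass for glyco PSMs
  glyco <- psms$n_glycans > 0
  expect_true(all(abs(psms$delta_mass[glyco] -
                      psms$total_glycan_mass[glyco]) < 0.1))
  # localization strings parse back to the planted assignment mostly
  both <- matched & psms$peptide == truth$peptide[m] &
    psms$localization_level %in% c("1", "1b")
  agree <- psms$site_assignments[both] == truth$site_assignment[m[both]]
  expect_gt(mean(agree), 0.9)
})

test_that("single-scan mode localizes on the identification scan itself", {
  scfg <- sim_config(seed = 41, n_glycopeptides = 12)
  run_path <- tempfile(fileext = ".mgf")
  sim <- simulate_run(scfg, run_path)
  # strip all EThcD scans: an HCD-only run
  hcd_only <- Filter(function(s) s$ms_level == 1L || s$activation == "HCD",
                     sim$run)
  run2 <- tempfile(fileext = ".mgf")
  write_mgf(hcd_only, run2)
  outdir <- tempfile()
  cfg <- load_workflow(NULL, overrides = list(
    run_file = run2, fasta = sim$fasta, glycan_db = scfg$glycan_db,
    output_dir = outdir, pairing_mode = "single", specificity = "full",
    max_missed_cleavages = 0, min_peptide_length = 7,
    max_peptide_length = 22, variable_mods = "none", max_glycans = 3))
  res <- suppressWarnings(run_workflow(cfg, verbose = FALSE))
  psms <- res$psms
  expect_gt(nrow(psms), 0)
  expect_identical(psms$spectrum_id, psms$paired_scan_id)
  # with no c/z evidence, multi-site cases cannot be localized
  truth <- sim$truth
  m <- match(psms$spectrum_id, truth$hcd_scan)
  multi <- !is.na(m) & truth$n_sites[m] > truth$n_glycans[m] &
    psms$n_glycans > 0
  expect_true(all(psms$localization_level[multi] == "3"))
})
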