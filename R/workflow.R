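## Workflow configuration (key=value text) and end-to-end orchestration:
## digest -> read run -> pair scans -> per-pair search -> oxonium filter ->
## box selection + localization -> q-values -> psm.tsv + sites.tsv.

.WORKFLOW_DEFAULTS <- list(
  run_file = "", fasta = "", glycan_db = "", oxonium_rules = "default",
  output_dir = ".",
  precursor_tol_ppm = 30, product_tol_ppm = 10, max_glycans = 5L,
  oxonium_min_intensity = 0.05, prob_threshold = 0.75, fdr = 0.01,
  weighting_base = 10,
  pairing_mode = "hcd_first", require_same_charge = TRUE,
  enzyme = "trypsin", specificity = "semi", max_missed_cleavages = 2L,
  min_peptide_length = 5L, max_peptide_length = 35L,
  variable_mods = "standard", decoy_mode = "reverse", candidate_cap = 5e6)

#' Load a workflow configuration file
#'
#' Human-readable `key=value` text, `#` comments; unknown or duplicate keys
#' are rejected with their line number; absent keys take defaults.
#' `overrides` (e.g. from CLI flags) take precedence over file values.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file.
#' @return Named list of class `workflow_config`.
#' @export
load_workflow <- function(path = NULL, overrides = list()) {
  cfg <- .WORKFLOW_DEFAULTS
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    seen <- character(0)
    for (k in seq_along(lines)) {
      l <- trimws(sub("#.*$", "", lines[k]))
      if (!nzchar(l)) next
      if (!grepl("=", l, fixed = TRUE)) {
        stop("workflow config line ", k, ": expected key=value, got '", l, "'")
      }
      key <- trimws(sub("=.*$", "", l))
      val <- trimws(sub("^[^=]*=", "", l))
      if (!key %in% names(.WORKFLOW_DEFAULTS)) {
        stop("workflow config line ", k, ": unknown key '", key, "'")
      }
      if (key %in% seen) stop("workflow config line ", k, ": duplicate key '", key, "'")
      seen <- c(seen, key)
      proto <- .WORKFLOW_DEFAULTS[[key]]
      cfg[[key]] <- if (is.logical(proto)) toupper(val) %in% c("TRUE", "1", "YES")
                    else if (is.numeric(proto)) as.numeric(val)
                    else val
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(.WORKFLOW_DEFAULTS)) stop("unknown config key '", key, "'")
    cfg[[key]] <- overrides[[key]]
  }
  structure(cfg, class = "workflow_config")
}

.resolve_mods <- function(spec_str) {
  switch(spec_str,
         standard = standard_variable_mods(),
         none = list(),
         stop("variable_mods must be 'standard' or 'none'"))
}

.wf_log <- function(verbose, ...) if (verbose) message("[glycopair] ", ...)

#' Run the full paired-scan workflow
#'
#' Executes: digest, read run, pair scans, per-pair peptide-first search,
#' oxonium filtering, glycan-box selection and localization, target-decoy
#' q-values; writes `psm.tsv` and `sites.tsv` to the output directory.
#' Deterministic given identical config and inputs. Per-stage counts (scans,
#' pairs, PSMs, filtered boxes, level histogram) are logged to stderr.
#'
#' @param config A `workflow_config` from [load_workflow()].
#' @param verbose Log per-stage counts?
#' @return Invisibly, a list with `psms` (data.frame), `sites` (data.frame)
#'   and the output paths.
#' @export
run_workflow <- function(config, verbose = TRUE) {
  for (req in c("run_file", "fasta", "glycan_db")) {
    if (!nzchar(config[[req]])) stop("workflow config: '", req, "' is required")
    if (!file.exists(config[[req]])) {
      stop("workflow config: ", req, " '", config[[req]], "' does not exist")
    }
  }
  params <- search_params(
    precursor_tol_ppm = config$precursor_tol_ppm,
    product_tol_ppm = config$product_tol_ppm,
    max_glycans = config$max_glycans,
    oxonium_min_intensity = config$oxonium_min_intensity,
    prob_threshold = config$prob_threshold, fdr = config$fdr,
    weighting_base = config$weighting_base)
  registry <- monosaccharide_registry()
  db <- parse_glycan_database(config$glycan_db, registry)
  rules <- if (identical(config$oxonium_rules, "default")) {
    default_oxonium_rules()
  } else if (identical(config$oxonium_rules, "none")) {
    list()
  } else {
    read_oxonium_rules(config$oxonium_rules, config$oxonium_min_intensity,
                       registry)
  }
  dspec <- digestion_spec(
    enzyme = config$enzyme, specificity = config$specificity,
    max_missed_cleavages = config$max_missed_cleavages,
    min_length = config$min_peptide_length,
    max_length = config$max_peptide_length,
    variable_mods = .resolve_mods(config$variable_mods))
  .wf_log(verbose, "digesting ", config$fasta)
  peps <- digest(config$fasta, dspec, config$decoy_mode, config$candidate_cap)
  .wf_log(verbose, nrow(peps), " peptide candidates (",
          sum(peps$is_decoy), " decoy)")
  index <- index_peptides(peps)
  offsets <- precompute_offset_index(db, params$max_glycans)
  .wf_log(verbose, length(offsets$mass), " unique combined glycan masses")
  run <- read_run(config$run_file)
  .wf_log(verbose, length(run), " scans read (",
          sum(vapply(run, function(s) s$ms_level == 2L, logical(1))), " MS2)")
  mode <- switch(config$pairing_mode, hcd_first = "hcd_first",
                 etd_first = "etd_first", single = "single",
                 stop("unknown pairing_mode '", config$pairing_mode, "'"))
  pairs <- pair_scans(run, mode, params$precursor_tol_ppm,
                      config$require_same_charge)
  .wf_log(verbose, length(pairs), " scan pairs")
  rows <- list()
  n_filtered <- 0L
  for (pr in pairs) {
    psm <- search_pair(pr, index, offsets, params)
    if (is.null(psm)) next
    sel <- if (length(psm$candidate_boxes)) {
      select_best_box(psm, pr, db, rules, params)
    } else NULL
    if (!is.null(sel)) n_filtered <- n_filtered + sel$filtered_out
    rows[[length(rows) + 1L]] <- psm_row(psm, sel, db,
                                         basename(config$run_file))
  }
  psms <- if (length(rows)) do.call(rbind, rows) else
    utils::head(psm_row(structure(list(first_scan_id = 0L, second_scan_id = 0L,
      sequence = "AAAAA", mods = numeric(0), protein_ids = "", peptide_start = 1L,
      is_decoy = FALSE, charge = 2L, precursor_mz = 0, observed_mass = 0,
      sequence_mass = 0, delta_mass = 0, hyperscore = 0,
      candidate_boxes = list()), class = "glyco_psm"), NULL, db), 0L)
  .wf_log(verbose, nrow(psms), " PSMs; ", n_filtered,
          " candidate boxes removed by oxonium filter")
  psms <- compute_qvalues(psms)
  accepted <- psms[psms$q_value <= params$fdr & !psms$is_decoy, , drop = FALSE]
  if (nrow(psms)) {
    lv <- table(factor(psms$localization_level,
                       levels = c("1", "1b", "2", "3", "")))
    .wf_log(verbose, "level histogram: ",
            paste(names(lv), lv, sep = "=", collapse = " "))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  psm_path <- file.path(config$output_dir, "psm.tsv")
  site_path <- file.path(config$output_dir, "sites.tsv")
  write_psm_table(psms, psm_path)
  sites <- summarize_sites(accepted)
  utils::write.table(sites, site_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .wf_log(verbose, nrow(accepted), " PSMs at q<=", params$fdr, "; ",
          sum(sites$confident), " confident site(s)")
  invisible(list(psms = psms, sites = sites, psm_path = psm_path,
                 site_path = site_path))
}
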