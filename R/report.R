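## Target-decoy q-values and tab-separated result tables (psm.tsv / sites.tsv).

.PSM_SCHEMA <- c("spectrum_id", "paired_scan_id", "file", "peptide",
                 "modified_peptide", "protein_ids", "is_decoy", "charge",
                 "precursor_mz", "observed_neutral_mass", "sequence_mass",
                 "delta_mass", "glycan_composition", "n_glycans",
                 "total_glycan_mass", "site_assignments", "site_probabilities",
                 "n_configurations", "localization_level", "hyperscore",
                 "opair_score", "q_value")

.modified_peptide <- function(sequence, mods) {
  if (!length(mods)) return(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- as.integer(names(mods))
  o <- order(pos, decreasing = TRUE)
  out <- aa
  for (j in o) {
    tag <- sprintf("[%+.4f]", mods[j])
    if (pos[j] == 0L) out[1] <- paste0(tag, out[1])
    else out[pos[j]] <- paste0(out[pos[j]], tag)
  }
  paste(out, collapse = "")
}

.format_assignment <- function(res, db) {
  if (is.null(res) || !length(res$best_assignment)) return("")
  paste(sprintf("%s:%s", names(res$best_assignment),
                db$text[res$best_assignment]), collapse = "; ")
}

.format_probs <- function(res) {
  if (is.null(res)) return("")
  P <- res$site_probabilities
  per_entry <- vapply(colnames(P), function(gl) {
    paste0(gl, "{", paste(sprintf("%s:%.3f", rownames(P), P[, gl]),
                          collapse = ","), "}")
  }, character(1))
  paste(per_entry, collapse = "; ")
}

#' Assemble one result-table row from a PSM and its localization
#'
#' @param psm A `glyco_psm`.
#' @param sel Output of [select_best_box()] (or `NULL` for a
#'   non-glycosylated PSM).
#' @param db The `glycan_db`.
#' @param file Run file name for the `file` column.
#' @return One-row data.frame in the fixed psm.tsv schema plus the optional
#'   `peptide_start` column.
#' @export
psm_row <- function(psm, sel, db, file = "") {
  res <- if (is.null(sel)) NULL else sel$result
  box <- if (is.null(sel)) NULL else sel$box
  glyco <- abs(psm$delta_mass) > 0.5  # glycan-sized offset was assigned
  comp <- if (!glyco) "" else if (is.null(box)) "unassigned"
          else format_composition(box_composition(db, box), db$registry)
  data.frame(
    spectrum_id = psm$first_scan_id, paired_scan_id = psm$second_scan_id,
    file = file, peptide = psm$sequence,
    modified_peptide = .modified_peptide(psm$sequence, psm$mods),
    protein_ids = psm$protein_ids, is_decoy = psm$is_decoy,
    charge = psm$charge, precursor_mz = psm$precursor_mz,
    observed_neutral_mass = psm$observed_mass,
    sequence_mass = psm$sequence_mass, delta_mass = psm$delta_mass,
    glycan_composition = comp,
    n_glycans = if (is.null(box)) 0L else box$n_glycans,
    total_glycan_mass = if (glyco) psm$delta_mass else 0,
    site_assignments = .format_assignment(res, db),
    site_probabilities = .format_probs(res),
    n_configurations = if (is.null(res)) 0 else res$n_configurations,
    localization_level = if (is.null(res)) {
      if (glyco) "3" else ""
    } else res$level,
    hyperscore = psm$hyperscore,
    opair_score = if (is.null(res)) 0 else res$opair_score,
    q_value = NA_real_, peptide_start = psm$peptide_start,
    stringsAsFactors = FALSE)
}

#' Target-decoy q-values
#'
#' Sorts PSM rows by hyperscore (descending); at each score threshold s,
#' `FDR(s) = #decoys >= s / max(1, #targets >= s)`; q-values are the running
#' minimum of FDR from the bottom of the list.
#'
#' @param psms data.frame of PSM rows with `hyperscore` and `is_decoy`.
#' @return The data.frame with `q_value` filled, sorted by descending
#'   hyperscore.
#' @export
compute_qvalues <- function(psms) {
  if (!nrow(psms)) return(psms)
  o <- order(-psms$hyperscore)
  psms <- psms[o, , drop = FALSE]
  nd <- cumsum(psms$is_decoy)
  nt <- cumsum(!psms$is_decoy)
  fdr <- nd / pmax(1, nt)
  psms$q_value <- rev(cummin(rev(fdr)))
  if (sum(psms$is_decoy) == 0L) {
    warning("no decoy PSMs present; q-values are all zero")
  }
  rownames(psms) <- NULL
  psms
}

#' Write / read the psm.tsv result table
#'
#' UTF-8, tab-separated, header row, fixed column order (extra columns such
#' as `peptide_start` are carried after the mandatory schema and tolerated in
#' any order on read). The round-trip is lossless.
#'
#' @param psms data.frame of PSM rows.
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  cols <- c(.PSM_SCHEMA, setdiff(names(psms), .PSM_SCHEMA))
  if (!nrow(psms)) {
    psms <- psms[, intersect(cols, names(psms)), drop = FALSE]
    missing <- setdiff(.PSM_SCHEMA, names(psms))
    for (mcol in missing) psms[[mcol]] <- character(0)
    cols <- c(.PSM_SCHEMA, setdiff(names(psms), .PSM_SCHEMA))
  }
  utils::write.table(psms[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_psm_table
#' @return For `read_psm_table`, the data.frame of PSM rows.
#' @export
read_psm_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = NA, comment.char = "",
                          fileEncoding = "UTF-8")
  missing <- setdiff(.PSM_SCHEMA, names(df))
  if (length(missing)) {
    stop("psm table ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("glycan_composition", "site_assignments", "site_probabilities",
                "localization_level", "file", "modified_peptide")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df[, c(.PSM_SCHEMA, setdiff(names(df), .PSM_SCHEMA)), drop = FALSE]
}

#' Site-level summary table
#'
#' One row per (protein, site): PSM count, glycan compositions observed and
#' the best localization level. Only levels 1 and 1b count as confidently
#' localized; a site appears in the table when at least one PSM places a
#' glycan on it with site probability above the threshold at level 1/1b/2.
#' Protein site positions are derived from `peptide_start` when present.
#'
#' @param psms PSM data.frame (localized rows).
#' @return data.frame: `protein`, `site`, `psm_count`, `glycans`,
#'   `best_level`, `confident` (logical: best level is 1 or 1b).
#' @export
summarize_sites <- function(psms) {
  rows <- list()
  for (r in seq_len(nrow(psms))) {
    sa <- psms$site_assignments[r]
    lv <- psms$localization_level[r]
    if (!nzchar(sa) || !lv %in% c("1", "1b", "2")) next
    prot <- strsplit(psms$protein_ids[r], ";", fixed = TRUE)[[1]][1]
    off <- if ("peptide_start" %in% names(psms) &&
               !is.na(psms$peptide_start[r])) psms$peptide_start[r] - 1L else 0L
    for (tok in strsplit(sa, ";", fixed = TRUE)[[1]]) {
      tok <- trimws(tok)
      site <- sub(":.*", "", tok)
      gl <- sub("^[^:]+:", "", tok)
      pos <- as.integer(sub("^[A-Z]", "", site)) + off
      site_label <- paste0(substr(site, 1, 1), pos)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = prot, site = site_label, glycan = gl, level = lv,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(protein = character(0), site = character(0),
                      psm_count = integer(0), glycans = character(0),
                      best_level = character(0), confident = logical(0)))
  }
  df <- do.call(rbind, rows)
  key <- paste(df$protein, df$site)
  agg <- lapply(split(df, key), function(d) {
    lvl_rank <- c("1" = 1, "1b" = 2, "2" = 3)
    best <- d$level[which.min(lvl_rank[d$level])]
    data.frame(protein = d$protein[1], site = d$site[1], psm_count = nrow(d),
               glycans = paste(sort(unique(d$glycan)), collapse = ";"),
               best_level = best, confident = best %in% c("1", "1b"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$protein, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}
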