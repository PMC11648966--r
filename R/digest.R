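## In-silico digestion: trypsin and StcE cleavage, full/semi specificity,
## missed cleavages, reversed decoys, variable modifications.

#' Digestion specification
#'
#' @param enzyme `"trypsin"` (cleave C-terminal to K/R), `"stce"` (mucinase
#'   StcE; modeled as cleaving N-terminal to any S or T, since glycosylation
#'   cannot be known in silico) or `"none"` (no cleavage; whole sequence).
#' @param specificity `"full"` or `"semi"` (one terminus may be nonspecific).
#' @param max_missed_cleavages Maximum missed cleavage sites.
#' @param min_length,max_length Peptide length bounds (min >= 4).
#' @param no_cleave_before_P For trypsin, suppress cleavage before proline.
#' @param variable_mods List of variable modifications, each a list with
#'   `residue` (one-letter codes, or `"nterm"` for the peptide N-terminus),
#'   `delta` (Da) and `max` (max occurrences). See [standard_variable_mods()].
#' @return List of class `digestion_spec`.
#' @export
digestion_spec <- function(enzyme = c("trypsin", "stce", "none"),
                           specificity = c("full", "semi"),
                           max_missed_cleavages = 2L,
                           min_length = 5L, max_length = 35L,
                           no_cleave_before_P = TRUE,
                           variable_mods = list()) {
  enzyme <- match.arg(enzyme)
  specificity <- match.arg(specificity)
  stopifnot(max_missed_cleavages >= 0, min_length >= 4)
  structure(list(enzyme = enzyme, specificity = specificity,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 no_cleave_before_P = no_cleave_before_P,
                 variable_mods = variable_mods),
            class = "digestion_spec")
}

#' Common variable modifications
#'
#' Oxidation (M, max 3), deamidation (N/Q, max 1), N-terminal acetylation.
#' @return List suitable for the `variable_mods` field of [digestion_spec()].
#' @export
standard_variable_mods <- function() {
  list(list(residue = "M", delta = 15.994915, max = 3L),
       list(residue = c("N", "Q"), delta = 0.984016, max = 1L),
       list(residue = "nterm", delta = 42.010565, max = 1L))
}

## Cleavage sites: positions after which the backbone is cut (0-based cut
## points between residue i and i+1 are represented by i).
.cut_points <- function(seq_chars, spec) {
  n <- length(seq_chars)
  if (spec$enzyme == "none" || n < 2L) return(integer(0))
  if (spec$enzyme == "trypsin") {
    i <- which(seq_chars[-n] %in% c("K", "R"))
    if (spec$no_cleave_before_P) i <- i[seq_chars[i + 1L] != "P"]
    i
  } else {  # stce: cut N-terminal to S/T, i.e. between i and i+1 when i+1 is S/T
    which(seq_chars[-1L] %in% c("S", "T"))
  }
}

.enumerate_peptides <- function(seq_chars, spec) {
  n <- length(seq_chars)
  cuts <- c(0L, .cut_points(seq_chars, spec), n)
  cuts <- sort(unique(cuts))
  nseg <- length(cuts) - 1L
  out <- list()
  for (a in seq_len(nseg)) {
    for (b in a:min(nseg, a + spec$max_missed_cleavages)) {
      start <- cuts[a] + 1L
      end <- cuts[b + 1L]
      len <- end - start + 1L
      if (len < spec$min_length && spec$specificity == "full") next
      if (spec$specificity == "full") {
        if (len > spec$max_length) next
        out[[length(out) + 1L]] <- c(start, end)
      } else {
        # semi: one terminus may be nonspecific; enumerate truncations
        out[[length(out) + 1L]] <- c(start, end)
        if (end > start) {
          for (s2 in seq(start + 1L, end)) {  # N-terminal ragged
            len2 <- end - s2 + 1L
            if (len2 >= spec$min_length && len2 <= spec$max_length) {
              out[[length(out) + 1L]] <- c(s2, end)
            }
          }
          for (e2 in seq(start, end - 1L)) {  # C-terminal ragged
            len2 <- e2 - start + 1L
            if (len2 >= spec$min_length && len2 <= spec$max_length) {
              out[[length(out) + 1L]] <- c(start, e2)
            }
          }
        }
      }
    }
  }
  out <- out[vapply(out, function(p) {
    l <- p[2] - p[1] + 1L
    l >= spec$min_length && l <= spec$max_length
  }, logical(1))]
  unique(out)
}

## Enumerate variable-mod states for one peptide; returns list of named
## numeric vectors (position -> delta), including the unmodified state.
.mod_states <- function(sequence, mods, cap = Inf) {
  states <- list(numeric(0))
  if (!length(mods)) return(states)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (md in mods) {
    if (identical(md$residue, "nterm")) {
      pos <- 0L
    } else {
      pos <- which(aa %in% md$residue)
    }
    if (!length(pos)) next
    opts <- list(integer(0))
    for (k in seq_len(min(md$max, length(pos)))) {
      cmb <- utils::combn(pos, k, simplify = FALSE)
      opts <- c(opts, cmb)
    }
    new_states <- vector("list", length(states) * length(opts))
    j <- 0L
    for (st in states) {
      for (op in opts) {
        j <- j + 1L
        if (length(op)) {
          add <- stats::setNames(rep(md$delta, length(op)), op)
          new_states[[j]] <- c(st, add)
        } else {
          new_states[[j]] <- st
        }
        if (j > cap) stop("variable-modification state explosion; ",
                          "tighten variable_mods or the candidate cap")
      }
    }
    states <- new_states
  }
  states
}

#' Digest a protein database
#'
#' Enumerates peptide candidates (and optionally reversed-sequence decoys)
#' from a FASTA file under a [digestion_spec()]. Variable-modification states
#' are expanded up to their per-mod maxima, subject to `candidate_cap`.
#'
#' @param fasta Path to a protein FASTA file.
#' @param spec A `digestion_spec`.
#' @param decoy_mode `"reverse"` (append decoys from reversed proteins) or
#'   `"none"`.
#' @param candidate_cap Abort if the number of (peptide, mod-state) candidates
#'   would exceed this (guards semi-enzymatic explosions).
#' @return data.frame with columns `sequence`, `protein_ids`, `start`
#'   (1-based position in protein), `is_decoy`, `mods` (list column of
#'   position->delta vectors), `mass` (neutral, Da), `n_sites` (S/T count).
#' @export
digest <- function(fasta, spec = digestion_spec(),
                   decoy_mode = c("reverse", "none"), candidate_cap = 5e6) {
  decoy_mode <- match.arg(decoy_mode)
  prots <- Biostrings::readAAStringSet(fasta)
  if (!length(prots)) stop("empty FASTA: ", fasta)
  names(prots) <- vapply(strsplit(names(prots), "[ \t]"), `[[`, character(1), 1)
  seqs <- as.character(prots)
  if (decoy_mode == "reverse") {
    rev_seqs <- vapply(seqs, function(s)
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), character(1))
    names(rev_seqs) <- paste0("rev_", names(seqs))
    seqs <- c(seqs, rev_seqs)
  }
  is_decoy_prot <- startsWith(names(seqs), "rev_")
  rows <- list()
  n_cand <- 0L
  for (p in seq_along(seqs)) {
    sq <- gsub("[^A-Z]", "", toupper(seqs[[p]]))
    chars <- strsplit(sq, "", fixed = TRUE)[[1]]
    chars[chars %in% c("U", "O", "B", "Z", "X", "J")] <- NA
    if (anyNA(chars)) next  # skip proteins with nonstandard residues
    for (se in .enumerate_peptides(chars, spec)) {
      pep <- substr(sq, se[1], se[2])
      states <- .mod_states(pep, spec$variable_mods, cap = candidate_cap)
      for (st in states) {
        n_cand <- n_cand + 1L
        if (n_cand > candidate_cap) {
          stop("candidate cap (", candidate_cap, ") exceeded; ",
               "tighten digestion limits")
        }
        rows[[n_cand]] <- list(sequence = pep, protein_ids = names(seqs)[p],
                               start = se[1], is_decoy = is_decoy_prot[p],
                               mods = st)
      }
    }
  }
  if (!length(rows)) stop("digestion produced no peptides")
  df <- data.frame(
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    protein_ids = vapply(rows, `[[`, character(1), "protein_ids"),
    start = vapply(rows, `[[`, integer(1), "start"),
    is_decoy = vapply(rows, `[[`, logical(1), "is_decoy"),
    stringsAsFactors = FALSE)
  df$mods <- lapply(rows, `[[`, "mods")
  # collapse identical (sequence, mods, decoy) across proteins
  modkey <- vapply(df$mods, function(m)
    paste(names(m), round(m, 4), sep = ":", collapse = ","), character(1))
  key <- paste(df$sequence, modkey, df$is_decoy)
  first <- !duplicated(key)
  prot_map <- split(df$protein_ids, key)
  df2 <- df[first, , drop = FALSE]
  df2$protein_ids <- vapply(prot_map[key[first]], function(x)
    paste(unique(x), collapse = ";"), character(1))
  df2$mass <- mapply(function(s, m) peptide_mass(s, m), df2$sequence, df2$mods)
  df2$n_sites <- vapply(strsplit(df2$sequence, "", fixed = TRUE),
                        function(a) sum(a %in% c("S", "T")), integer(1))
  rownames(df2) <- NULL
  df2
}
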