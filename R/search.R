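## Peptide-first search of the collisional scan: the precursor mass is matched
## to a peptide plus the combined mass of a multiset of glycans (a "box");
## only backbone b/y ions of the naked peptide are scored, so each distinct
## combined glycan mass is a single mass offset rather than a combinatorial
## set of site configurations.

#' Search parameter set
#'
#' Defaults follow common practice for paired-scan O-glycopeptide searches:
#' 30 ppm precursor and 10 ppm product tolerance, at most 5 glycans per
#' peptide, a 5% summed relative-intensity oxonium threshold, a 0.75 site
#' probability threshold, 1% FDR.
#'
#' @param precursor_tol_ppm,product_tol_ppm Mass tolerances (ppm).
#' @param max_glycans Maximum glycans per peptide.
#' @param oxonium_min_intensity Default minimum summed relative intensity for
#'   oxonium rules lacking their own threshold.
#' @param prob_threshold Site-probability threshold for confident localization.
#' @param fdr q-value acceptance threshold.
#' @param weighting_base Base of the exponential path weighting used in
#'   localization.
#' @param min_hyperscore PSMs scoring below this are discarded.
#' @return List of class `search_params`.
#' @export
search_params <- function(precursor_tol_ppm = 30, product_tol_ppm = 10,
                          max_glycans = 5L, oxonium_min_intensity = 0.05,
                          prob_threshold = 0.75, fdr = 0.01,
                          weighting_base = 10, min_hyperscore = 0) {
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 product_tol_ppm = product_tol_ppm,
                 max_glycans = as.integer(max_glycans),
                 oxonium_min_intensity = oxonium_min_intensity,
                 prob_threshold = prob_threshold, fdr = fdr,
                 weighting_base = weighting_base,
                 min_hyperscore = min_hyperscore),
            class = "search_params")
}

#' Precompute the glycan mass-offset index
#'
#' Enumerates all glycan boxes up to `max_glycans` and groups them by combined
#' mass rounded to `mass_decimals`; the index is binary-searchable by mass
#' window during search.
#'
#' @param db A `glycan_db`.
#' @param max_glycans Maximum box size.
#' @param mass_decimals Grouping precision (decimals).
#' @return List of class `offset_index` with sorted `mass` and parallel
#'   `boxes` (list of box lists).
#' @export
precompute_offset_index <- function(db, max_glycans, mass_decimals = 4) {
  boxes <- enumerate_boxes(db, max_glycans)
  if (!length(boxes)) {
    return(structure(list(mass = numeric(0), boxes = list()),
                     class = "offset_index"))
  }
  key <- round(vapply(boxes, `[[`, numeric(1), "mass"), mass_decimals)
  grp <- split(boxes, key)
  mass <- as.numeric(names(grp))
  o <- order(mass)
  structure(list(mass = mass[o], boxes = unname(grp[o])),
            class = "offset_index")
}

#' Look up offset-index groups in a mass window
#' @param index An `offset_index`.
#' @param target Mass (Da).
#' @param tol_ppm Window half-width in ppm of `target`.
#' @return Integer positions into `index$mass`.
#' @export
offset_lookup <- function(index, target, tol_ppm) {
  tol <- abs(target) * tol_ppm * 1e-6
  lo <- findInterval(target - tol, index$mass) + 1L
  hi <- findInterval(target + tol, index$mass)
  if (hi < lo) integer(0) else lo:hi
}

#' X!Tandem-style hyperscore of a naked peptide against a spectrum
#'
#' Matches singly and doubly protonated b and y ions of the glycan-free
#' (modified) peptide. Score =
#' `ln(n_b!) + ln(n_y!) + ln(sum_b_intensity * sum_y_intensity)` with the
#' factorials capped at 10 and a score of 0 when either ion series has no
#' matched intensity.
#'
#' @param spec A `glyco_spectrum`.
#' @param sequence Peptide sequence.
#' @param mods Named mod-delta vector.
#' @param product_tol_ppm Fragment tolerance (ppm).
#' @return List with `score`, `n_b`, `n_y`.
#' @export
hyperscore <- function(spec, sequence, mods = NULL, product_tol_ppm = 10) {
  if (nchar(sequence) < 2L) return(list(score = 0, n_b = 0L, n_y = 0L))
  sums <- c(b = 0, y = 0)
  nmatch <- c(b = 0L, y = 0L)
  for (ty in c("b", "y")) {
    hit_pos <- logical(nchar(sequence) - 1L)
    for (z in 1:2) {
      th <- fragment_mz(sequence, ty, z, mods)
      m <- match_peaks(th, spec$mz, product_tol_ppm)
      hit <- !is.na(m)
      sums[ty] <- sums[ty] + sum(spec$intensity[m[hit]])
      hit_pos <- hit_pos | hit
    }
    nmatch[ty] <- sum(hit_pos)
  }
  if (sums["b"] <= 0 || sums["y"] <= 0) {
    return(list(score = 0, n_b = unname(nmatch["b"]), n_y = unname(nmatch["y"])))
  }
  sc <- lfactorial(min(nmatch["b"], 10L)) + lfactorial(min(nmatch["y"], 10L)) +
    log(sums["b"] * sums["y"])
  list(score = unname(sc), n_b = unname(nmatch["b"]), n_y = unname(nmatch["y"]))
}

#' Build a mass-sorted candidate index from a digest
#' @param peptides data.frame from [digest()].
#' @return The data.frame sorted by `mass` with class `peptide_index`.
#' @export
index_peptides <- function(peptides) {
  out <- peptides[order(peptides$mass, peptides$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peptide_index", class(out))
  out
}

#' Search one scan pair
#'
#' The first (collisional) scan is searched for candidate peptides whose
#' neutral mass equals the observed precursor neutral mass minus either zero
#' or some combined glycan mass in the offset index, within the precursor
#' tolerance. Glycan offsets are considered only for peptides with at least
#' one S/T, and only boxes with no more glycans than candidate sites are
#' retained. Candidates are ranked by hyperscore on the first scan; ties are
#' broken by fewer glycans in the smallest candidate box, then by peptide
#' sequence.
#'
#' @param pair A scan pair from [pair_scans()].
#' @param index A `peptide_index`.
#' @param offsets An `offset_index`.
#' @param params A `search_params`.
#' @return A `glyco_psm` list, or `NULL` when nothing matches. Fields:
#'   peptide info, `charge`, `observed_mass`, `delta_mass`, `hyperscore`,
#'   `candidate_boxes` (possibly empty for non-glycosylated matches).
#' @export
search_pair <- function(pair, index, offsets, params = search_params()) {
  s1 <- pair$first
  z <- s1$precursor_charge
  if (is.na(z) || z < 1L) return(NULL)
  M <- (s1$precursor_mz - PROTON_MASS) * z
  tol <- M * params$precursor_tol_ppm * 1e-6
  # candidate (peptide, offset-group) pairs: offset 0 (non-glyco) plus groups
  targets <- c(0, offsets$mass)
  cand_pep <- integer(0)
  cand_off <- integer(0)  # 0 = no glycan, else index into offsets$mass
  for (k in seq_along(targets)) {
    pm <- M - targets[k]
    if (pm <= 0) next
    lo <- findInterval(pm - tol, index$mass) + 1L
    hi <- findInterval(pm + tol, index$mass)
    if (hi < lo) next
    sel <- lo:hi
    if (k > 1L) sel <- sel[index$n_sites[sel] >= 1L]
    if (length(sel)) {
      cand_pep <- c(cand_pep, sel)
      cand_off <- c(cand_off, rep(k - 1L, length(sel)))
    }
  }
  if (!length(cand_pep)) return(NULL)
  upep <- unique(cand_pep)
  hs <- lapply(upep, function(i)
    hyperscore(s1, index$sequence[i], index$mods[[i]], params$product_tol_ppm))
  score <- vapply(hs, `[[`, numeric(1), "score")
  keep <- score > params$min_hyperscore
  if (!any(keep)) return(NULL)
  upep <- upep[keep]
  hs <- hs[keep]
  score <- score[keep]
  # per-peptide candidate boxes (size-capped by site count)
  box_of <- function(i) {
    ks <- cand_off[cand_pep == i]
    ks <- ks[ks > 0L]
    if (!length(ks)) return(list())
    bx <- unlist(offsets$boxes[ks], recursive = FALSE)
    bx[vapply(bx, `[[`, integer(1), "n_glycans") <= index$n_sites[i]]
  }
  boxes <- lapply(upep, box_of)
  # peptides matched only through now-empty glycan routes are invalid
  direct <- vapply(upep, function(i) any(cand_off[cand_pep == i] == 0L), logical(1))
  valid <- direct | vapply(boxes, length, integer(1)) > 0L
  if (!any(valid)) return(NULL)
  upep <- upep[valid]; hs <- hs[valid]; score <- score[valid]; boxes <- boxes[valid]
  min_box <- vapply(boxes, function(b) {
    if (!length(b)) 0L else min(vapply(b, `[[`, integer(1), "n_glycans"))
  }, integer(1))
  ord <- order(-score, min_box, index$sequence[upep])
  b <- ord[1]
  i <- upep[b]
  structure(list(
    first_scan_id = s1$scan_id,
    second_scan_id = if (identical(pair$mode, "single")) s1$scan_id else pair$second$scan_id,
    sequence = index$sequence[i], mods = index$mods[[i]],
    protein_ids = index$protein_ids[i], peptide_start = index$start[i],
    is_decoy = index$is_decoy[i], charge = z,
    precursor_mz = s1$precursor_mz, observed_mass = M,
    sequence_mass = index$mass[i], delta_mass = M - index$mass[i],
    hyperscore = score[b], n_b = hs[[b]]$n_b, n_y = hs[[b]]$n_y,
    candidate_boxes = boxes[[b]]), class = "glyco_psm")
}

## ---- oxonium rules ----------------------------------------------------------

#' Read an oxonium rule file
#'
#' Tab-separated lines: `residues<TAB>mz1,mz2,...<TAB>min_rel_intensity`
#' (third column optional; `#` comments allowed). A rule applies to a glycan
#' box when the box's summed composition contains at least the residue counts
#' in the rule; the rule passes when the summed base-peak-relative intensity
#' of peaks matching any of its ions is at or above the threshold.
#'
#' @param path Rule file.
#' @param default_min Fallback threshold for rules lacking a third column.
#' @param registry Monosaccharide registry.
#' @return List of rules: `residues` (glycan_composition), `ion_mzs`,
#'   `min_intensity`.
#' @export
read_oxonium_rules <- function(path, default_min = 0.05,
                               registry = monosaccharide_registry()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("oxonium rule line ", k, ": expected residues<TAB>ions")
    mzs <- as.numeric(strsplit(f[2], ",", fixed = TRUE)[[1]])
    if (!length(mzs) || anyNA(mzs)) stop("oxonium rule line ", k, ": bad ion list")
    thr <- if (length(f) >= 3L && nzchar(f[3])) as.numeric(f[3]) else default_min
    if (is.na(thr) || thr < 0 || thr > 1) {
      stop("oxonium rule line ", k, ": threshold must be in [0,1]")
    }
    list(residues = parse_composition(f[1], registry), ion_mzs = mzs,
         min_intensity = thr)
  })
}

#' Default oxonium rule set
#'
#' The four standard residue-ion pairs shipped with the package:
#' HexNAc(1)Hex(1) 366.1395; Hex(1) 163.0601/145.0495; NeuAc(1)
#' 274.0921/292.1027; NeuGc(1) 290.0870/308.0976, each at a 5% summed
#' relative-intensity minimum.
#' @return Rule list as from [read_oxonium_rules()].
#' @export
default_oxonium_rules <- function() {
  read_oxonium_rules(system.file("extdata", "oxonium_rules.tsv",
                                 package = "glycopair"))
}

#' Oxonium-ion prefilter for a candidate glycan box
#'
#' Rules are evaluated against the first (collisional) scan of the pair only.
#' Every rule whose residues are contained in the box's summed composition
#' must find its ions with summed base-peak-relative intensity at or above
#' its threshold.
#'
#' @param first_scan The collisional `glyco_spectrum`.
#' @param box_comp Summed `glycan_composition` of the box.
#' @param rules Rule list ([read_oxonium_rules()]); empty list = always pass.
#' @param tol_ppm Ion match tolerance (ppm).
#' @return `TRUE` (pass) or `FALSE`.
#' @export
oxonium_filter <- function(first_scan, box_comp, rules, tol_ppm = 10) {
  if (!length(rules)) return(TRUE)
  rel <- base_peak_normalize(first_scan)
  for (r in rules) {
    need <- r$residues
    have <- box_comp[names(need)]
    have[is.na(have)] <- 0L
    if (any(have < as.integer(need))) next  # rule not applicable
    m <- match_peaks(r$ion_mzs, first_scan$mz, tol_ppm)
    tot <- sum(rel[unique(m[!is.na(m)])])
    if (tot < r$min_intensity) return(FALSE)
  }
  TRUE
}
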