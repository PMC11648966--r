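## Glycan compositions, composition databases, oxonium ions, and the
## configuration-counting combinatorics that motivate peptide-first search.

#' Parse a glycan composition string
#'
#' Byonic-style composition text, e.g. `"HexNAc(2)Hex(1)NeuAc(1)"`. Order of
#' segments is free on input; the canonical form emitted by
#' [format_composition()] follows registry order.
#'
#' @param text Composition string.
#' @param registry Monosaccharide registry (see [monosaccharide_registry()]).
#' @return Named integer vector of counts (class `glycan_composition`),
#'   ordered by the registry, zero counts dropped.
#' @export
parse_composition <- function(text, registry = monosaccharide_registry()) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty composition string")
  m <- gregexpr("([A-Za-z]+)\\(([0-9]+)\\)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(gsub("[[:space:]]", "", text))) {
    stop("malformed composition: '", text, "'")
  }
  names_ <- sub("\\(.*", "", toks)
  counts <- as.integer(sub(".*\\(([0-9]+)\\)", "\\1", toks))
  unknown <- setdiff(names_, registry$name)
  if (length(unknown)) {
    stop("unknown monosaccharide ", paste(unknown, collapse = ","),
         " in composition '", text, "'")
  }
  if (anyDuplicated(names_)) stop("repeated monosaccharide in '", text, "'")
  full <- stats::setNames(integer(nrow(registry)), registry$name)
  full[names_] <- counts
  out <- full[full > 0L]
  class(out) <- "glycan_composition"
  out
}

#' Canonical text form of a composition
#' @param comp A `glycan_composition` (named integer vector).
#' @param registry Monosaccharide registry (fixes segment order).
#' @return Character like `"HexNAc(2)Hex(1)"`.
#' @export
format_composition <- function(comp, registry = monosaccharide_registry()) {
  comp <- comp[comp > 0L]
  ord <- order(match(names(comp), registry$name))
  paste0(names(comp)[ord], "(", unclass(comp)[ord], ")", collapse = "")
}

#' Monoisotopic mass of a composition
#' @inheritParams format_composition
#' @return Sum of residue masses in Da.
#' @export
composition_mass <- function(comp, registry = monosaccharide_registry()) {
  if (!length(comp)) return(0)
  idx <- match(names(comp), registry$name)
  if (anyNA(idx)) stop("composition names not in registry")
  sum(registry$mass[idx] * as.integer(comp))
}

#' Sum two compositions
#' @keywords internal
add_compositions <- function(a, b) {
  nm <- union(names(a), names(b))
  out <- stats::setNames(integer(length(nm)), nm)
  out[names(a)] <- out[names(a)] + as.integer(a)
  out[names(b)] <- out[names(b)] + as.integer(b)
  out <- out[out > 0L]
  class(out) <- "glycan_composition"
  out
}

#' Read a glycan composition database
#'
#' One composition per line, `"Name(count)..."`, optionally followed by
#' `" % <mass>"` (the annotation must agree with the computed mass within
#' 0.01 Da). `#` starts a comment; blank lines are ignored. Entries are
#' deduplicated-checked and sorted by mass for reproducible iteration.
#'
#' @param path Path to the database file.
#' @param registry Monosaccharide registry.
#' @return Object of class `glycan_db`: list with `entries` (list of
#'   compositions), `mass` (numeric vector), `text` (canonical strings) and
#'   `source_path`.
#' @export
parse_glycan_database <- function(path, registry = monosaccharide_registry()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  entries <- list()
  masses <- numeric(0)
  texts <- character(0)
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "%", fixed = TRUE)[[1]]
    comp <- tryCatch(parse_composition(parts[1], registry),
                     error = function(e) {
                       stop("glycan database line ", k, ": ", conditionMessage(e),
                            call. = FALSE)
                     })
    m <- composition_mass(comp, registry)
    if (length(parts) > 1L) {
      ann <- suppressWarnings(as.numeric(trimws(parts[2])))
      if (is.na(ann) || abs(ann - m) > 0.01) {
        stop("glycan database line ", k, ": annotated mass ", trimws(parts[2]),
             " disagrees with computed mass ", round(m, 4))
      }
    }
    txt <- format_composition(comp, registry)
    if (txt %in% texts) stop("glycan database line ", k, ": duplicate composition ", txt)
    entries[[length(entries) + 1L]] <- comp
    masses <- c(masses, m)
    texts <- c(texts, txt)
  }
  ord <- order(masses, texts)
  structure(list(entries = entries[ord], mass = masses[ord], text = texts[ord],
                 source_path = path, registry = registry),
            class = "glycan_db")
}

#' @export
print.glycan_db <- function(x, ...) {
  cat("glycan_db with", length(x$entries), "composition(s)\n")
  if (length(x$entries)) {
    cat(paste0("  ", x$text, "  [", sprintf("%.4f", x$mass), " Da]"), sep = "\n")
  }
  invisible(x)
}

#' Length of a glycan database
#' @param x A `glycan_db`.
#' @param ... ignored.
#' @export
length.glycan_db <- function(x) length(x$entries)

#' Oxonium ion m/z of a glycan composition
#'
#' Singly protonated oxonium ion of a (partial) glycan: composition mass plus
#' a proton, optionally after one water loss.
#'
#' @param comp A `glycan_composition`.
#' @param water_loss Subtract one water (e.g. the 145.0495 hexose ion)?
#' @param registry Monosaccharide registry.
#' @return m/z of the singly charged ion.
#' @examples
#' oxonium_mz(parse_composition("Hex(1)"))                      # 163.0601
#' oxonium_mz(parse_composition("Hex(1)"), water_loss = TRUE)   # 145.0495
#' oxonium_mz(parse_composition("HexNAc(1)Hex(1)"))             # 366.1395
#' @export
oxonium_mz <- function(comp, water_loss = FALSE,
                       registry = monosaccharide_registry()) {
  if (!length(comp) || sum(comp) == 0L) stop("empty composition")
  m <- composition_mass(comp, registry) + PROTON_MASS
  if (water_loss) m <- m - WATER_MASS
  m
}

#' Count glycan configurations considered by a conventional vs peptide-first search
#'
#' Number of distinct glycan multisets of size 1..k drawn with repetition from
#' a database of `n_glycans_in_db` compositions, where
#' `k = min(n_sites, max_glycans)`. Closed form:
#' `choose(n_glycans_in_db + k, k) - 1` (the empty multiset is excluded).
#' This is the per-peptide search-space size a conventional (glycan-first)
#' engine must enumerate; a peptide-first engine needs only the distinct
#' combined masses ([count_unique_combined_masses()]).
#'
#' @param n_glycans_in_db Database size (>= 1).
#' @param n_sites Number of candidate S/T sites in the peptide (>= 1).
#' @param max_glycans Maximum glycans allowed per peptide (>= 1).
#' @return Integer-valued count (returned as double; may exceed 2^31).
#' @examples
#' count_configurations(32, 5, 5)  # 435896
#' count_configurations(32, 8, 8)  # 76904684
#' @export
count_configurations <- function(n_glycans_in_db, n_sites, max_glycans = n_sites) {
  stopifnot(n_glycans_in_db >= 1, n_sites >= 1, max_glycans >= 1)
  k <- min(n_sites, max_glycans)
  round(choose(n_glycans_in_db + k, k)) - 1
}

## Recursive enumeration of nondecreasing index tuples (multisets).
## visit(idx) is called for every multiset of size 1..max_n; returns count.
.enumerate_multisets <- function(n_entries, max_n, visit = NULL) {
  count <- 0L
  rec <- function(prefix, lo) {
    for (i in lo:n_entries) {
      cur <- c(prefix, i)
      count <<- count + 1L
      if (!is.null(visit)) visit(cur)
      if (length(cur) < max_n) rec(cur, i)
    }
  }
  if (n_entries >= 1 && max_n >= 1) rec(integer(0), 1L)
  count
}

#' Brute-force configuration count by explicit multiset enumeration
#'
#' Enumerates every multiset explicitly; intended as an independent check of
#' the closed form in [count_configurations()] at small-to-moderate sizes.
#'
#' @inheritParams count_configurations
#' @return Count of enumerated multisets.
#' @export
count_configurations_bruteforce <- function(n_glycans_in_db, n_sites,
                                            max_glycans = n_sites) {
  k <- min(n_sites, max_glycans)
  .enumerate_multisets(n_glycans_in_db, k)
}

#' Enumerate glycan boxes
#'
#' A *glycan box* is a multiset of database entries carried by one peptide.
#' Enumerates all boxes of size 1..`max_glycans`; when `target_mass` is given,
#' only boxes whose total mass lies within `tolerance_ppm` of it are returned.
#'
#' @param db A `glycan_db`.
#' @param max_glycans Maximum box size.
#' @param target_mass Optional total-mass filter (Da).
#' @param tolerance_ppm Mass tolerance in ppm of `target_mass`.
#' @return List of boxes sorted by total mass; each a list with `idx`
#'   (sorted db-entry indices, with repetition), `n_glycans`, `mass`.
#' @export
enumerate_boxes <- function(db, max_glycans, target_mass = NULL,
                            tolerance_ppm = 10) {
  stopifnot(inherits(db, "glycan_db"), max_glycans >= 1)
  n <- length(db$entries)
  if (n == 0L) return(list())
  lo_hi <- NULL
  if (!is.null(target_mass)) {
    tol <- abs(target_mass) * tolerance_ppm * 1e-6
    lo_hi <- c(target_mass - tol, target_mass + tol)
    if (target_mass <= 0) return(list())
  }
  boxes <- list()
  min_entry <- min(db$mass)
  rec <- function(prefix, lo, mass) {
    for (i in lo:n) {
      m2 <- mass + db$mass[i]
      if (!is.null(lo_hi) && m2 > lo_hi[2]) break  # entries sorted by mass
      cur <- c(prefix, i)
      keep <- is.null(lo_hi) || (m2 >= lo_hi[1] && m2 <= lo_hi[2])
      if (keep) {
        boxes[[length(boxes) + 1L]] <<- list(idx = cur,
                                             n_glycans = length(cur),
                                             mass = m2)
      }
      if (length(cur) < max_glycans &&
          (is.null(lo_hi) || m2 + min_entry <= lo_hi[2])) {
        rec(cur, i, m2)
      }
    }
  }
  rec(integer(0), 1L, 0)
  boxes[order(vapply(boxes, `[[`, numeric(1), "mass"))]
}

#' Number of unique combined glycan masses
#'
#' Counts the distinct total masses among all boxes of size 1..`max_glycans`,
#' after rounding to `mass_decimals` decimals. This is the peptide-first
#' search-space size: always no larger than [count_configurations()].
#'
#' @inheritParams enumerate_boxes
#' @param mass_decimals Rounding used to decide mass uniqueness (default 4,
#'   i.e. ~0.1 mDa).
#' @return Integer count.
#' @export
count_unique_combined_masses <- function(db, max_glycans, mass_decimals = 4) {
  boxes <- enumerate_boxes(db, max_glycans)
  length(unique(round(vapply(boxes, `[[`, numeric(1), "mass"), mass_decimals)))
}

#' Total composition of a box
#' @param db A `glycan_db`.
#' @param box A box from [enumerate_boxes()].
#' @return A `glycan_composition` summing the member entries.
#' @export
box_composition <- function(db, box) {
  out <- db$entries[[box$idx[1]]]
  for (i in box$idx[-1]) out <- add_compositions(out, db$entries[[i]])
  out
}

#' Canonical text of a box (semicolon-joined member compositions)
#' @keywords internal
box_text <- function(db, box) paste(db$text[box$idx], collapse = ";")
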