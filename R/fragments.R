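## Theoretical backbone fragment ions (b/y for collisional scans, c/z-dot for
## electron-based activation) and ppm peak matching.

#' Cumulative prefix masses of a (modified) peptide
#'
#' `prefix[i]` = sum of residue masses 1..i plus modification deltas at
#' positions <= i (position 0 = N-terminal mods count toward every prefix).
#' @keywords internal
.prefix_masses <- function(sequence, mods = NULL) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  res <- .AA_MASS[aa]
  if (length(mods)) {
    pos <- as.integer(names(mods))
    for (j in seq_along(pos)) {
      if (pos[j] == 0L) res[1] <- res[1] + mods[j] else res[pos[j]] <- res[pos[j]] + mods[j]
    }
  }
  cumsum(unname(res))
}

#' Theoretical fragment m/z values
#'
#' Fragment conventions: b = prefix; y = suffix + water; c = b + NH3;
#' z = z-dot radical (y - NH3 + H). `glycan_prefix`/`glycan_suffix` add a
#' glycan mass to the prefix (c/b) or suffix (z/y) fragments, used when
#' glycans are retained on electron-activation fragments.
#'
#' @param sequence Peptide sequence.
#' @param type `"b"`, `"y"`, `"c"` or `"z"`.
#' @param charge Product charge (1 or 2).
#' @param mods Named numeric vector of mod deltas by position.
#' @param glycan_prefix,glycan_suffix Extra neutral mass (Da) carried by
#'   prefix / suffix fragments.
#' @return Numeric vector of m/z for fragment lengths `1..L-1` (prefix types)
#'   or `L-1..1` aligned to cleavage position (suffix types are returned so
#'   that element `i` is the fragment complementary to prefix length `i`).
#' @export
fragment_mz <- function(sequence, type = c("b", "y", "c", "z"), charge = 1L,
                        mods = NULL, glycan_prefix = 0, glycan_suffix = 0) {
  type <- match.arg(type)
  pre <- .prefix_masses(sequence, mods)
  L <- length(pre)
  total <- pre[L]
  ppos <- pre[seq_len(L - 1L)]          # prefix of length i, i = 1..L-1
  spos <- total - ppos                  # suffix complementary to prefix i
  neutral <- switch(type,
    b = ppos + glycan_prefix,
    c = ppos + NH3_MASS + glycan_prefix,
    y = spos + WATER_MASS + glycan_suffix,
    z = spos + WATER_MASS - NH3_MASS + .ELEMENT_MASS[["H"]] + glycan_suffix)
  (neutral + charge * PROTON_MASS) / charge
}

#' Match theoretical m/z values against spectrum peaks
#'
#' @param theo Theoretical m/z vector.
#' @param mz Sorted spectrum m/z vector.
#' @param tol_ppm Tolerance in ppm of the theoretical value.
#' @return Integer vector: index into `mz` of the nearest peak within
#'   tolerance, or `NA`.
#' @export
match_peaks <- function(theo, mz, tol_ppm) {
  if (!length(mz)) return(rep(NA_integer_, length(theo)))
  idx <- findInterval(theo, mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mz))
  d_lo <- abs(mz[lo] - theo)
  d_hi <- abs(mz[hi] - theo)
  best <- ifelse(d_lo <= d_hi, lo, hi)
  d <- pmin(d_lo, d_hi)
  ok <- d <= theo * tol_ppm * 1e-6
  out <- ifelse(ok, best, NA_integer_)
  as.integer(out)
}
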