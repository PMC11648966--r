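## Monoisotopic mass bookkeeping: elements, amino acid residues, and the
## monosaccharide registry. All residue masses are derived from elemental
## formulas rather than hard-coded, so printed diagnostic-ion m/z values can
## serve as regression checks.

.ELEMENT_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' Physical constants used throughout
#'
#' Monoisotopic masses in Da: the proton (charge carrier), water and ammonia
#' (terminal/fragment adjustments).
#' @keywords internal
PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565
NH3_MASS <- 17.0265491

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style formula such as `"C8H13NO5"` and sums monoisotopic
#' element masses. Supported elements: C, H, N, O, S, P.
#'
#' @param formula Character formula, e.g. `"C6H10O5"`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O")      # 18.010565
#' formula_mass("C6H10O5")  # hexose residue
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("malformed elemental formula: ", formula)
  }
  total <- 0
  for (tok in toks) {
    el <- sub("[0-9]+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.ELEMENT_MASS)) {
      stop("unknown element '", el, "' in formula ", formula)
    }
    total <- total + .ELEMENT_MASS[[el]] * n
  }
  total
}

## Amino acid residue formulas (residue = amino acid minus water).
.AA_FORMULA <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

.AA_MASS <- local({
  v <- vapply(.AA_FORMULA, formula_mass, numeric(1))
  names(v) <- names(.AA_FORMULA)
  v
})

#' Neutral monoisotopic peptide mass
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @param mods Optional numeric vector of modification mass deltas (Da) named
#'   by 1-based residue position; `"0"` denotes the N-terminus.
#' @return Neutral monoisotopic mass in Da (residues + water + mods).
#' @export
peptide_mass <- function(sequence, mods = NULL) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(aa %in% names(.AA_MASS))) {
    stop("unknown residue(s) in '", sequence, "': ",
         paste(setdiff(aa, names(.AA_MASS)), collapse = ","))
  }
  m <- sum(.AA_MASS[aa]) + WATER_MASS
  if (length(mods)) m <- m + sum(mods)
  m
}

## ---- monosaccharide registry ------------------------------------------------

.DEFAULT_MONOSACCHARIDES <- data.frame(
  name = c("HexNAc", "Hex", "Fuc", "NeuAc", "NeuGc", "Pent", "Phospho", "Sulfo"),
  formula = c("C8H13NO5", "C6H10O5", "C6H10O4", "C11H17NO8", "C11H17NO9",
              "C5H8O4", "HPO3", "SO3"),
  stringsAsFactors = FALSE
)

#' The monosaccharide registry
#'
#' Returns the table of monosaccharide (and small-modification) residue codes
#' the glycan machinery understands: a `name`, an elemental `formula`, and a
#' monoisotopic `mass` (Da, residue mass — the mass a unit adds to a peptide).
#' Additional residues can be appended from a two-column TSV
#' (`name<TAB>formula`) via `extra_tsv`.
#'
#' @param extra_tsv Optional path to a TSV of extra residues (no header),
#'   columns name and elemental formula.
#' @return data.frame with columns `name`, `formula`, `mass`.
#' @examples
#' monosaccharide_registry()
#' @export
monosaccharide_registry <- function(extra_tsv = NULL) {
  reg <- .DEFAULT_MONOSACCHARIDES
  if (!is.null(extra_tsv)) {
    ext <- utils::read.table(extra_tsv, sep = "\t", header = FALSE,
                             col.names = c("name", "formula"),
                             stringsAsFactors = FALSE, comment.char = "#")
    reg <- rbind(reg, ext)
  }
  if (anyDuplicated(reg$name)) {
    stop("duplicate monosaccharide name(s) in registry: ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ","))
  }
  reg$mass <- vapply(reg$formula, formula_mass, numeric(1), USE.NAMES = FALSE)
  reg
}
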