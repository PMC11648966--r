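# Fixtures are built in code: tiny glycan databases, peptide spectra with
# exact theoretical ladders, and small FASTA files.

reg <- glycopair::monosaccharide_registry()

write_tmp_db <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

tiny_db <- function(lines = c("HexNAc(1)", "Hex(1)")) {
  parse_glycan_database(write_tmp_db(lines), reg)
}

write_tmp_fasta <- function(seqs, ids = sprintf("prot%02d", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# Spectrum containing exactly the given m/z values (plus optional extras),
# equal intensities unless given.
peaks_spectrum <- function(mz, intensity = rep(100, length(mz)), scan_id = 1L,
                          precursor_mz = 500, charge = 2L,
                          activation = "EThcD") {
  spectrum(scan_id, 2L, activation = activation, precursor_mz = precursor_mz,
           precursor_charge = charge, mz = mz, intensity = intensity)
}

# Complete singly charged ladder of a given type for a naked peptide.
full_ladder <- function(sequence, types = c("b", "y"), charges = 1L,
                        mods = NULL) {
  unlist(lapply(types, function(ty)
    unlist(lapply(charges, function(z) fragment_mz(sequence, ty, z, mods)))))
}

# A random localization test instance: peptide, box, scan with a random
# subset of true-assignment c/z ions plus decoy peaks.
random_loc_instance <- function(db, max_sites = 5, max_glycans = 3) {
  repeat {
    L <- sample(6:14, 1)
    aa <- sample(c("A", "G", "L", "P", "K", "E", "V", "S", "T"), L,
                 replace = TRUE, prob = c(1, 1, 1, 1, 1, 1, 1, 1.5, 1.5))
    sites <- which(aa %in% c("S", "T"))
    if (length(sites) >= 1 && length(sites) <= max_sites) break
  }
  sequence <- paste(aa, collapse = "")
  n_gly <- sample(seq_len(min(length(sites), max_glycans)), 1)
  occ <- sort(sample(sites, n_gly))
  glycans <- sample(length(db$entries), n_gly, replace = TRUE)
  box <- list(idx = sort(glycans), n_glycans = n_gly,
              mass = sum(db$mass[glycans]))
  # true-assignment c/z ions, each kept with probability 0.6
  gp <- function(i) sum(db$mass[glycans[occ <= i]])
  mz <- numeric(0)
  for (z in 1:2) {
    for (i in seq_len(L - 1)) {
      if (stats::runif(1) < 0.6) {
        mz <- c(mz, fragment_mz(sequence, "c", z, glycan_prefix = gp(i))[i])
      }
      if (stats::runif(1) < 0.6) {
        mz <- c(mz, fragment_mz(sequence, "z", z,
                                glycan_suffix = box$mass - gp(i))[i])
      }
    }
  }
  mz <- c(mz, stats::runif(5, 150, 2000))  # unmatched noise
  list(sequence = sequence, box = box, occ = occ, glycans = glycans,
       scan = peaks_spectrum(mz))
}
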