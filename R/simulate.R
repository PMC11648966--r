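## Ground-truth synthetic paired-scan glycopeptide runs. Emulates
## HCD-pd-EThcD acquisition: per glycopeptide one collisional scan (naked
## b/y ladder + oxonium ions, glycans dissociated) and one electron-activation
## scan (c/z-dot ladder with glycans retained at the true sites), interleaved
## between MS1 scans, with ppm jitter, peak dropout and random noise peaks.

#' Simulation configuration
#'
#' @param seed Integer; fixes all randomness end-to-end.
#' @param n_glycopeptides Number of simulated glycopeptide precursors.
#' @param fasta `"random"` (generate `n_proteins` random proteins) or a path
#'   to a FASTA to draw tryptic peptides from.
#' @param n_proteins,protein_length Random-proteome shape.
#' @param glycan_db Path to a glycan composition database (default: the
#'   bundled 12-composition O-glycan set).
#' @param max_glycans_per_peptide Cap on glycans per peptide.
#' @param site_occupancy Probability that each S/T carries a glycan.
#' @param detection_prob Probability each theoretical fragment ion is
#'   observed (applies to both scans, each charge state independently).
#' @param ppm_jitter_sd Gaussian m/z jitter, ppm (0 = exact masses).
#' @param noise_peaks Uniform random noise peaks added per MS2 scan.
#' @param oxonium_emission Emit composition-implied oxonium ions in the
#'   collisional scan?
#' @param pairing_order `"hcd_first"` or `"etd_first"`.
#' @param pairs_per_block MS2 scan pairs between consecutive MS1 scans.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_glycopeptides = 50L, fasta = "random",
                       n_proteins = 20L, protein_length = c(150L, 400L),
                       glycan_db = NULL, max_glycans_per_peptide = 3L,
                       site_occupancy = 0.5, detection_prob = 1.0,
                       ppm_jitter_sd = 0, noise_peaks = 0L,
                       oxonium_emission = TRUE,
                       pairing_order = c("hcd_first", "etd_first"),
                       pairs_per_block = 3L) {
  stopifnot(site_occupancy >= 0, site_occupancy <= 1,
            detection_prob >= 0, detection_prob <= 1, ppm_jitter_sd >= 0)
  if (is.null(glycan_db)) {
    glycan_db <- system.file("extdata", "oglycan_db_12.txt",
                             package = "glycopair")
  }
  structure(list(seed = as.integer(seed),
                 n_glycopeptides = as.integer(n_glycopeptides), fasta = fasta,
                 n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 glycan_db = glycan_db,
                 max_glycans_per_peptide = as.integer(max_glycans_per_peptide),
                 site_occupancy = site_occupancy,
                 detection_prob = detection_prob,
                 ppm_jitter_sd = ppm_jitter_sd,
                 noise_peaks = as.integer(noise_peaks),
                 oxonium_emission = oxonium_emission,
                 pairing_order = match.arg(pairing_order),
                 pairs_per_block = as.integer(pairs_per_block)),
            class = "sim_config")
}

## Amino acid alphabet with rough natural frequencies; S/T enriched a little
## so tryptic peptides usually carry candidate glycosites.
.AA_POOL <- c(A = 8, R = 6, N = 4, D = 5, C = 1, E = 6, Q = 4, G = 7, H = 2,
              I = 5, L = 9, K = 7, M = 2, F = 4, P = 4, S = 9, T = 8, V = 6,
              W = 1, Y = 3)

#' Generate a random protein FASTA
#'
#' @param path Output FASTA path.
#' @param n_proteins Number of proteins.
#' @param length_range Min/max protein length.
#' @return `path`, invisibly. Randomness comes from the current RNG state.
#' @export
random_fasta <- function(path, n_proteins = 20L, length_range = c(150L, 400L)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in seq_len(n_proteins)) {
    len <- sample(length_range[1]:length_range[2], 1L)
    aa <- sample(names(.AA_POOL), len, replace = TRUE, prob = .AA_POOL)
    writeLines(c(sprintf(">sim_prot_%03d synthetic", p),
                 paste(aa, collapse = "")), con)
  }
  invisible(path)
}

.jitter <- function(mz, ppm_sd) {
  if (ppm_sd <= 0) return(mz)
  mz * (1 + stats::rnorm(length(mz), 0, ppm_sd * 1e-6))
}

.lognorm_intensity <- function(n) exp(stats::rnorm(n, 0, 0.5)) * 100

## Oxonium ions implied by a total composition (the bundled diagnostic set).
.oxonium_peaks <- function(comp, registry) {
  mz <- numeric(0)
  cnt <- function(x) if (x %in% names(comp)) comp[[x]] else 0L
  if (cnt("HexNAc") >= 1L) {
    hx <- parse_composition("HexNAc(1)", registry)
    mz <- c(mz, oxonium_mz(hx, FALSE, registry), oxonium_mz(hx, TRUE, registry))
  }
  if (cnt("Hex") >= 1L) {
    h <- parse_composition("Hex(1)", registry)
    mz <- c(mz, oxonium_mz(h, FALSE, registry), oxonium_mz(h, TRUE, registry))
  }
  if (cnt("HexNAc") >= 1L && cnt("Hex") >= 1L) {
    hh <- parse_composition("HexNAc(1)Hex(1)", registry)
    mz <- c(mz, oxonium_mz(hh, FALSE, registry))
  }
  if (cnt("NeuAc") >= 1L) {
    na_ <- parse_composition("NeuAc(1)", registry)
    mz <- c(mz, oxonium_mz(na_, FALSE, registry), oxonium_mz(na_, TRUE, registry))
  }
  if (cnt("NeuGc") >= 1L) {
    ng <- parse_composition("NeuGc(1)", registry)
    mz <- c(mz, oxonium_mz(ng, FALSE, registry), oxonium_mz(ng, TRUE, registry))
  }
  mz
}

#' Simulate a paired-scan glycopeptide run with ground truth
#'
#' Draws tryptic peptides bearing S/T sites from the (random or given)
#' proteome, places glycans at sampled sites, and writes interleaved
#' MS1 / paired-MS2 scans plus a ground-truth TSV. With `hexose_free = TRUE`
#' only Hex-free database compositions are planted (an entrapment-style run:
#' the spectra then also lack the 145.05/163.06/366.14 ions).
#'
#' @param config A `sim_config`.
#' @param run_path Output run file (`.mgf` or `.mzML` by extension).
#' @param truth_path Output ground-truth TSV.
#' @param hexose_free Plant only hexose-free glycans?
#' @return Invisibly, a list with the run (list of spectra), the truth
#'   data.frame, and the FASTA path used.
#' @export
simulate_run <- function(config, run_path, truth_path = NULL,
                         hexose_free = FALSE) {
  set.seed(config$seed)
  registry <- monosaccharide_registry()
  db <- parse_glycan_database(config$glycan_db, registry)
  allowed <- seq_along(db$entries)
  if (hexose_free) {
    has_hex <- vapply(db$entries, function(e)
      "Hex" %in% names(e) && e[["Hex"]] > 0L, logical(1))
    allowed <- allowed[!has_hex]
    if (!length(allowed)) stop("no hexose-free compositions in database")
  }
  fasta <- config$fasta
  if (identical(fasta, "random")) {
    fasta <- file.path(tempdir(),
                       sprintf("glycopair_sim_%d.fasta", config$seed))
    random_fasta(fasta, config$n_proteins, config$protein_length)
  }
  spec <- digestion_spec(enzyme = "trypsin", specificity = "full",
                         max_missed_cleavages = 0L, min_length = 7L,
                         max_length = 22L)
  peps <- digest(fasta, spec, decoy_mode = "none")
  peps <- peps[peps$n_sites >= 1L & !grepl("[CW]", peps$sequence), ,
               drop = FALSE]
  if (!nrow(peps)) stop("proteome yielded no glycosylatable peptides")
  run <- list()
  truth <- list()
  scan_id <- 0L
  new_ms1 <- function() {
    scan_id <<- scan_id + 1L
    spectrum(scan_id, 1L, mz = c(400, 800, 1200), intensity = c(10, 20, 10),
             retention_time = scan_id)
  }
  run[[1]] <- new_ms1()
  attempts <- 0L
  g <- 0L
  while (g < config$n_glycopeptides) {
    attempts <- attempts + 1L
    if (attempts > 50L * config$n_glycopeptides) {
      stop("could not place glycans on sampled peptides; ",
           "check occupancy/database settings")
    }
    row <- peps[sample(nrow(peps), 1L), ]
    sites <- which(strsplit(row$sequence, "", fixed = TRUE)[[1]] %in% c("S", "T"))
    occ <- sites[stats::runif(length(sites)) < config$site_occupancy]
    if (!length(occ)) occ <- sites[sample.int(length(sites), 1L)]
    if (length(occ) > config$max_glycans_per_peptide) {
      occ <- sort(occ[sample.int(length(occ),
                                 config$max_glycans_per_peptide)])
    }
    glycans <- sample(allowed, length(occ), replace = TRUE)
    g <- g + 1L
    comp_total <- db$entries[[glycans[1]]]
    if (length(glycans) > 1L) {
      for (gi in glycans[-1]) comp_total <- add_compositions(comp_total, db$entries[[gi]])
    }
    box_mass <- sum(db$mass[glycans])
    pep_mass <- row$mass
    z <- sample(2:4, 1L, prob = c(2, 2, 1))
    prec_mz <- (pep_mass + box_mass + z * PROTON_MASS) / z
    # --- collisional scan: naked b/y + oxonium + precursor residual
    mz1 <- numeric(0)
    for (ty in c("b", "y")) for (zz in 1:2) {
      th <- fragment_mz(row$sequence, ty, zz)
      th <- th[stats::runif(length(th)) < config$detection_prob]
      mz1 <- c(mz1, th)
    }
    if (config$oxonium_emission) {
      mz1 <- c(mz1, .oxonium_peaks(comp_total, registry))
    }
    mz1 <- c(mz1, prec_mz)
    int1 <- .lognorm_intensity(length(mz1))
    if (config$oxonium_emission) {
      # oxonium ions are prominent in collisional scans of glycopeptides
      n_ox <- length(.oxonium_peaks(comp_total, registry))
      if (n_ox) {
        ox_pos <- length(mz1) - n_ox:1  # positions just before the residual
        int1[ox_pos] <- int1[ox_pos] + 150
      }
    }
    if (config$noise_peaks > 0L) {
      mz1 <- c(mz1, stats::runif(config$noise_peaks, 120, prec_mz * z))
      int1 <- c(int1, exp(stats::rnorm(config$noise_peaks, -2, 0.5)) * 100)
    }
    mz1 <- .jitter(mz1, config$ppm_jitter_sd)
    # --- electron-activation scan: c/z-dot with glycans at true sites
    glyco_prefix <- function(i) sum(db$mass[glycans[occ <= i]])
    mz2 <- numeric(0)
    Lp <- nchar(row$sequence)
    for (zz in 1:2) {
      for (i in seq_len(Lp - 1L)) {
        gp <- glyco_prefix(i)
        gs <- box_mass - gp
        cc <- fragment_mz(row$sequence, "c", zz, glycan_prefix = gp)[i]
        zzv <- fragment_mz(row$sequence, "z", zz, glycan_suffix = gs)[i]
        if (stats::runif(1) < config$detection_prob) mz2 <- c(mz2, cc)
        if (stats::runif(1) < config$detection_prob) mz2 <- c(mz2, zzv)
      }
    }
    mz2 <- c(mz2, prec_mz)
    int2 <- .lognorm_intensity(length(mz2))
    if (config$noise_peaks > 0L) {
      mz2 <- c(mz2, stats::runif(config$noise_peaks, 120, prec_mz * z))
      int2 <- c(int2, exp(stats::rnorm(config$noise_peaks, -2, 0.5)) * 100)
    }
    mz2 <- .jitter(mz2, config$ppm_jitter_sd)
    acts <- if (config$pairing_order == "hcd_first") c("HCD", "EThcD")
            else c("EThcD", "HCD")
    peaks <- if (config$pairing_order == "hcd_first") list(list(mz1, int1), list(mz2, int2))
             else list(list(mz2, int2), list(mz1, int1))
    ids <- integer(2)
    for (k in 1:2) {
      scan_id <- scan_id + 1L
      ids[k] <- scan_id
      run[[length(run) + 1L]] <- spectrum(
        scan_id, 2L, activation = acts[k], precursor_mz = prec_mz,
        precursor_charge = z, retention_time = scan_id,
        mz = peaks[[k]][[1]], intensity = peaks[[k]][[2]])
    }
    hcd_id <- ids[if (config$pairing_order == "hcd_first") 1 else 2]
    etd_id <- ids[if (config$pairing_order == "hcd_first") 2 else 1]
    aa <- strsplit(row$sequence, "", fixed = TRUE)[[1]]
    truth[[g]] <- data.frame(
      hcd_scan = hcd_id, etd_scan = etd_id, peptide = row$sequence,
      protein = row$protein_ids, peptide_start = row$start, charge = z,
      precursor_mz = prec_mz,
      glycan_box = paste(sort(db$text[glycans]), collapse = ";"),
      site_assignment = paste(sprintf("%s%d:%s", aa[occ], occ,
                                      db$text[glycans]), collapse = "; "),
      n_glycans = length(glycans), n_sites = length(sites),
      stringsAsFactors = FALSE)
    if (g %% config$pairs_per_block == 0L) {
      run[[length(run) + 1L]] <- new_ms1()
    }
  }
  if (run[[length(run)]]$ms_level != 1L) run[[length(run) + 1L]] <- new_ms1()
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(hcd_scan = integer(0), etd_scan = integer(0),
               peptide = character(0), protein = character(0),
               peptide_start = integer(0), charge = integer(0),
               precursor_mz = numeric(0), glycan_box = character(0),
               site_assignment = character(0), n_glycans = integer(0),
               n_sites = integer(0), stringsAsFactors = FALSE)
  ext <- tolower(tools::file_ext(run_path))
  if (ext == "mgf") write_mgf(run, run_path) else write_mzml(run, run_path)
  if (!is.null(truth_path)) {
    utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(run = run, truth = truth_df, fasta = fasta))
}

#' Entrapment-style run with hexose-free ground truth
#'
#' Convenience wrapper: all planted glycans lack hexose and the collisional
#' scans therefore carry no Hex-diagnostic oxonium ions, so searching with a
#' hexose-containing database plus the default oxonium rules should report
#' no hexose-containing glycopeptides.
#'
#' @inheritParams simulate_run
#' @export
make_entrapment_run <- function(config, run_path, truth_path = NULL) {
  simulate_run(config, run_path, truth_path, hexose_free = TRUE)
}
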