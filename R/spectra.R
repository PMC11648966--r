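## Spectrum records, MGF and mzML reading/writing, base-peak normalization,
## and collisional/electron-activation scan pairing.

#' Construct a spectrum record
#'
#' @param scan_id Integer scan number.
#' @param ms_level 1 or 2.
#' @param activation One of `"HCD"`, `"ETD"`, `"EThcD"`, `"EAD"`, `"unknown"`.
#' @param precursor_mz Precursor m/z (MS2 only; `NA` for MS1).
#' @param precursor_charge Integer charge or `NA` when unknown.
#' @param retention_time Seconds.
#' @param mz,intensity Numeric peak vectors (sorted ascending by m/z on
#'   construction).
#' @return List of class `glyco_spectrum`.
#' @export
spectrum <- function(scan_id, ms_level, activation = "unknown",
                     precursor_mz = NA_real_, precursor_charge = NA_integer_,
                     retention_time = NA_real_, mz = numeric(0),
                     intensity = numeric(0)) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  if (ms_level == 2L && (is.na(precursor_mz) || precursor_mz <= 0)) {
    stop("MS2 scan ", scan_id, " lacks a positive precursor m/z")
  }
  structure(list(scan_id = as.integer(scan_id), ms_level = as.integer(ms_level),
                 activation = activation, precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 retention_time = retention_time, mz = mz,
                 intensity = intensity),
            class = "glyco_spectrum")
}

#' @export
print.glyco_spectrum <- function(x, ...) {
  cat(sprintf("scan %d MS%d %s  %d peaks", x$scan_id, x$ms_level,
              x$activation, length(x$mz)))
  if (x$ms_level == 2L) {
    cat(sprintf("  precursor %.4f z=%s", x$precursor_mz,
                ifelse(is.na(x$precursor_charge), "?", x$precursor_charge)))
  }
  cat("\n")
  invisible(x)
}

#' Base-peak normalized intensities
#'
#' Divides intensities by the maximum so the base peak is 1.0; this is the
#' relative-intensity scale on which oxonium-ion thresholds are stated.
#'
#' @param spec A `glyco_spectrum` with at least one peak.
#' @return Numeric vector of relative intensities in `[0, 1]`, parallel to
#'   `spec$mz`.
#' @export
base_peak_normalize <- function(spec) {
  if (!length(spec$mz)) stop("cannot normalize an empty spectrum")
  spec$intensity / max(spec$intensity)
}

## ---- MGF --------------------------------------------------------------------

#' Read an MGF peak list
#'
#' Dialect: `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`, `CHARGE`,
#' `RTINSECONDS`, optional `SCANS` and `ACTIVATION=HCD|ETD|EThcD|EAD` headers,
#' then `m/z intensity` lines. MGF carries MS2 scans only. Lines between
#' blocks starting with `# MS1 SCAN=<id>` (an extension written by
#' [write_mgf()]) are read back as peakless MS1 boundary markers so that
#' pairing blocks survive an MGF round-trip.
#'
#' @param path MGF file path.
#' @return List of `glyco_spectrum` in file order.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  run <- list()
  i <- 1L
  n <- length(lines)
  auto_id <- 0L
  while (i <= n) {
    line <- trimws(lines[i])
    if (startsWith(line, "# MS1 SCAN=")) {
      id <- as.integer(sub("# MS1 SCAN=", "", line, fixed = TRUE))
      run[[length(run) + 1L]] <- spectrum(id, 1L)
      i <- i + 1L
    } else if (line == "BEGIN IONS") {
      hdr <- list(pepmass = NA_real_, charge = NA_integer_, rt = NA_real_,
                  scan = NA_integer_, activation = "unknown", title = "")
      mz <- numeric(0)
      int <- numeric(0)
      i <- i + 1L
      while (i <= n && trimws(lines[i]) != "END IONS") {
        l <- trimws(lines[i])
        if (grepl("^PEPMASS=", l)) {
          hdr$pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", l), "[ \t]")[[1]][1])
        } else if (grepl("^CHARGE=", l)) {
          hdr$charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", l)))
        } else if (grepl("^RTINSECONDS=", l)) {
          hdr$rt <- as.numeric(sub("^RTINSECONDS=", "", l))
        } else if (grepl("^SCANS=", l)) {
          hdr$scan <- as.integer(sub("^SCANS=", "", l))
        } else if (grepl("^ACTIVATION=", l)) {
          hdr$activation <- sub("^ACTIVATION=", "", l)
        } else if (grepl("^TITLE=", l)) {
          hdr$title <- sub("^TITLE=", "", l)
        } else if (grepl("^[0-9]", l)) {
          xy <- as.numeric(strsplit(l, "[ \t]+")[[1]][1:2])
          mz <- c(mz, xy[1])
          int <- c(int, xy[2])
        }
        i <- i + 1L
      }
      i <- i + 1L  # skip END IONS
      auto_id <- auto_id + 1L
      if (is.na(hdr$pepmass)) {
        stop("MGF block ", auto_id, " (", hdr$title, ") lacks PEPMASS")
      }
      run[[length(run) + 1L]] <- spectrum(
        scan_id = if (is.na(hdr$scan)) auto_id else hdr$scan,
        ms_level = 2L, activation = hdr$activation,
        precursor_mz = hdr$pepmass, precursor_charge = hdr$charge,
        retention_time = hdr$rt, mz = mz, intensity = int)
    } else {
      i <- i + 1L
    }
  }
  run
}

#' Write a run to MGF
#'
#' MS2 scans become `BEGIN IONS` blocks (with `SCANS`, `PEPMASS`, `CHARGE`,
#' `RTINSECONDS` and `ACTIVATION` headers); MS1 scans are written as
#' `# MS1 SCAN=<id>` comment markers so block boundaries used by scan pairing
#' round-trip.
#'
#' @param run List of `glyco_spectrum`.
#' @param path Output path.
#' @export
write_mgf <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in run) {
    if (s$ms_level == 1L) {
      writeLines(sprintf("# MS1 SCAN=%d", s$scan_id), con)
      next
    }
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=scan_%d", s$scan_id), con)
    writeLines(sprintf("SCANS=%d", s$scan_id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$precursor_charge)) {
      writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    }
    if (!is.na(s$retention_time)) {
      writeLines(sprintf("RTINSECONDS=%.3f", s$retention_time), con)
    }
    if (s$activation != "unknown") {
      writeLines(sprintf("ACTIVATION=%s", s$activation), con)
    }
    if (length(s$mz)) {
      writeLines(sprintf("%.6f %.6g", s$mz, s$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

## ---- mzML (via mzR) ---------------------------------------------------------

.activation_from_filter <- function(fs) {
  if (is.na(fs) || !nzchar(fs)) return("unknown")
  l <- tolower(fs)
  if (grepl("etd", l) && grepl("hcd", l)) "EThcD"
  else if (grepl("sa", l) && grepl("etd", l)) "EThcD"
  else if (grepl("etd", l)) "ETD"
  else if (grepl("ead", l)) "EAD"
  else if (grepl("hcd", l)) "HCD"
  else "unknown"
}

#' Read an mzML run
#'
#' Centroided spectra are read with \pkg{mzR}; activation is inferred from the
#' Thermo-style filter string when present (tokens `hcd`, `etd`, `sa`, `ead`),
#' else reported as `"unknown"`.
#'
#' @param path mzML file.
#' @return List of `glyco_spectrum` in acquisition order.
#' @export
read_mzml <- function(path) {
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  run <- vector("list", nrow(h))
  for (i in seq_len(nrow(h))) {
    pk <- mzR::peaks(f, i)
    ch <- h$precursorCharge[i]
    run[[i]] <- spectrum(
      scan_id = h$acquisitionNum[i], ms_level = h$msLevel[i],
      activation = if (h$msLevel[i] == 2L)
        .activation_from_filter(h$filterString[i]) else "unknown",
      precursor_mz = if (h$msLevel[i] == 2L) h$precursorMZ[i] else NA_real_,
      precursor_charge = if (!is.na(ch) && ch > 0) as.integer(ch) else NA_integer_,
      retention_time = h$retentionTime[i],
      mz = pk[, 1], intensity = pk[, 2])
  }
  run
}

#' Write a run to mzML (via mzR)
#'
#' Activation is encoded in a Thermo-style filter string so that
#' [read_mzml()] recovers it.
#'
#' @param run List of `glyco_spectrum`.
#' @param path Output path.
#' @export
write_mzml <- function(run, path) {
  n <- length(run)
  pks <- vector("list", n)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = integer(n), msLevel = integer(n),
    polarity = rep(1L, n), peaksCount = integer(n), totIonCurrent = numeric(n),
    retentionTime = numeric(n), basePeakMZ = numeric(n),
    basePeakIntensity = numeric(n), collisionEnergy = numeric(n),
    ionisationEnergy = numeric(n), lowMZ = numeric(n), highMZ = numeric(n),
    precursorScanNum = integer(n), precursorMZ = numeric(n),
    precursorCharge = integer(n), precursorIntensity = numeric(n),
    mergedScan = integer(n), mergedResultScanNum = integer(n),
    mergedResultStartScanNum = integer(n), mergedResultEndScanNum = integer(n),
    injectionTime = numeric(n), filterString = character(n),
    spectrumId = character(n), centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n), stringsAsFactors = FALSE)
  last_ms1 <- 0L
  for (i in seq_len(n)) {
    s <- run[[i]]
    pks[[i]] <- cbind(mz = s$mz, intensity = s$intensity)
    hdr$acquisitionNum[i] <- s$scan_id
    hdr$msLevel[i] <- s$ms_level
    hdr$peaksCount[i] <- length(s$mz)
    hdr$totIonCurrent[i] <- sum(s$intensity)
    hdr$retentionTime[i] <- if (is.na(s$retention_time)) i else s$retention_time
    hdr$basePeakMZ[i] <- if (length(s$mz)) s$mz[which.max(s$intensity)] else 0
    hdr$basePeakIntensity[i] <- if (length(s$mz)) max(s$intensity) else 0
    hdr$lowMZ[i] <- if (length(s$mz)) min(s$mz) else 0
    hdr$highMZ[i] <- if (length(s$mz)) max(s$mz) else 0
    hdr$spectrumId[i] <- sprintf("scan=%d", s$scan_id)
    if (s$ms_level == 1L) {
      last_ms1 <- s$scan_id
      hdr$filterString[i] <- "FTMS + p NSI Full ms"
      hdr$precursorMZ[i] <- NA_real_
      hdr$precursorCharge[i] <- NA_integer_
    } else {
      act <- switch(s$activation, HCD = "hcd25.00", ETD = "etd30.00",
                    EThcD = "etd30.00 sa hcd15.00", EAD = "ead10.00", "cid30.00")
      hdr$filterString[i] <- sprintf("FTMS + p NSI d Full ms2 %.4f@%s",
                                     s$precursor_mz, act)
      hdr$precursorScanNum[i] <- last_ms1
      hdr$precursorMZ[i] <- s$precursor_mz
      hdr$precursorCharge[i] <- if (is.na(s$precursor_charge)) 0L else s$precursor_charge
      hdr$precursorIntensity[i] <- 1000
      hdr$isolationWindowTargetMZ[i] <- s$precursor_mz
      hdr$isolationWindowLowerOffset[i] <- 0.8
      hdr$isolationWindowUpperOffset[i] <- 0.8
    }
  }
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a run in mzML or MGF format
#'
#' @param path Input file.
#' @param format `"mzML"`, `"MGF"` or `"auto"` (by extension).
#' @return List of `glyco_spectrum` in acquisition order.
#' @export
read_run <- function(path, format = c("auto", "mzML", "MGF")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzML", mgf = "MGF",
                     stop("cannot infer run format from extension '", ext, "'"))
  }
  if (format == "mzML") read_mzml(path) else read_mgf(path)
}

## ---- scan pairing -----------------------------------------------------------

.first_activation <- function(mode) switch(mode, hcd_first = c("HCD"),
                                           etd_first = c("ETD", "EThcD", "EAD"))
.second_activation <- function(mode) switch(mode, hcd_first = c("ETD", "EThcD", "EAD"),
                                            etd_first = c("HCD"))

#' Pair collisional with electron-activation MS2 scans
#'
#' Considers only MS2 scans lying between the same two consecutive MS1 scans
#' (the MS1 scans act as block boundaries). Within each block, each unpaired
#' scan of the first activation type is paired greedily with the earliest
#' subsequent unpaired scan of the second type whose precursor m/z matches
#' within `precursor_tol_ppm` (and whose charge matches when
#' `require_same_charge` and both charges are known). Each MS2 scan joins at
#' most one pair. In `single` mode every MS2 scan forms a pair with itself
#' (identification and localization use the same scan).
#'
#' @param run List of `glyco_spectrum` in acquisition order.
#' @param mode `"hcd_first"`, `"etd_first"` or `"single"`.
#' @param precursor_tol_ppm Pairing tolerance in ppm.
#' @param require_same_charge Require equal known charges?
#' @return List of pairs; each a list with `first` and `second`
#'   (`glyco_spectrum`; identical in single mode) and `mode`.
#' @export
pair_scans <- function(run, mode = c("hcd_first", "etd_first", "single"),
                       precursor_tol_ppm = 30, require_same_charge = TRUE) {
  mode <- match.arg(mode)
  pairs <- list()
  if (mode == "single") {
    for (s in run) {
      if (s$ms_level == 2L) {
        pairs[[length(pairs) + 1L]] <- list(first = s, second = s, mode = mode)
      }
    }
    return(pairs)
  }
  ftypes <- .first_activation(mode)
  stypes <- .second_activation(mode)
  is_ms1 <- vapply(run, function(s) s$ms_level == 1L, logical(1))
  block_id <- cumsum(is_ms1)
  idx2 <- which(!is_ms1)
  for (b in unique(block_id[idx2])) {
    blk <- idx2[block_id[idx2] == b]
    used <- logical(length(blk))
    for (a in seq_along(blk)) {
      s1 <- run[[blk[a]]]
      if (used[a] || !(s1$activation %in% ftypes)) next
      for (z in seq_along(blk)) {
        if (z <= a || used[z]) next
        s2 <- run[[blk[z]]]
        if (!(s2$activation %in% stypes)) next
        dmz <- abs(s2$precursor_mz - s1$precursor_mz)
        if (dmz > s1$precursor_mz * precursor_tol_ppm * 1e-6) next
        if (require_same_charge && !is.na(s1$precursor_charge) &&
            !is.na(s2$precursor_charge) &&
            s1$precursor_charge != s2$precursor_charge) next
        pairs[[length(pairs) + 1L]] <- list(first = s1, second = s2, mode = mode)
        used[a] <- TRUE
        used[z] <- TRUE
        break
      }
    }
  }
  pairs
}
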