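test_that("MGF round-trips peak lists, precursors and activation", {
  run <- list(
    spectrum(1L, 1L, mz = c(400, 500), intensity = c(1, 2)),
    spectrum(2L, 2L, "HCD", 812.3701, 2L, 10.0,
             mz = c(100.5, 200.25, 366.1395), intensity = c(5, 50, 10)),
    spectrum(3L, 2L, "EThcD", 812.3702, 2L, 10.5,
             mz = c(300.1, 400.2), intensity = c(7, 9)))
  path <- tempfile(fileext = ".mgf")
  write_mgf(run, path)
  back <- read_mgf(path)
  expect_length(back, 3L)
  expect_equal(vapply(back, `[[`, integer(1), "ms_level"), c(1L, 2L, 2L))
  expect_equal(back[[2]]$mz, run[[2]]$mz, tolerance = 1e-6)
  expect_equal(back[[2]]$intensity, run[[2]]$intensity, tolerance = 1e-6)
  expect_equal(back[[3]]$precursor_mz, 812.3702, tolerance = 1e-6)
  expect_identical(back[[2]]$activation, "HCD")
  expect_identical(back[[3]]$activation, "EThcD")
  expect_identical(back[[3]]$precursor_charge, 2L)
})

test_that("mzML round-trips through mzR with activation recovered", {
  run <- list(
    spectrum(1L, 1L, mz = c(400, 500), intensity = c(1, 2)),
    spectrum(2L, 2L, "HCD", 812.3701, 2L, 10.0,
             mz = c(100.5, 200.25), intensity = c(5, 50)),
    spectrum(3L, 2L, "EThcD", 812.3702, 2L, 10.5,
             mz = c(300.1, 400.2), intensity = c(7, 9)))
  path <- tempfile(fileext = ".mzML")
  write_mzml(run, path)
  back <- read_run(path)  # format inferred from extension
  expect_length(back, 3L)
  expect_equal(vapply(back, `[[`, integer(1), "ms_level"), c(1L, 2L, 2L))
  expect_equal(back[[2]]$mz, run[[2]]$mz, tolerance = 1e-6)
  expect_identical(back[[2]]$activation, "HCD")
  expect_identical(back[[3]]$activation, "EThcD")
  expect_equal(back[[3]]$precursor_mz, 812.3702, tolerance = 1e-5)
})

test_that("MGF requires PEPMASS and constructor rejects bad MS2", {
  path <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "100 5", "END IONS"), path)
  expect_error(read_mgf(path), "PEPMASS")
  expect_error(spectrum(1L, 2L, precursor_mz = NA), "precursor")
})

test_that("base-peak normalization scales the max to one", {
  s <- peaks_spectrum(c(100, 200), intensity = c(50, 100))
  expect_equal(base_peak_normalize(s), c(0.5, 1.0))
  expect_equal(base_peak_normalize(peaks_spectrum(300, intensity = 7)), 1.0)
  s3 <- peaks_spectrum(c(1, 2, 3), intensity = c(4, 4, 4))
  expect_equal(base_peak_normalize(s3), c(1, 1, 1))
  expect_error(base_peak_normalize(spectrum(1L, 1L)), "empty")
})

test_that("scan pairing follows MS1 block boundaries and precursor match", {
  ms1 <- function(id) spectrum(id, 1L, mz = 400, intensity = 1)
  hcd <- function(id, mz, z = 2L) spectrum(id, 2L, "HCD", mz, z, mz = 100, intensity = 1)
  etd <- function(id, mz, z = 2L) spectrum(id, 2L, "ETD", mz, z, mz = 100, intensity = 1)

  p <- pair_scans(list(ms1(1), hcd(2, 812.3701), etd(3, 812.3702), ms1(4)), "hcd_first", 20)
  expect_length(p, 1L)
  expect_identical(c(p[[1]]$first$scan_id, p[[1]]$second$scan_id), c(2L, 3L))

  # non-matching precursor: no pair
  expect_length(pair_scans(list(ms1(1), hcd(2, 812.37), etd(3, 900.0), ms1(4)),
                           "hcd_first", 20), 0L)

  # greedy skips the non-matching intermediate ETD
  p <- pair_scans(list(ms1(1), hcd(2, 812.37), etd(3, 500.0), etd(4, 812.37), ms1(5)),
                  "hcd_first", 20)
  expect_length(p, 1L)
  expect_identical(c(p[[1]]$first$scan_id, p[[1]]$second$scan_id), c(2L, 4L))

  # no pair across an MS1 boundary
  expect_length(pair_scans(list(ms1(1), hcd(2, 812.37), ms1(3), etd(4, 812.37), ms1(5)),
                           "hcd_first", 20), 0L)

  # charge mismatch blocks pairing only when required
  r <- list(ms1(1), hcd(2, 812.37, 2L), etd(3, 812.37, 3L), ms1(4))
  expect_length(pair_scans(r, "hcd_first", 20, require_same_charge = TRUE), 0L)
  expect_length(pair_scans(r, "hcd_first", 20, require_same_charge = FALSE), 1L)

  # etd-first mode reverses the roles
  p <- pair_scans(list(ms1(1), etd(2, 700.1), hcd(3, 700.1), ms1(4)), "etd_first", 20)
  expect_length(p, 1L)
  expect_identical(p[[1]]$first$scan_id, 2L)

  # single mode: every MS2 pairs with itself
  p <- pair_scans(list(ms1(1), etd(2, 700.1), etd(3, 800.1)), "single")
  expect_length(p, 2L)
  expect_identical(p[[1]]$first$scan_id, p[[1]]$second$scan_id)
})

test_that("pairing uses each MS2 scan at most once and is deterministic", {
  ms1 <- function(id) spectrum(id, 1L, mz = 400, intensity = 1)
  set.seed(42)
  for (rep in 1:10) {
    run <- list(ms1(1L))
    id <- 1L
    mzs <- round(runif(6, 400, 1200), 2)
    for (k in 1:6) {
      id <- id + 1L
      act <- sample(c("HCD", "ETD"), 1)
      run[[length(run) + 1L]] <- spectrum(id, 2L, act, sample(mzs, 1), 2L,
                                          mz = 100, intensity = 1)
      if (k %% 3 == 0) {
        id <- id + 1L
        run[[length(run) + 1L]] <- ms1(id)
      }
    }
    p1 <- pair_scans(run, "hcd_first", 20)
    p2 <- pair_scans(run, "hcd_first", 20)
    expect_identical(p1, p2)
    ids <- unlist(lapply(p1, function(x) c(x$first$scan_id, x$second$scan_id)))
    expect_identical(anyDuplicated(ids), 0L)
    for (x in p1) {
      expect_lte(abs(x$first$precursor_mz - x$second$precursor_mz),
                 x$first$precursor_mz * 20e-6)
    }
  }
})
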