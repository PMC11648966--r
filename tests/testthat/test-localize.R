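empty_scan <- function() peaks_spectrum(numeric(0), numeric(0))

setup_db <- local({
  db2 <- NULL
  function() {
    if (is.null(db2)) db2 <<- tiny_db(c("HexNAc(1)", "Hex(1)"))
    db2
  }
})

box_of <- function(db, idx) list(idx = sort(idx), n_glycans = length(idx),
                                 mass = sum(db$mass[idx]))

test_that("graph configuration counts match assignment combinatorics", {
  db <- setup_db()
  one <- box_of(db, 1L)
  # 1 glycan, 2 sites -> 2 configurations, uniform with an empty scan
  g <- build_graph("GASTAK", NULL, one, db, empty_scan())
  r <- localize(g)
  expect_equal(r$n_configurations, 2)
  expect_equal(unname(r$site_probabilities[, 1]), c(0.5, 0.5))
  expect_identical(r$level, "3")
  # two identical glycans on two sites -> forced single path, level 1b
  g2 <- build_graph("GASTAK", NULL, box_of(db, c(1L, 1L)), db, empty_scan())
  r2 <- localize(g2)
  expect_equal(r2$n_configurations, 1)
  expect_identical(r2$level, "1b")
  expect_equal(sum(r2$site_probabilities), 2)
  # two distinct glycans on two sites -> two configurations, none resolvable
  g2b <- build_graph("GASTAK", NULL, box_of(db, c(1L, 2L)), db, empty_scan())
  expect_equal(localize(g2b)$n_configurations, 2)
  # 2 distinct glycans, 3 sites -> 6 ordered injective assignments
  g3 <- build_graph("GSATSK", NULL, box_of(db, c(1L, 2L)), db, empty_scan())
  expect_equal(localize(g3)$n_configurations, 6)
  # infeasible box
  expect_error(build_graph("GASAAK", NULL, box_of(db, c(1L, 1L)), db,
                           empty_scan()), "infeasible")
})

test_that("one extra site-determining ion gives the 0.909 split at base 10", {
  db <- setup_db()
  one <- box_of(db, 1L)  # HexNAc
  hexnac <- db$mass[1]
  c1 <- fragment_mz("GASTAK", "c")                       # naked c ions
  cg <- fragment_mz("GASTAK", "c", glycan_prefix = hexnac)
  scan <- peaks_spectrum(c(c1[2], cg[3], cg[4]))  # naked c2, glyco c3, c4
  r <- localize(build_graph("GASTAK", NULL, one, db, scan))
  # S3 config matches 3 ions, T4 config 2 -> P(S3) = 10^3/(10^3+10^2)
  expect_equal(r$best_path_score, 3)
  expect_equal(unname(r$site_probabilities["S3", 1]), 1000 / 1100,
               tolerance = 1e-9)
  expect_identical(r$level, "1")
  expect_identical(names(r$best_assignment), "S3")
  expect_gte(r$n_site_determining, 1L)
})

test_that("single-site forced localization is level 1b by elimination", {
  db <- setup_db()
  r <- localize(build_graph("GASAAK", NULL, box_of(db, 1L), db, empty_scan()))
  expect_equal(unname(r$site_probabilities[1, 1]), 1.0)
  expect_equal(r$n_configurations, 1)
  expect_identical(r$level, "1b")
})

test_that("partial evidence yields level 2: one glycan pinned, one not", {
  db <- setup_db()
  hx <- which(db$text == "HexNAc(1)")
  box <- box_of(db, c(hx, which(db$text == "Hex(1)")))  # on sites S2,T4,S5
  scan <- peaks_spectrum(fragment_mz("GSATSK", "c",
                                     glycan_prefix = db$mass[hx])[2])
  r <- localize(build_graph("GSATSK", NULL, box, db, scan))
  # c2+HexNAc pins HexNAc to S2 (P=20/24); Hex splits between T4/S5
  expect_equal(unname(r$site_probabilities["S2", "HexNAc(1)"]), 20 / 24,
               tolerance = 1e-9)
  expect_lt(max(r$site_probabilities[, "Hex(1)"]), 0.75)
  expect_identical(r$level, "2")
})

test_that("probabilities conserve multiplicity and ignore unmatched noise", {
  db <- setup_db()
  set.seed(301)
  for (k in 1:25) {
    inst <- random_loc_instance(db)
    g <- build_graph(inst$sequence, NULL, inst$box, db, inst$scan)
    r <- localize(g)
    # per-entry site probabilities sum to the entry's multiplicity
    mult <- table(inst$box$idx)
    for (j in seq_along(r$entry)) {
      expect_equal(sum(r$site_probabilities[, j]),
                   as.integer(mult[as.character(r$entry[j])]),
                   tolerance = 1e-6)
    }
    # adding noise peaks that match no theoretical ion changes nothing
    noisy <- inst$scan
    noisy$mz <- c(noisy$mz, c(123.456, 1999.1, 2500.7))
    noisy$intensity <- c(noisy$intensity, c(5, 5, 5))
    o <- order(noisy$mz)
    noisy$mz <- noisy$mz[o]
    noisy$intensity <- noisy$intensity[o]
    r2 <- localize(build_graph(inst$sequence, NULL, inst$box, db, noisy))
    expect_equal(r2$site_probabilities, r$site_probabilities, tolerance = 1e-9)
  }
})

test_that("adding a site-determining ion for an assignment raises its probability", {
  db <- setup_db()
  one <- box_of(db, 1L)
  hexnac <- db$mass[1]
  cg <- fragment_mz("GASTAK", "c", glycan_prefix = hexnac)
  base <- peaks_spectrum(cg[3])              # one ion supporting S3
  two <- peaks_spectrum(c(cg[3], fragment_mz("GASTAK", "z",
                          glycan_suffix = hexnac)[2]))    # z4+glycan also S3
  p1 <- localize(build_graph("GASTAK", NULL, one, db, base))
  p2 <- localize(build_graph("GASTAK", NULL, one, db, two))
  expect_gte(p2$site_probabilities["S3", 1], p1$site_probabilities["S3", 1])
})

test_that("dynamic program agrees with the brute-force oracle", {
  db12 <- parse_glycan_database(
    system.file("extdata", "oglycan_db_12.txt", package = "glycopair"), reg)
  set.seed(77)
  for (k in 1:40) {
    inst <- random_loc_instance(db12, max_sites = 5, max_glycans = 3)
    g <- build_graph(inst$sequence, NULL, inst$box, db12, inst$scan)
    r_dp <- localize(g)
    r_bf <- brute_force_localize(inst$sequence, NULL, inst$box, db12,
                                 inst$scan)
    expect_equal(r_dp$best_path_score, r_bf$best_path_score)
    expect_equal(r_dp$site_probabilities, r_bf$site_probabilities,
                 tolerance = 1e-9)
    expect_identical(r_dp$level, r_bf$level)
    expect_equal(r_dp$n_configurations, r_bf$n_configurations)
  }
})

test_that("select_best_box prefers the box with more matched glyco ions", {
  db <- setup_db()
  hexnac <- db$mass[1]
  # precursor consistent with one HexNAc on GASTAK
  prec <- (peptide_mass("GASTAK") + hexnac + 2 * 1.007276) / 2
  scan2 <- peaks_spectrum(fragment_mz("GASTAK", "c", glycan_prefix = hexnac)[3:5],
                          scan_id = 2L, precursor_mz = prec)
  s1 <- peaks_spectrum(c(full_ladder("GASTAK"), 204.0867), precursor_mz = prec)
  # two artificial candidate boxes of nearly equal mass: HexNAc vs Hex
  psm <- list(sequence = "GASTAK", mods = NULL,
              candidate_boxes = list(box_of(db, 1L), box_of(db, 2L)))
  sel <- select_best_box(psm, list(first = s1, second = scan2, mode = "hcd_first"),
                         db, list(), search_params())
  expect_identical(sel$box$idx, 1L)   # the HexNAc box matches 3 glyco-c ions
  expect_identical(sel$result$level, "1")
  # all boxes removed by an impossible rule -> unassigned fallback
  strict <- list(list(residues = parse_composition("HexNAc(1)", reg),
                      ion_mzs = 999.999, min_intensity = 0.5),
                 list(residues = parse_composition("Hex(1)", reg),
                      ion_mzs = 998.0, min_intensity = 0.5))
  sel2 <- select_best_box(psm, list(first = s1, second = scan2, mode = "hcd_first"),
                          db, strict, search_params())
  expect_null(sel2$box)
  expect_identical(sel2$filtered_out, 2L)
})
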