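test_that("hyperscore counts ion series and matches the hand-computed formula", {
  # complete 1+ b/y ladder of PEPTIDE -> all 6 positions in both series
  s <- peaks_spectrum(full_ladder("PEPTIDE"))
  hs <- hyperscore(s, "PEPTIDE")
  expect_identical(c(hs$n_b, hs$n_y), c(6L, 6L))
  expect_gt(hs$score, 0)

  # no overlap -> score 0
  s0 <- peaks_spectrum(c(1000, 1100, 1200))
  expect_equal(hyperscore(s0, "PEPTIDE")$score, 0)

  # hand-built 3-peak oracle for GASK: b2 + y1 + y2 matched
  b <- fragment_mz("GASK", "b")
  y <- fragment_mz("GASK", "y")
  s3 <- peaks_spectrum(c(b[2], y[3], y[2]), intensity = c(30, 20, 10))
  # y vector index i is the fragment complementary to prefix i: y[3]=y1, y[2]=y2
  hs3 <- hyperscore(s3, "GASK")
  expect_identical(c(hs3$n_b, hs3$n_y), c(1L, 2L))
  expect_equal(hs3$score, log(1) + log(2) + log(30 * (20 + 10)),
               tolerance = 1e-9)
})

test_that("offset index groups boxes by combined mass and is searchable", {
  db <- tiny_db("HexNAc(1)")
  idx <- precompute_offset_index(db, 2)
  expect_equal(idx$mass, c(203.0794, 406.1587), tolerance = 1e-4)
  hit <- offset_lookup(idx, 406.1587, 10)
  expect_identical(length(hit), 1L)
  expect_identical(idx$boxes[[hit]][[1]]$idx, c(1L, 1L))
  expect_length(offset_lookup(idx, 1000, 10), 0L)
})

test_that("search_pair recovers a synthetic glycopeptide with its box", {
  db <- tiny_db(c("HexNAc(1)", "Hex(1)"))
  fa <- write_tmp_fasta("GASTAKGGGR")
  peps <- digest(fa, digestion_spec(min_length = 4, max_missed_cleavages = 0),
                 "none")
  idx <- index_peptides(peps)
  off <- precompute_offset_index(db, 2)
  hexnac <- db$mass[db$text == "HexNAc(1)"]
  prec <- (peptide_mass("GASTAK") + hexnac + 2 * 1.007276) / 2
  s1 <- peaks_spectrum(c(full_ladder("GASTAK"), 204.0867), scan_id = 10L,
                       precursor_mz = prec, activation = "HCD")
  s2 <- peaks_spectrum(fragment_mz("GASTAK", "c", glycan_prefix = hexnac),
                       scan_id = 11L, precursor_mz = prec)
  pair <- list(first = s1, second = s2, mode = "hcd_first")
  psm <- search_pair(pair, idx, off, search_params())
  expect_identical(psm$sequence, "GASTAK")
  expect_equal(psm$delta_mass, hexnac, tolerance = 1e-3)
  expect_identical(length(psm$candidate_boxes), 1L)
  expect_identical(psm$candidate_boxes[[1]]$idx,
                   which(db$text == "HexNAc(1)"))

  # a glycan-sized delta on a peptide without S/T yields nothing
  fa2 <- write_tmp_fasta("GAAAVLKGGGR")
  idx2 <- index_peptides(digest(fa2, digestion_spec(min_length = 4), "none"))
  prec2 <- (peptide_mass("GAAAVLK") + hexnac + 2 * 1.007276) / 2
  s1b <- peaks_spectrum(full_ladder("GAAAVLK"), precursor_mz = prec2)
  expect_null(search_pair(list(first = s1b, second = s1b, mode = "single"),
                          idx2, off, search_params()))

  # precursor mass matching nothing
  s1c <- peaks_spectrum(c(500, 600), precursor_mz = 2500.123)
  expect_null(search_pair(list(first = s1c, second = s1c, mode = "single"),
                          idx, off, search_params()))
})

test_that("non-glycosylated precursors match with an empty candidate box", {
  fa <- write_tmp_fasta("GASTAKGGGR")
  idx <- index_peptides(digest(fa, digestion_spec(min_length = 4), "none"))
  off <- precompute_offset_index(tiny_db("HexNAc(1)"), 2)
  prec <- (peptide_mass("GASTAK") + 2 * 1.007276) / 2
  s1 <- peaks_spectrum(full_ladder("GASTAK"), precursor_mz = prec)
  psm <- search_pair(list(first = s1, second = s1, mode = "single"), idx, off,
                     search_params())
  expect_identical(psm$sequence, "GASTAK")
  expect_length(psm$candidate_boxes, 0L)
  expect_lt(abs(psm$delta_mass), 0.01)
})

test_that("oxonium filter gates boxes by diagnostic ions in the first scan", {
  rules <- default_oxonium_rules()
  hex_comp <- parse_composition("HexNAc(1)Hex(1)", reg)
  # Hex ion present at 40% relative intensity, threshold 5% -> pass
  s <- peaks_spectrum(c(163.0601, 366.1395, 500), intensity = c(40, 40, 100))
  expect_true(oxonium_filter(s, hex_comp, rules))
  # NeuAc-containing box, no NeuAc ions -> fail
  neu_comp <- parse_composition("HexNAc(1)NeuAc(1)", reg)
  s2 <- peaks_spectrum(c(204.0867, 500), intensity = c(50, 100))
  expect_false(oxonium_filter(s2, neu_comp, rules))
  # HexNAc-only box: no applicable rule -> vacuous pass
  expect_true(oxonium_filter(s2, parse_composition("HexNAc(2)", reg), rules))
  # empty rule list is the identity
  expect_true(oxonium_filter(s2, neu_comp, list()))
  # sub-threshold summed intensity fails
  s3 <- peaks_spectrum(c(163.0601, 366.1395, 500), intensity = c(1, 1, 100))
  expect_false(oxonium_filter(s3, hex_comp, rules))
})

test_that("oxonium rule files parse and validate", {
  p <- tempfile()
  writeLines(c("# comment", "Hex(1)\t163.0601,145.0495\t0.10",
               "NeuAc(1)\t274.0921,292.1027"), p)
  rules <- read_oxonium_rules(p, default_min = 0.07)
  expect_length(rules, 2L)
  expect_equal(rules[[1]]$min_intensity, 0.10)
  expect_equal(rules[[2]]$min_intensity, 0.07)  # fallback default
  writeLines("Hex(1)", p)
  expect_error(read_oxonium_rules(p), "TAB")
  writeLines("Hex(1)\t163.06\t1.7", p)
  expect_error(read_oxonium_rules(p), "threshold")
})
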