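Package: glycopair
Title: Paired-Scan O-Glycopeptide Identification and Site Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peptide-first identification and glycan site localization for
    O-glycoproteomics data acquired as paired collisional / electron-activation
    tandem-MS scans (e.g. HCD-pd-EThcD). The collisional scan is searched for
    the peptide plus a total glycan-mass offset drawn from combinations of a
    glycan composition database; the paired electron-activation scan is then
    used to deconvolute the total glycan mass into individual glycans localized
    to serine/threonine sites via a graph dynamic-programming algorithm with
    site probabilities and four localization confidence levels. Includes
    diagnostic oxonium-ion filtering, target-decoy q-values, tab-separated
    reporting, mzML/MGF input, and a synthetic paired-spectra generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    mzR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
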