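---
title: "Paired-scan O-glycopeptide localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-scan O-glycopeptide localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopair)
```

## The problem

O-glycans attach to serine and threonine with no consensus sequence motif,
so every S/T in a peptide is a candidate glycosite. They are also labile:
collisional activation (HCD) strips them from the backbone, while
electron-based activation (ETD/EThcD/EAD) preserves them on c/z• fragments.
Modern acquisition therefore pairs the two: an HCD scan identifies the
peptide, a paired EThcD scan of the same precursor localizes the glycans.

The search-space obstacle is combinatorial. With a database of $n$ glycan
compositions and up to $k$ glycans per peptide, the number of distinct
glycan multisets is

$$\binom{n + k}{k} - 1,$$

which for $n = 32,\ k = 5$ is 435,896 and for $k = 8$ is 76,904,684 —
per peptide. A conventional (glycan-first) engine must consider all of
them. The peptide-first strategy implemented here instead searches the HCD
scan for *naked* backbone b/y ions plus a single precursor mass offset equal
to the *combined* glycan mass; only the distinct combined masses matter
(`count_unique_combined_masses()`), typically orders of magnitude fewer, and
the deconvolution into individual glycans and sites is deferred to the
EThcD scan.

## Scan pairing

MS2 scans are paired only within blocks bounded by consecutive MS1 scans.
Within a block, each unpaired scan of the first activation type is paired
greedily with the earliest subsequent unpaired scan of the second type whose
precursor m/z agrees within the precursor tolerance (default 30 ppm) and,
by default, whose charge agrees when both are known. Greedy earliest-match
reflects trigger-scan acquisition, where the dependent scan immediately
follows its trigger; each scan joins at most one pair. `etd_first` swaps
the roles, and `single` mode treats every MS2 scan as its own pair, which is
how purely EThcD/EAD (or HCD-only) runs are analyzed.

## Peptide-first search

Candidates come from in-silico digestion (trypsin with configurable
cleavage-before-proline suppression, or the mucinase StcE modeled as
cleaving N-terminal to any S/T, full or semi specificity, reversed-protein
decoys, variable modifications expanded to their per-modification maxima
under a global candidate cap). For an observed neutral precursor mass $M$, a
candidate peptide of mass $m_p$ is scored if $M - m_p$ is within tolerance
of zero (non-glycosylated) or of some combined glycan mass in the offset
index — the latter only for peptides with at least one S/T, and only boxes
with no more glycans than candidate sites are retained. Scoring uses an
X!Tandem-style hyperscore over 1+/2+ b/y ions of the naked peptide:
$\ln n_b! + \ln n_y! + \ln(\Sigma I_b \cdot \Sigma I_y)$ with factorials
capped at 10. Ties prefer fewer glycans, then lexicographic sequence.

## Oxonium-ion filtering

Glycan compositions leave low-mass diagnostic fragments in the collisional
scan. A rule file maps residue requirements to ion lists with a minimum
summed base-peak-relative intensity (default 5%); the bundled default set is
HexNAc(1)Hex(1) → 366.1395; Hex(1) → 163.0601, 145.0495; NeuAc(1) →
274.0921, 292.1027; NeuGc(1) → 290.0870, 308.0976. A candidate glycan box is
considered for localization only if every applicable rule passes **in the
first scan of the pair**. All ion masses in the package are derived from
elemental formulas and the proton mass (1.007276 Da), never hard-coded;
the printed values above serve as regression checks in the test suite.

## The localization graph

For a PSM with peptide length $L$, candidate sites $s_1 < \dots < s_r$, and
glycan box $B$ (a multiset of database entries), the localization graph has
nodes $(i, c)$ with $i \in 0..L$ and $c \subseteq B$ the sub-multiset
already placed on sites $\le i$. Edges keep $c$ fixed between sites and may
add one glycan at a site, so root-to-sink paths correspond one-to-one with
full assignments of $B$ to sites (at most one glycan per site). Node
$(i, c)$ is scored by counting matched ions among the c-ion of length $i$
carrying $\mathrm{mass}(c)$ and the z•-ion of length $L - i$ carrying
$\mathrm{mass}(B) - \mathrm{mass}(c)$, at charges 1+ and 2+ within the
product tolerance (10 ppm default). Conventions: c = b + NH₃;
z• = y − NH₃ + H•.

A path's weight is $w_p = b^{\,\mathrm{score}(p)}$ with base $b = 10$
(configurable). Site probabilities
$$P(\text{site } s \text{ carries } g) =
  \frac{\sum_{p:\, p(s)=g} w_p}{\sum_p w_p}$$
are computed *exactly* by a forward–backward pass over the graph — no path
enumeration — and per-entry probabilities sum to the entry's multiplicity by
construction. The best assignment is the maximum-score path (ties resolved
deterministically toward the smaller child box). `brute_force_localize()`
enumerates every assignment explicitly and serves as the independent oracle;
the test suite requires agreement to 1e-9 on hundreds of randomized
instances.

Base 10 was chosen so that a single additional site-determining ion takes a
two-way ambiguity to $10/(10+1) \approx 0.909 > 0.75$ — i.e. one clean ion
of spectral evidence is "confident" under the 0.75 threshold. A
*site-determining* ion is a matched c/z• ion whose theoretical m/z differs
between at least two feasible configurations at its position.

## Confidence levels

With probability threshold 0.75 (configurable):

* **1** — every glycan instance has a site with $P > 0.75$ and at least one
  site-determining ion was matched on the best path;
* **1b** — every instance localized, but by elimination: the assignment is
  forced (a single configuration) or no site-determining ion was matched;
* **2** — at least one, but not all, instances localized;
* **3** — none localized.

Two boundary decisions were genuinely open and are resolved as follows.
First, level 1b is applied whenever *all* instances are localized without
spectral evidence (the alternative reading — some instances forced — would
blur the 1/1b boundary for mixed cases; mixed cases land in level 2 here
when the evidenced instance is confident and the forced one is not
resolvable). Second, localization evidence is drawn only from electron-based
activation scans: if the available localization scan is collisional (HCD),
c/z• ions are physically absent and matching against it would only collect
chance coincidences, so ion matching is skipped and localization degenerates
to elimination. This reproduces the characteristic behavior of HCD-only
searches, whose multi-site identifications are all level 3.

## FDR

PSMs are ranked by hyperscore; $\mathrm{FDR}(s) = \#\{\text{decoys} \ge s\}
/ \max(1, \#\{\text{targets} \ge s\})$, and q-values are the running minimum
from the bottom. Decoys are reversed proteins. This deliberately replaces
semiparametric rescoring (PeptideProphet-style) with a self-contained,
testable estimator; the calibration test plants ground truth and checks the
empirical false discovery proportion at $q \le 0.01$ stays within 0.02
averaged over 20 seeds. Glycan-composition-level FDR is out of scope: the
oxonium filter improves composition plausibility but is not an error-rate
control.

## The synthetic generator

`simulate_run()` emulates HCD-pd-EThcD acquisition: per glycopeptide a
collisional scan (naked 1+/2+ b/y ladder, composition-implied oxonium ions
at high relative intensity, a precursor-sized residual) and an
electron-activation scan (1+/2+ c/z• ladder with glycans retained at the
true sites), interleaved between MS1 scans (three pairs per block), with
i.i.d. per-ion dropout (`detection_prob`), Gaussian ppm jitter, and uniform
noise peaks. Intensities are log-normal (σ = 0.5 on the relative scale) —
only relative intensities matter to any algorithm here. Charges are drawn
2:2:1 from {2, 3, 4}. Peptides are fully tryptic (7–22 residues, no missed
cleavages) from random 20-protein proteomes with mildly S/T-enriched
composition; site occupancy is 0.5 per S/T, capped at 3 glycans per peptide.
A `hexose_free` mode plants only Hex-free compositions (entrapment-style):
the spectra then lack the 145.05/163.06/366.14 ions and hexose-containing
assignments must be suppressed by the oxonium filter.

What the generator does **not** model: chromatographic peak shape, isotope
envelopes, co-isolation chimeras, profile-mode peaks, intensity structure
along the ladder, or N-glycans. Passing the end-to-end tests therefore
demonstrates correctness of the pairing/search/deconvolution machinery under
controlled noise, not instrument-grade performance on real data.

## Numerical and degenerate-input choices

* Monoisotopic element masses from standard tables; proton 1.007276 Da,
  water 18.010565 Da; residue masses always derived from formulas.
* Combined-mass uniqueness uses rounding to 4 decimals (~0.1 mDa), matching
  the precision at which diagnostic ions are conventionally printed.
* Peak matching takes the nearest peak within ppm tolerance; path weights
  are exact doubles (scores are bounded by $4(L-1)$ matched ions, far below
  overflow for tryptic peptide lengths).
* Empty localization scan → combinatorially uniform probabilities; box size
  equal to site count → single configuration, level 1b; box larger than the
  site count → "infeasible box" error at graph construction.
* All candidate boxes filtered out → the PSM is retained with composition
  `"unassigned"` at level 3.
* Glycan databases are sorted by mass; box enumeration prunes by the target
  window, and ties everywhere break deterministically (fewer glycans, then
  canonical composition text), so identical inputs give byte-identical
  outputs.

## Problem sizes used in the shipped experiments

The validation experiments are sized for a single CPU: 500 glycopeptides
for the noise-free recovery run, 100 for the entrapment run, 25 × 20 seeds
for FDR calibration, 200 randomized instances (≤ 10⁵ configurations each)
for the DP-vs-brute-force equivalence, and exhaustive multiset enumeration
up to the 435,896-configuration 5-site case for the combinatorics check.

## Known limitations

* Localization uses c/z• ions only; b/y co-scoring of hybrid EThcD spectra
  is not implemented.
* No deisotoping, mass calibration, or charge deconvolution — inputs are
  assumed centroided and deisotoped.
* The exponential path weighting is a design choice calibrated to the 0.75
  probability convention, not a fitted error model.
* Site-level aggregation reports the first protein of shared peptides;
  protein inference is out of scope.
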