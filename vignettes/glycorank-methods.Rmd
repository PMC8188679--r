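---
title: "Methods: glycan mass calculus, glycosite localization, target scoring and survival models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycan mass calculus, glycosite localization, target scoring and survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycorank)
```

`glycorank` chains four analysis stages — O-glycome annotation, glycopeptide
annotation with glycosite localization, candidate curation and target
scoring, and cohort survival statistics — plus seeded simulators that emulate
every input the stages consume. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic data do
and do not demonstrate.

## 1. Permethylated benzyl O-glycan mass calculus

In a cellular O-glycome reporter/amplification (CORA) experiment, cells
glycosylate a cell-permeable benzyl-GalNAc mimetic and secrete the benzyl
O-glycans, which are permethylated and measured by nanoLC-ESI-MS. The mass
model is purely compositional: a glycan is a count vector over
{Hex, HexNAc, dHex, NeuAc}. Every mass derives from six monoisotopic
elemental constants (C 12, H 1.0078250319, N 14.0030740052, O 15.9949146221,
S 31.97207069, Na 22.98976928); no ion value is hard-coded.

Extending an already-permethylated glycan by one permethylated residue adds
a linkage-independent increment: the dehydro residue mass plus a fixed
number of CH2 groups (Hex and HexNAc 3, dHex 2, NeuAc 5), i.e. 204.0998,
245.1263, 174.0892 and 361.1737 Da. The full benzyl glycoside closes with an
aglycone constant C8H10O (122.0732 Da) — the benzyl cap plus the residual
methylation site of the reducing-end GalNAc core — and a charge carrier.
Protonation reproduces the entire published ten-ion ladder (Tn 368.2 through
di-sialylated core 2 at 1743.9) to 0.1 Da, so the proton is the default
adduct; `[M+Na]+`, common for permethylated glycans, sits behind the
`adduct = "sodium"` flag. Because only rounded values are printed, the
adduct is a modelling choice: we adopted the one that matches print.

Numerical contract: comparisons against printed values use round-half-up
(1 decimal for profile ions, 2 for oxonium ions), since base R's banker's
rounding would turn 1294.65 into 1294.6. Compositions for the four core 2
ions are fixed by residue-increment arithmetic from the ladder spacings and
recorded in `default_glycan_library()`.

`annotate_oglycome()` matches each library species to the nearest peak
within a tolerance (default 0.3 Da, suited to 1-decimal profile ions;
configurable). Ties break by higher intensity, then lower m/z, which makes
annotation invariant to peak and library order. Relative abundance is
matched intensity over summed matched intensity; unmatched species stay in
the profile with zero abundance and an `absent` flag, and an empty peak list
is an empty profile, not an error.

## 2. Glycopeptide annotation and glycosite localization

Digestion is rule-based: trypsin cleaves C-terminal to K/R, chymotrypsin
C-terminal to F/W/Y/L/M, neither before proline. The chymotrypsin
specificity is a declared high-specificity dialect — the wet-lab protocol it
mirrors does not state one. Peptides carry 1-based protein coordinates, and
0-missed-cleavage peptides tile the protein exactly (a property test).

Fragment prediction emits singly charged monoisotopic b/y/c/z ions
(indices 1..n−1) with modification deltas applied to the correct
prefix/suffix, under the conventions c = b + NH3 and z• = y − NH3 + H
(z-dot default, plain z behind a flag). Variable modifications are Met
oxidation (+15.9949), carbamidomethyl-Cys (+57.0215), and Ser/Thr HexNAc
(+203.0794) and HexNAc-Hex (+365.1322); the nominal printed deltas
(+15.9, +57, +203.1, +365.1) are read as rounded monoisotopic values, and
the exact values are used internally.

The scorer is a deliberately simple, fully specified stand-in for a
SequestHT/Percolator pipeline (out of scope): a candidate is accepted only
if its precursor matches within 5 ppm (charges 2–8 accepted; fragments are
matched singly charged only — a documented simplification), and its score is
the matched-ion fraction at 0.1 Da. Oxonium gating replaces Percolator
q-values: a glycopeptide PSM reaches `high` confidence only with matched
fraction ≥ 0.6 (configurable) *and* a peak near 204.0867 or 366.1395;
otherwise it is `medium_low`. These tiers are declared, not recovered from
any published threshold.

Localization enumerates every placement of the glycan multiset (up to
`max_glycans_per_peptide = 3` occupied sites, both glycans allowed
simultaneously) over the peptide's S/T sites and counts matched
*site-determining* c/z ions — ions whose m/z differs between at least two
placements. The verdict is `unique` iff exactly one placement strictly
dominates; ties propagate as `ambiguous` with the tied site set. Intact
glycopeptide Y-ion ladders, target-decoy FDR and N-glycosylation are
non-goals.

## 3. Curation, expression filters and the target score

Curation keeps proteins with ≥ 1 high-confidence glycopeptide or ≥ 2
distinct medium/low glycopeptides; multiplicity counts distinct peptide
sequences — the strictest reading computable from a PSM table, chosen over
counting spectra or glycoforms. The differential-expression filter is
boundary-inclusive (linear fold ≥ 2 and p ≤ 0.05; the linear-ratio reading
is our choice since log2 is not stated). Tumour expression bins partition
percent-positive patients as 80–100 high / 40–79 moderate / 1–39 low / 0
negative, with missing data `unknown`.

The 0–15 target score's per-criterion point values are this package's
declared rubric (the published system states only the maximum and four
example totals): healthy-tissue absence 0–5 from a weighted expression
burden (high 2, moderate 1, low 0.5 per tissue; 5/4/3/2/1 points at burden
0/≤1/≤2/≤4/≤8), urothelium absence 0–2, tumour bin 0–3, plasma-membrane
localization 0–2, prognosis association 0–1, up-regulation 0–2, minus 3 for
lymphoid/gamete expression, clamped to [0, 15]. Unknown annotations score 0
(worst case) rather than excluding the protein; a
`require_tumour_data = TRUE` flag reproduces rankings restricted to proteins
with tumour expression data. The whole rubric is a plain list
(`default_rubric()`), so alternative weightings are drop-in. Exhaustive
lattice enumeration verifies the bounds, the reachable ceiling of 15, and
per-attribute monotonicity. Ranking is deterministic: score desc, tumour bin,
then protein id.

## 4. Cohort statistics

IHC H-scores multiply intensity (0–3) by extension in tenths (0–10), giving
0–30; the location phenotype (cytoplasm vs membrane-and-cytoplasm) is
binary, with no intensity weighting. The membrane/cytoplasm ratio is
computed among positive cases per stage; a zero denominator is reported as
undefined, never infinity.

Association tests on 2×2 tables auto-select Fisher's exact test exactly when
any cell holds fewer than 5 individuals, else Pearson chi-square without
continuity correction (Yates behind a flag). The Fisher p-value is two-sided
by the minimum-likelihood rule; the test suite verifies it against an
exhaustive hypergeometric enumeration over all tables with margins ≤ 12.

Kaplan–Meier, log-rank and Cox regression are implemented from their
defining formulas because their numerics are part of this package's
contract: the product-limit estimator per group; the log-rank statistic from
observed-minus-expected events over pooled distinct event times with the
hypergeometric variance, referred to chi-square on groups − 1 df; and the
Cox partial likelihood maximized by Newton–Raphson with Efron tie handling,
step-halving, convergence at relative log-likelihood change < 1e-9 within 50
iterations, and explicit flags for non-convergence, monotone likelihood
(|log HR| > 15) and zero-information covariates (HR 1, p 1). Group "mean
survival" is the restricted mean to the largest observed time — the standard
software output for that label — with the curves available for medians. The
`survival` package serves as an independent cross-check in the tests, never
as the implementation.

## 5. Synthetic data: what it emulates, and what it does not

All generators are pure functions of (parameters, seed); each draws from its
own substream derived from the master seed, so adding a generator never
perturbs existing outputs, and every generator emits a planted-truth object
sufficient to score its downstream stage.

* `simulate_oglycome()` plants one peak per species at its theoretical m/z
  (jitter < tolerance/2), log-normal intensities, and noise peaks uniform on
  300–1800 m/z kept 2 tolerances away from library ions.
* `simulate_glycopeptide_spectra()` emits the complete b/y/c/z ladder of one
  glycopeptide per protein minus seeded dropout, plus oxonium markers and
  noise on 350–1800 m/z (the acquisition window of the EThcD runs it
  mimics), with exact doubly charged precursors.
* `simulate_expression_and_tissues()` plants up-regulated genes clearing the
  fold/p thresholds while the rest straddle them, and gives a configurable
  fraction of proteins an all-negative ("restricted") healthy-tissue
  profile.
* `simulate_cohort()` samples stages, assigns the membrane phenotype with
  per-stage probabilities r/(1+r) derived from published membrane/cytoplasm
  ratios (0.07/0.38/0.33/0.46/0.63 for Ta–T4, carried to metastases),
  and draws exponential survival (baseline mean 148 months, the reported
  membrane-negative group mean) with hazard multiplied by exp(log HR)
  (default ln 3.87) for membrane-positive patients, under independent
  exponential censoring (mean 226 months, the longest follow-up of the
  series it emulates). Default cohort size is 104, a typical retrospective
  series; Weibull hazards sit behind `weibull_shape`.

Problem sizes in the test suite were chosen as the smallest that exercise
the statistics meaningfully: localization recovery uses 50 proteins at 20%
ion dropout; hazard-ratio recovery uses 100 cohorts of n = 500; the log-rank
null calibration uses 200 cohorts of n = 104.

These simulations validate the *algorithms*, not the biology: spectra have
no isotope envelopes, chemical noise structure, co-eluting species or
retention-time dimension; expression tables have no correlation structure;
survival is constant-hazard. Passing recovery tests therefore shows the
pipeline is correct under its stated model, not that it would match any
particular clinical series. The published patient-level results (83 vs 148
months, log-rank p = 0.035, HR 3.87) rest on unpublished raw cohort data and
are intentionally not asserted; the package instead checks the recoverability
properties above on data where the truth is known.
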