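# glycorank

Glycomics-guided glycoproteomics biomarker discovery for bladder cancer, as a
tested, desk-scale R pipeline.

Aggressive bladder tumours remodel their surface *O*-glycome towards
short-chain sialylated glycans (sialyl-Tn, sialyl-T). Proteins that carry
these glycans at the cancer-cell membrane — while being absent from healthy
urothelium and other healthy tissues — are attractive targets for guided
therapeutics. `glycorank` implements the full discovery workflow that turns
raw glycan and glycopeptide mass spectra plus public-style expression tables
into a ranked list of candidate glycoprotein targets, and associates the
resulting immunohistochemistry phenotypes with patient survival:

1. **O-glycome annotation** (`annotate_oglycome`). Secreted benzyl
   *O*-glycans from CORA experiments are permethylated and measured by
   nanoLC-ESI-MS. For a glycan composition Hex_h HexNAc_n dHex_f NeuAc_s the
   singly protonated permethylated benzyl glycoside mass is computed from
   elemental formulas as

   `m/z = h·204.0998 + n·245.1263 + f·174.0892 + s·361.1737 + 122.0732 + 1.00728`

   (each term a dehydro residue plus its methylation sites; the constant is
   the benzyl-aglycone closure C8H10O). Library species are matched to peaks
   and quantified as percent of summed matched intensity.
2. **Glycopeptide annotation and glycosite localization**
   (`digest`, `theoretical_ions`, `match_spectrum`, `localize_glycosite`,
   `annotate_glycopeptides`). In-silico trypsin/chymotrypsin digestion,
   b/y/c/z fragment prediction with variable modifications (Met oxidation,
   carbamidomethyl-Cys, and HexNAc +203.1 / HexNAc-Hex +365.1 on Ser/Thr),
   matched-ion-fraction scoring at 5 ppm precursor / 0.1 Da fragment
   tolerance, oxonium-ion gating (204.09 / 366.14), and site localization
   from site-determining EThcD c/z ions.
3. **Curation and target ranking** (`curate_proteins`, `venn_counts`,
   `apply_de_filter`, `bin_tumour_expression`, `target_score`,
   `rank_candidates`). Proteins with ≥ 2 distinct glycopeptides (or ≥ 1
   high-confidence one) are retained, annotated with tumour-vs-normal
   differential expression (fold ≥ 2, p ≤ 0.05) and tissue-atlas style
   expression bins, and ranked by a 0–15 *target score* that rewards tumour
   over-expression, membrane localization and healthy-tissue absence and
   penalizes lymphoid/gamete expression.
4. **Cohort statistics** (`ihc_score`, `membrane_cytoplasm_ratio`,
   `association_test`, `km_logrank`, `cox_fit`). IHC H-scores (intensity 0–3
   × extension in 10% cut-offs), chi-square/Fisher association tests,
   Kaplan–Meier curves with log-rank tests, and Cox proportional-hazards
   regression (Newton–Raphson, Efron ties) for the membrane-phenotype
   survival analysis.
5. **Synthetic data** (`simulate_*`). Seeded generators emulate every input
   — O-glycome peak lists, EThcD glycopeptide MGFs, DE tables, tissue
   matrices and patient cohorts — with planted ground truth, so every stage
   is testable end to end without external data.

## Worked example

```r
library(glycorank)

# annotate a synthetic O-glycome spectrum against the default library
sim <- simulate_oglycome(seed = 7)
profile <- annotate_oglycome(sim$peaks, default_glycan_library())
head(profile[order(-profile$relative_abundance), ], 3)
#> # A tibble: 3 x 6
#>   label        expected_mz matched_mz intensity relative_abundance absent
#>   <chr>              <dbl>      <dbl>     <dbl>              <dbl> <lgl>
#> 1 di-sialyl-T        1295.      1295.   116628.               32.4 FALSE
#> 2 sialyl-core2       1179.      1179.    50204.               14.0 FALSE
#> 3 fucosyl-T           746.       747.    50123.               13.9 FALSE

# localize a planted glycosite from EThcD c/z ions
proteins <- simulate_proteome(5, seed = 7)
spectra  <- simulate_glycopeptide_spectra(proteins, seed = 7)
psms     <- annotate_glycopeptides(spectra$spectra, proteins)
psms[1, c("protein_id", "peptide", "localization", "confidence")]
#> # A tibble: 1 x 4
#>   protein_id peptide       localization confidence
#>   <chr>      <chr>         <chr>        <chr>
#> 1 PROT0001   ICDAFQHQTHTAR unique       high

# survival association of a planted membrane phenotype (log HR = ln 3.87)
cohort <- simulate_cohort(cohort_size = 500, seed = 7)$cohort
cohort$membrane <- as.integer(cohort$location == "membrane_and_cytoplasm")
tidy(cox_fit(cohort, "membrane"))
#> # A tibble: 1 x 6
#>   term     estimate hazard_ratio std_error statistic  p_value
#>   <chr>       <dbl>        <dbl>     <dbl>     <dbl>    <dbl>
#> 1 membrane     1.32         3.74     0.135      9.77 1.45e-22
```

The relative abundances are percentages of the summed matched intensities
(here di-sialylated T dominates the simulated profile); the PSM row shows a
uniquely localized high-confidence glycopeptide; the Cox fit recovers a
hazard ratio close to the planted 3.87 for membrane-positive patients.

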