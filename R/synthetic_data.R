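# Per-generator substreams derived from the master seed, so adding a
# generator never perturbs the outputs of existing ones.
.stream_offsets <- c(proteome = 1L, oglycome = 2L, spectra = 3L,
                     expression = 4L, cohort = 5L)

derive_seed <- function(seed, stream) {
  offset <- .stream_offsets[[stream]]
  as.integer((as.numeric(seed) %% 100000) * 10007 + offset)
}

#' Default stage-wise membrane-phenotype probabilities
#'
#' Probability that a positive case shows membrane (and cytoplasm) staining,
#' per stage, derived from membrane/cytoplasm ratios r via r / (1 + r). The
#' default ratios (0.07 Ta, 0.38 T1, 0.33 T2, 0.46 T3, 0.63 T4, and 0.63
#' carried over to metastases) reflect the rising membrane phenotype with
#' stage seen in bladder tumour series.
#'
#' @return Named numeric vector of probabilities by stage.
#' @export
default_membrane_prob_by_stage <- function() {
  ratios <- c(Ta = 0.07, T1 = 0.38, T2 = 0.33, T3 = 0.46, T4 = 0.63, MET = 0.63)
  ratios / (1 + ratios)
}

#' Simulate a proteome
#'
#' Random protein sequences over the 20 standard residues with guaranteed
#' Ser/Thr content and tryptic sites, suitable as search space and substrate
#' for the glycopeptide spectrum simulator.
#'
#' @param n_proteins Number of proteins.
#' @param seed Master seed.
#' @param length_range Protein length range (uniform).
#' @return A tibble with `protein_id`, `sequence`.
#' @export
simulate_proteome <- function(n_proteins = 50, seed = 1,
                              length_range = c(60, 200)) {
  withr::with_seed(derive_seed(seed, "proteome"), {
    aa <- names(.aa_residues)
    # S/T and K/R mildly enriched so every protein yields glycosylatable
    # tryptic peptides
    wts <- stats::setNames(rep(1, length(aa)), aa)
    wts[c("S", "T")] <- 2
    wts[c("K", "R")] <- 1.6
    wts["P"] <- 0.5
    tibble::tibble(
      protein_id = sprintf("PROT%04d", seq_len(n_proteins)),
      sequence = vapply(seq_len(n_proteins), function(i) {
        len <- sample(length_range[1]:length_range[2], 1)
        paste(sample(aa, len, replace = TRUE, prob = wts), collapse = "")
      }, character(1))
    )
  })
}

#' Simulate an O-glycome peak list with planted truth
#'
#' Plants one peak per selected library species at its theoretical m/z plus a
#' uniform jitter below `tolerance/2`, with seeded log-normal intensities,
#' and adds noise peaks drawn uniformly over the scan range but kept at least
#' `2 * tolerance` away from every library m/z.
#'
#' @param library Glycan library (default [default_glycan_library()]).
#' @param species Labels of the planted species (default: all).
#' @param seed Master seed.
#' @param jitter Maximum absolute m/z jitter (default `tolerance / 2`).
#' @param tolerance Annotation tolerance the data are generated for
#'   (default 0.3 Da).
#' @param n_noise Number of noise peaks.
#' @param scan_range m/z range for noise peaks.
#' @return A list with `peaks` (tibble `mz`, `intensity`) and `truth`
#'   (planted species with true relative abundances).
#' @export
simulate_oglycome <- function(library = default_glycan_library(),
                              species = library$label, seed = 1,
                              tolerance = 0.3, jitter = tolerance / 2,
                              n_noise = 30, scan_range = c(300, 1800)) {
  library <- validate_glycan_library(library)
  planted <- library[library$label %in% species, , drop = FALSE]
  if (nrow(planted) == 0 && n_noise == 0) {
    stop("nothing to simulate", call. = FALSE)
  }
  withr::with_seed(derive_seed(seed, "oglycome"), {
    intensity <- stats::rlnorm(nrow(planted), meanlog = 10, sdlog = 1)
    signal <- tibble::tibble(
      mz = planted$expected_mz +
        stats::runif(nrow(planted), -jitter, jitter),
      intensity = intensity
    )
    noise <- tibble::tibble(mz = numeric(0), intensity = numeric(0))
    if (n_noise > 0) {
      keep_out <- library$expected_mz
      mzs <- numeric(0)
      attempts <- 0
      while (length(mzs) < n_noise && attempts < 200 * n_noise) {
        cand <- stats::runif(n_noise, scan_range[1], scan_range[2])
        ok <- vapply(cand, function(m) all(abs(keep_out - m) > 2 * tolerance),
                     logical(1))
        mzs <- c(mzs, cand[ok])
        attempts <- attempts + n_noise
      }
      if (length(mzs) < n_noise) {
        stop("library too dense for noise-peak placement", call. = FALSE)
      }
      noise <- tibble::tibble(mz = mzs[seq_len(n_noise)],
                              intensity = stats::rlnorm(n_noise, 7, 1))
    }
    peaks <- normalize_peaks(dplyr::bind_rows(signal, noise))
    truth <- planted[, c("label", "expected_mz")]
    truth$intensity <- intensity
    truth$relative_abundance <- 100 * intensity / sum(intensity)
    list(peaks = peaks, truth = truth)
  })
}

#' Simulate EThcD glycopeptide spectra with planted glycosites
#'
#' For each selected protein, picks a tryptic peptide carrying Ser/Thr,
#' plants one glycan (HexNAc or HexNAc-Hex) on a random site, and emits the
#' full b/y/c/z fragment ladder minus seeded random dropout, plus oxonium
#' marker ions and uniform noise peaks over the acquisition range. Precursors
#' are exact doubly charged theoretical values.
#'
#' @param proteins A tibble with `protein_id`, `sequence` (e.g. from
#'   [simulate_proteome()]).
#' @param seed Master seed.
#' @param ion_dropout Probability that any fragment ion is dropped.
#' @param n_noise Noise peaks per spectrum.
#' @param scan_range m/z range of noise peaks (acquisition window).
#' @param omit_oxonium Suppress oxonium marker ions (used to exercise the
#'   confidence demotion rule).
#' @param peptide_length Acceptable peptide length range.
#' @return A list with `spectra` (tibble as from [read_mgf()]) and `truth`
#'   (tibble: `spectrum_id`, `protein_id`, `peptide`, `peptide_start`,
#'   `site_protein`, `site_peptide`, `glycan`).
#' @export
simulate_glycopeptide_spectra <- function(proteins, seed = 1, ion_dropout = 0,
                                          n_noise = 10,
                                          scan_range = c(350, 1800),
                                          omit_oxonium = FALSE,
                                          peptide_length = c(6, 30)) {
  stopifnot(nrow(proteins) > 0)
  withr::with_seed(derive_seed(seed, "spectra"), {
    rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
      peps <- digest(proteins$sequence[i], "trypsin", max_missed = 0)
      peps <- peps[nchar(peps$peptide) >= peptide_length[1] &
                     nchar(peps$peptide) <= peptide_length[2], , drop = FALSE]
      peps <- peps[vapply(peps$peptide,
                          function(p) length(st_sites(p)) >= 1, logical(1)), ,
                   drop = FALSE]
      if (nrow(peps) == 0) return(NULL)
      pick <- peps[sample(nrow(peps), 1), ]
      sites <- st_sites(pick$peptide)
      site <- if (length(sites) == 1) sites else sample(sites, 1)
      glycan <- sample(.glyco_mod_names, 1)
      mods <- tibble::tibble(position = site, name = glycan)
      ladder <- theoretical_ions(pick$peptide, mods, c("b", "y", "c", "z"))
      keep <- stats::runif(nrow(ladder)) >= ion_dropout
      frag <- ladder[keep, , drop = FALSE]
      peak_tbl <- tibble::tibble(
        mz = frag$mz,
        intensity = stats::rlnorm(nrow(frag), 8, 0.5)
      )
      if (!omit_oxonium) {
        peak_tbl <- dplyr::bind_rows(peak_tbl, tibble::tibble(
          mz = unname(.oxonium_targets()),
          intensity = stats::rlnorm(2, 9, 0.3)
        ))
      }
      if (n_noise > 0) {
        peak_tbl <- dplyr::bind_rows(peak_tbl, tibble::tibble(
          mz = stats::runif(n_noise, scan_range[1], scan_range[2]),
          intensity = stats::rlnorm(n_noise, 6, 1)
        ))
      }
      neutral <- peptide_neutral_mass(pick$peptide, mods)
      list(
        spectrum = tibble::tibble(
          spectrum_id = sprintf("%s_scan%d", proteins$protein_id[i], i),
          precursor_mz = (neutral + 2 * .proton_mass) / 2,
          charge = 2L,
          peaks = list(normalize_peaks(peak_tbl))
        ),
        truth = tibble::tibble(
          spectrum_id = sprintf("%s_scan%d", proteins$protein_id[i], i),
          protein_id = proteins$protein_id[i],
          peptide = pick$peptide,
          peptide_start = pick$start,
          site_peptide = site,
          site_protein = pick$start - 1L + site,
          glycan = glycan
        )
      )
    })
    rows <- purrr::compact(rows)
    list(
      spectra = purrr::map_dfr(rows, "spectrum"),
      truth = purrr::map_dfr(rows, "truth")
    )
  })
}

#' Simulate a differential-expression table and a tissue-expression matrix
#'
#' Plants a set of up-regulated genes whose fold change and p-value clear the
#' filter thresholds while the remaining genes straddle them, and draws
#' healthy-tissue expression categories in which a configurable subset shows
#' a restricted (all-negative) pattern mimicking an ideal target profile.
#'
#' @param n_proteins Number of genes/proteins; ids `PROT0001`...
#' @param seed Master seed.
#' @param de_fraction_up Fraction of planted up-regulated genes.
#' @param planted_fold_range Linear fold-change range for planted genes.
#' @param min_fold,max_p Filter thresholds the planted genes must clear.
#' @param restricted_fraction Fraction of proteins given an all-negative
#'   healthy-tissue profile.
#' @param tissues Healthy tissue panel.
#' @return A list with `de_table`, `tissue_matrix` (long tibble:
#'   `protein_id`, `tissue`, `level`) and `truth` (`up_ids`,
#'   `restricted_ids`).
#' @export
simulate_expression_and_tissues <- function(n_proteins = 100, seed = 1,
                                            de_fraction_up = 0.1,
                                            planted_fold_range = c(2, 10),
                                            min_fold = 2, max_p = 0.05,
                                            restricted_fraction = 0.05,
                                            tissues = c(
                                              "brain", "endocrine", "immune",
                                              "muscle", "respiratory",
                                              "digestive", "urinary",
                                              "reproductive", "adipose", "skin"
                                            )) {
  n_up <- round(n_proteins * de_fraction_up)
  stopifnot(n_proteins >= n_up)
  withr::with_seed(derive_seed(seed, "expression"), {
    ids <- sprintf("PROT%04d", seq_len(n_proteins))
    up_ids <- sample(ids, n_up)
    rest <- setdiff(ids, up_ids)
    # non-planted genes straddle the thresholds: low fold, or good fold but
    # non-significant p
    low_fold <- sample(c(TRUE, FALSE), length(rest), replace = TRUE)
    de_table <- tibble::tibble(
      protein_id = c(up_ids, rest),
      fold_change = c(
        stats::runif(n_up, planted_fold_range[1], planted_fold_range[2]),
        ifelse(low_fold,
               stats::runif(length(rest), 0.5, min_fold - 0.05),
               stats::runif(length(rest), min_fold, planted_fold_range[2]))
      ),
      p_value = c(
        stats::runif(n_up, 1e-6, max_p),
        ifelse(low_fold,
               stats::runif(length(rest), 1e-6, 1),
               stats::runif(length(rest), max_p + 1e-6, 1))
      ),
      cohort = sample(c("MIBC", "both"), n_proteins, replace = TRUE)
    )
    de_table <- de_table[order(de_table$protein_id), ]

    restricted_ids <- sample(ids, round(n_proteins * restricted_fraction))
    levels <- c("high", "moderate", "low", "negative", "not_available")
    tissue_matrix <- tidyr::expand_grid(protein_id = ids, tissue = tissues)
    tissue_matrix$level <- ifelse(
      tissue_matrix$protein_id %in% restricted_ids,
      "negative",
      sample(levels, nrow(tissue_matrix), replace = TRUE,
             prob = c(0.15, 0.2, 0.25, 0.3, 0.1))
    )
    list(de_table = de_table, tissue_matrix = tissue_matrix,
         truth = list(up_ids = sort(up_ids),
                      restricted_ids = sort(restricted_ids)))
  })
}

#' Simulate a patient cohort with a planted membrane-phenotype hazard
#'
#' Samples stages from a configurable distribution, assigns the membrane
#' phenotype per stage via Bernoulli draws whose default probabilities derive
#' from published membrane/cytoplasm ratios, and draws exponential survival
#' times whose hazard is multiplied by `exp(planted_log_hr)` for
#' membrane-positive patients, with independent exponential censoring.
#' Intensity and extension readings are drawn consistently with the location
#' call (negative location gives intensity 0 and extension 0).
#'
#' @param cohort_size Number of patients (minimum 20; default 104, a typical
#'   retrospective tumour series).
#' @param seed Master seed.
#' @param stage_probs Named stage distribution.
#' @param membrane_prob Named per-stage membrane probabilities (default
#'   [default_membrane_prob_by_stage()]).
#' @param negative_prob Probability a patient is IHC-negative.
#' @param planted_log_hr Planted log hazard ratio of the membrane phenotype
#'   (default `log(3.87)`).
#' @param baseline_mean_months Mean survival of the membrane-negative group
#'   (exponential; default 148 months).
#' @param censoring_mean_months Mean of the exponential censoring time
#'   (default 226 months, the longest follow-up of a typical series).
#' @param weibull_shape Optional Weibull shape; `NULL` (default) keeps the
#'   constant-hazard exponential model.
#' @return A list with `cohort` (a cohort tibble, see [read_cohort()]) and
#'   `truth` (planted log-HR and per-stage membrane probabilities).
#' @export
simulate_cohort <- function(cohort_size = 104, seed = 1,
                            stage_probs = c(Ta = 0.33, T1 = 0.22, T2 = 0.20,
                                            T3 = 0.12, T4 = 0.08, MET = 0.05),
                            membrane_prob = default_membrane_prob_by_stage(),
                            negative_prob = 0.15,
                            planted_log_hr = log(3.87),
                            baseline_mean_months = 148,
                            censoring_mean_months = 226,
                            weibull_shape = NULL) {
  if (cohort_size < 20) stop("cohort_size must be at least 20", call. = FALSE)
  withr::with_seed(derive_seed(seed, "cohort"), {
    stage <- sample(names(stage_probs), cohort_size, replace = TRUE,
                    prob = stage_probs)
    negative <- stats::runif(cohort_size) < negative_prob
    membrane <- !negative &
      stats::runif(cohort_size) < membrane_prob[stage]
    location <- dplyr::case_when(
      negative ~ "negative",
      membrane ~ "membrane_and_cytoplasm",
      TRUE ~ "cytoplasm"
    )
    intensity <- ifelse(negative, 0L, sample(1:3, cohort_size, replace = TRUE))
    extension <- ifelse(negative, 0L,
                        10L * sample(1:10, cohort_size, replace = TRUE))
    rate <- exp(planted_log_hr * membrane) / baseline_mean_months
    surv_time <- if (is.null(weibull_shape)) {
      stats::rexp(cohort_size, rate)
    } else {
      stats::rweibull(cohort_size, shape = weibull_shape,
                      scale = 1 / rate)
    }
    cens_time <- stats::rexp(cohort_size, 1 / censoring_mean_months)
    cohort <- tibble::tibble(
      patient_id = sprintf("PT%04d", seq_len(cohort_size)),
      stage = stage,
      grade = ifelse(stage %in% c("Ta", "T1") & stats::runif(cohort_size) < 0.6,
                     "low", "high"),
      intensity = as.integer(intensity),
      extension = as.integer(extension),
      location = location,
      followup_months = round(pmin(surv_time, cens_time), 2),
      event = as.integer(surv_time <= cens_time)
    )
    list(cohort = validate_cohort(cohort),
         truth = list(planted_log_hr = planted_log_hr,
                      membrane_prob = as.list(membrane_prob)))
  })
}

#' Write a synthetic-truth sidecar
#'
#' Serializes the `truth` element of any simulator's output as JSON next to
#' the generated dataset, so recovery metrics downstream never need to read
#' generator internals.
#'
#' @param truth A list or tibble of planted ground truth.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
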