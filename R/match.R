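# oxonium diagnostics checked in every glycopeptide spectrum
.oxonium_targets <- function() {
  c(hexnac = oxonium_mz(glycan_composition(hexnac = 1)),
    hexnac_hex = oxonium_mz(glycan_composition(hex = 1, hexnac = 1)))
}

# is any observed peak within tol of any target m/z?
any_peak_near <- function(peaks, targets, tol) {
  if (nrow(peaks) == 0) return(logical(length(targets)) | FALSE)
  vapply(targets, function(t) any(abs(peaks$mz - t) <= tol), logical(1))
}

count_matched <- function(theoretical_mz, peaks, tol) {
  if (nrow(peaks) == 0) return(0L)
  sum(vapply(theoretical_mz, function(t) any(abs(peaks$mz - t) <= tol), logical(1)))
}

empty_psm <- function() {
  tibble::tibble(
    protein_id = character(0), peptide = character(0),
    start = integer(0), end = integer(0),
    modifications = list(), matched_fraction = numeric(0),
    oxonium_present = logical(0), localization = character(0),
    candidate_sites = list(), confidence = character(0)
  )
}

#' Match a spectrum against a glycopeptide candidate
#'
#' Scores one candidate (peptide plus modifications) against one spectrum.
#' The candidate is accepted only when the observed precursor m/z is within
#' the ppm tolerance of the theoretical value. The score is the matched-ion
#' fraction: matched theoretical fragments over emitted theoretical fragments
#' at the Da fragment tolerance. Oxonium evidence (a peak near the HexNAc ion
#' at 204.09 or the Hex-HexNAc ion at 366.14) is required, together with a
#' matched fraction at or above `min_matched_fraction`, for a glycopeptide to
#' reach `high` confidence; otherwise the PSM is `medium_low`.
#'
#' @param spectrum A one-row tibble (or list) with `precursor_mz`, `charge`
#'   and a `peaks` tibble, as produced by [read_mgf()].
#' @param peptide Candidate peptide sequence.
#' @param modifications Data frame with `position` (1-based in peptide) and
#'   `name`, or NULL.
#' @param config A [search_config()].
#' @param protein_id,peptide_start Provenance carried into the PSM; candidate
#'   glycosites are reported in 1-based protein coordinates via
#'   `peptide_start`.
#' @return A one-row GlycoPSM tibble (`protein_id`, `peptide`, `start`, `end`,
#'   `modifications`, `matched_fraction`, `oxonium_present`, `localization`,
#'   `candidate_sites`, `confidence`), or a zero-row tibble when the
#'   precursor does not match.
#' @export
match_spectrum <- function(spectrum, peptide, modifications = NULL,
                           config = search_config(),
                           protein_id = NA_character_, peptide_start = 1L) {
  if (is.data.frame(spectrum)) spectrum <- as.list(spectrum[1, ])
  if (is.list(spectrum$peaks) && !is.data.frame(spectrum$peaks)) {
    spectrum$peaks <- spectrum$peaks[[1]]
  }
  if (is.null(spectrum$precursor_mz) || is.na(spectrum$precursor_mz) ||
      is.null(spectrum$charge) || is.na(spectrum$charge)) {
    stop("missing precursor metadata (precursor m/z and charge required)",
         call. = FALSE)
  }
  modifications <- validate_modifications(peptide, modifications,
                                          config$modification_table)
  z <- spectrum$charge
  neutral <- peptide_neutral_mass(peptide, modifications, config$modification_table)
  theo_mz <- (neutral + z * .proton_mass) / z
  ppm <- abs(spectrum$precursor_mz - theo_mz) / theo_mz * 1e6
  if (ppm > config$precursor_tol_ppm) return(empty_psm())

  theo <- theoretical_ions(peptide, modifications, config$ion_series,
                           z_dot = config$z_dot,
                           modification_table = config$modification_table)
  peaks <- normalize_peaks(spectrum$peaks)
  matched_fraction <- if (nrow(theo) == 0) 0 else
    count_matched(theo$mz, peaks, config$fragment_tol_da) / nrow(theo)
  oxonium_present <- any(any_peak_near(peaks, .oxonium_targets(),
                                       config$fragment_tol_da))

  glyco_positions <- modifications$position[
    modifications$name %in% .glyco_mod_names]
  is_glyco <- length(glyco_positions) > 0
  confidence <- if (matched_fraction >= config$min_matched_fraction &&
                    (!is_glyco || oxonium_present)) "high" else "medium_low"

  tibble::tibble(
    protein_id = protein_id,
    peptide = peptide,
    start = as.integer(peptide_start),
    end = as.integer(peptide_start + nchar(peptide) - 1L),
    modifications = list(modifications),
    matched_fraction = matched_fraction,
    oxonium_present = oxonium_present,
    localization = if (is_glyco && length(glyco_positions) == 1 &&
                       length(st_sites(peptide)) == 1) "unique" else "unlocalized",
    candidate_sites = list(as.integer(peptide_start - 1L + glyco_positions)),
    confidence = confidence
  )
}

st_sites <- function(peptide) {
  which(strsplit(peptide, "")[[1]] %in% c("S", "T"))
}

# all distinct placements of the glyco-mod multiset onto candidate S/T sites;
# returns a list of tibbles(position, name)
glyco_placements <- function(sites, glyco_names) {
  k <- length(glyco_names)
  if (k == 0 || length(sites) < k) return(list())
  combos <- lapply(utils::combn(seq_along(sites), k, simplify = FALSE),
                   function(i) sites[i])
  perms <- unique_permutations(glyco_names)
  out <- list()
  for (cmb in combos) {
    for (p in perms) {
      out[[length(out) + 1]] <- tibble::tibble(position = cmb, name = p)
    }
  }
  out
}

unique_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in unique_permutations(rest)) out[[length(out) + 1]] <- c(v, p)
  }
  out
}

#' Localize O-glycosites from site-determining c/z ions
#'
#' Enumerates every placement of the glycan modifications of a PSM over the
#' candidate Ser/Thr sites of its peptide and counts, for each placement, the
#' matched site-determining c/z ions: fragment ions whose m/z differs between
#' at least two placements. The localization is `unique` when exactly one
#' placement has strictly more matched site-determining ions than every
#' other; otherwise `ambiguous` with the tied candidate set retained.
#'
#' @param peptide Peptide sequence carrying at least one Ser/Thr.
#' @param glyco_mods Character vector of glycan modification names
#'   (`"HexNAc"`, `"HexNAc-Hex"`) carried by the peptide.
#' @param peaks Observed fragment peaks (tibble with `mz`, `intensity`).
#' @param config A [search_config()] with c and/or z in `ion_series`.
#' @param peptide_start 1-based start of the peptide in its protein, used to
#'   report candidate sites in protein coordinates.
#' @return A list with `localization` (`"unique"`/`"ambiguous"`), `sites`
#'   (protein coordinates of the best placement, or of all tied placements),
#'   `best_modifications` (tibble of the winning placement in peptide
#'   coordinates) and `evidence` (per-placement matched site-determining ion
#'   counts).
#' @export
localize_glycosite <- function(peptide, glyco_mods, peaks,
                               config = search_config(), peptide_start = 1L) {
  if (!any(c("c", "z") %in% config$ion_series)) {
    stop("localization requires c and/or z ions in the ion series", call. = FALSE)
  }
  sites <- st_sites(peptide)
  if (length(sites) == 0) stop("no candidate S/T site in peptide", call. = FALSE)
  glyco_mods <- as.character(glyco_mods)
  placements <- glyco_placements(sites, glyco_mods)
  if (length(placements) == 0) {
    stop("more glycans than candidate sites", call. = FALSE)
  }
  peaks <- normalize_peaks(peaks)
  cz <- intersect(config$ion_series, c("c", "z"))
  ladders <- purrr::map(placements, function(m) {
    theoretical_ions(peptide, m, cz, z_dot = config$z_dot,
                     modification_table = config$modification_table)
  })
  if (length(placements) == 1) {
    m <- placements[[1]]
    return(list(
      localization = "unique",
      sites = as.integer(peptide_start - 1L + sort(m$position)),
      best_modifications = m,
      evidence = tibble::tibble(placement = 1L, matched_site_determining = NA_integer_)
    ))
  }
  # site-determining: for a given ion label, masses are not all identical
  # across placements
  labels <- ladders[[1]]$label
  mz_mat <- vapply(ladders, function(l) l$mz[match(labels, l$label)],
                   numeric(length(labels)))
  determining <- apply(mz_mat, 1, function(v) {
    max(v) - min(v) > 1e-9
  })
  counts <- vapply(seq_along(placements), function(i) {
    count_matched(mz_mat[determining, i], peaks, config$fragment_tol_da)
  }, integer(1))
  best <- max(counts)
  winners <- which(counts == best)
  if (length(winners) == 1) {
    m <- placements[[winners]]
    list(
      localization = "unique",
      sites = as.integer(peptide_start - 1L + sort(m$position)),
      best_modifications = m,
      evidence = tibble::tibble(placement = seq_along(placements),
                                matched_site_determining = counts)
    )
  } else {
    tied_sites <- sort(unique(unlist(
      purrr::map(placements[winners], function(m) m$position))))
    list(
      localization = "ambiguous",
      sites = as.integer(peptide_start - 1L + tied_sites),
      best_modifications = placements[[winners[1]]],
      evidence = tibble::tibble(placement = seq_along(placements),
                                matched_site_determining = counts)
    )
  }
}

#' Annotate glycopeptide spectra against a proteome
#'
#' The end-to-end search: digests every protein, enumerates glycopeptide
#' candidates (a multiset of HexNAc / HexNAc-Hex modifications over the
#' peptide's Ser/Thr sites, up to `max_glycans_per_peptide`) whose precursor
#' matches within the ppm tolerance, scores each candidate placement with
#' [match_spectrum()] semantics, localizes glycosites from site-determining
#' c/z ions when the ion series allows, and reports the best PSM per
#' spectrum.
#'
#' @param spectra A spectra tibble as returned by [read_mgf()].
#' @param proteins A tibble with `protein_id` and `sequence`.
#' @param config A [search_config()].
#' @return A GlycoPSM tibble, one row per confidently assigned spectrum, with
#'   `spectrum_id` prepended.
#' @export
annotate_glycopeptides <- function(spectra, proteins, config = search_config()) {
  mods <- config$modification_table
  glyco_deltas <- mods$delta_mass[match(.glyco_mod_names, mods$name)]

  peptides <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    d <- digest(proteins$sequence[i], config$protease, config$max_missed_cleavages)
    d$protein_id <- proteins$protein_id[i]
    d
  })
  peptides <- dplyr::distinct(peptides, .data$protein_id, .data$peptide,
                              .keep_all = TRUE)
  peptides$base_mass <- vapply(peptides$peptide, peptide_neutral_mass, numeric(1))
  peptides$n_st <- vapply(peptides$peptide, function(p) length(st_sites(p)), integer(1))

  # glyco count combinations (HexNAc count, HexNAc-Hex count), including none
  combos <- tidyr::expand_grid(
    n_hexnac = 0:config$max_glycans_per_peptide,
    n_hexnachex = 0:config$max_glycans_per_peptide
  )
  combos <- combos[combos$n_hexnac + combos$n_hexnachex <=
                     config$max_glycans_per_peptide, ]
  combos$delta <- combos$n_hexnac * glyco_deltas[1] +
    combos$n_hexnachex * glyco_deltas[2]

  out <- purrr::map_dfr(seq_len(nrow(spectra)), function(si) {
    spec <- list(precursor_mz = spectra$precursor_mz[si],
                 charge = spectra$charge[si],
                 peaks = spectra$peaks[[si]])
    if (is.na(spec$precursor_mz) || is.na(spec$charge)) return(empty_psm())
    z <- spec$charge
    neutral_obs <- z * (spec$precursor_mz - .proton_mass)
    tol_da <- spec$precursor_mz * config$precursor_tol_ppm / 1e6 * z

    best_psm <- NULL
    best_key <- c(-Inf, -Inf)
    for (ci in seq_len(nrow(combos))) {
      k <- combos$n_hexnac[ci] + combos$n_hexnachex[ci]
      cand <- peptides[abs(peptides$base_mass + combos$delta[ci] - neutral_obs)
                       <= tol_da & peptides$n_st >= k, ]
      if (nrow(cand) == 0) next
      glyco_names <- c(rep("HexNAc", combos$n_hexnac[ci]),
                       rep("HexNAc-Hex", combos$n_hexnachex[ci]))
      for (pi in seq_len(nrow(cand))) {
        pep <- cand$peptide[pi]
        loc <- NULL
        placement <- tibble::tibble(position = integer(0), name = character(0))
        if (k > 0) {
          if (any(c("c", "z") %in% config$ion_series)) {
            loc <- localize_glycosite(pep, glyco_names, spec$peaks, config,
                                      peptide_start = cand$start[pi])
            placement <- loc$best_modifications
          } else {
            placement <- glyco_placements(st_sites(pep), glyco_names)[[1]]
          }
        }
        psm <- match_spectrum(spec, pep, placement, config,
                              protein_id = cand$protein_id[pi],
                              peptide_start = cand$start[pi])
        if (nrow(psm) == 0) next
        if (!is.null(loc)) {
          psm$localization <- loc$localization
          psm$candidate_sites <- list(loc$sites)
        }
        key <- c(psm$matched_fraction,
                 as.integer(identical(psm$localization, "unique")))
        if (key[1] > best_key[1] ||
            (key[1] == best_key[1] && key[2] > best_key[2])) {
          best_key <- key
          best_psm <- psm
        }
      }
    }
    if (is.null(best_psm)) return(empty_psm())
    dplyr::bind_cols(tibble::tibble(spectrum_id = spectra$spectrum_id[si]), best_psm)
  })
  out
}
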