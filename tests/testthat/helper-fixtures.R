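# Shared fixture builders.

make_psm <- function(protein, peptide, confidence, glyco = "HexNAc") {
  tibble::tibble(
    protein_id = protein, peptide = peptide, start = 1L,
    end = nchar(peptide),
    modifications = list(tibble::tibble(position = 1L, name = glyco)),
    matched_fraction = 0.5, oxonium_present = TRUE,
    localization = "unique", candidate_sites = list(1L),
    confidence = confidence
  )
}

# finite attribute lattice for exhaustive target-score enumeration
score_lattice <- function() {
  tissue_levels <- c("high", "moderate", "low", "negative")
  tidyr::expand_grid(
    tissue = tissue_levels,
    urothelium = c("high", "moderate", "low", "negative"),
    tumour_bin = c("unknown", "negative", "low", "moderate", "high"),
    membrane = c(FALSE, TRUE),
    prognosis = c(FALSE, TRUE),
    de_status = c("unknown", "not_up", "up_MIBC"),
    lymphoid_or_gamete = c(TRUE, FALSE)
  )
}

lattice_score <- function(row) {
  target_score(
    healthy_tissue_profile = c(tissue = row$tissue),
    urothelium = row$urothelium, tumour_bin = row$tumour_bin,
    membrane = row$membrane, prognosis = row$prognosis,
    de_status = row$de_status, lymphoid_or_gamete = row$lymphoid_or_gamete
  )
}
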