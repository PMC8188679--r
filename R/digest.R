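#' Default variable-modification table
#'
#' The four variable modifications of the glycoproteomic searches: methionine
#' oxidation, cysteine carbamidomethylation, and O-glycosylation of Ser/Thr
#' with a single HexNAc (Tn antigen) or HexNAc-Hex (T antigen). Delta masses
#' are exact monoisotopic values computed from elemental formulas; the
#' familiar nominal values (+15.99, +57.02, +203.1, +365.1) are their
#' rounded forms.
#'
#' @return A tibble with `name`, `delta_mass` (Da), `allowed_residues`
#'   (string of amino-acid letters) and `glyco` (logical).
#' @export
default_modification_table <- function() {
  tibble::tibble(
    name = c("Oxidation", "Carbamidomethyl", "HexNAc", "HexNAc-Hex"),
    delta_mass = c(
      formula_mass(O = 1),
      formula_mass(C = 2, H = 3, N = 1, O = 1),
      unname(.glycan_residues[["hexnac"]]),
      unname(.glycan_residues[["hexnac"]] + .glycan_residues[["hex"]])
    ),
    allowed_residues = c("M", "C", "ST", "ST"),
    glyco = c(FALSE, FALSE, TRUE, TRUE)
  )
}

.glyco_mod_names <- c("HexNAc", "HexNAc-Hex")

#' Search configuration for glycopeptide annotation
#'
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 5).
#' @param fragment_tol_da Fragment tolerance in Da (default 0.1).
#' @param ion_series Character vector drawn from `b`, `y`, `c`, `z`. CID-style
#'   searches use `c("b","y")`; EThcD searches add the c/z ions that preserve
#'   labile O-glycans (default).
#' @param protease `"trypsin"` or `"chymotrypsin"`.
#' @param max_missed_cleavages Maximum missed cleavages (default 2).
#' @param max_glycans_per_peptide Maximum occupied glycosites per peptide
#'   (default 3).
#' @param min_matched_fraction Matched-ion fraction required (together with
#'   oxonium evidence for glycopeptides) for `high` confidence (default 0.6).
#' @param z_dot Use z-dot (z+1) ions, the radical species observed in
#'   ETD-based fragmentation (default TRUE).
#' @param modification_table See [default_modification_table()].
#' @return A `search_config` list.
#' @export
search_config <- function(precursor_tol_ppm = 5, fragment_tol_da = 0.1,
                          ion_series = c("b", "y", "c", "z"),
                          protease = c("trypsin", "chymotrypsin"),
                          max_missed_cleavages = 2, max_glycans_per_peptide = 3,
                          min_matched_fraction = 0.6, z_dot = TRUE,
                          modification_table = default_modification_table()) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_da > 0,
            length(ion_series) > 0, all(ion_series %in% c("b", "y", "c", "z")))
  structure(list(
    precursor_tol_ppm = precursor_tol_ppm,
    fragment_tol_da = fragment_tol_da,
    ion_series = unique(ion_series),
    protease = match.arg(protease),
    max_missed_cleavages = max_missed_cleavages,
    max_glycans_per_peptide = max_glycans_per_peptide,
    min_matched_fraction = min_matched_fraction,
    z_dot = z_dot,
    modification_table = modification_table
  ), class = "search_config")
}

check_sequence <- function(sequence) {
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(.aa_residues))
  if (length(bad) > 0) {
    stop("illegal residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  residues
}

#' In-silico proteolytic digestion
#'
#' Trypsin cleaves C-terminal to K/R but not before proline; chymotrypsin
#' C-terminal to F/W/Y/L/M, also not before proline (the high-specificity
#' dialect). All peptides with up to `max_missed` missed cleavages are
#' returned with 1-based protein coordinates.
#'
#' @param sequence Protein sequence (standard one-letter amino-acid codes).
#' @param protease `"trypsin"` or `"chymotrypsin"`.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @return A tibble with `peptide`, `start`, `end`, `missed_cleavages`.
#' @examples
#' digest("AKRPW", "trypsin", max_missed = 0)  # AK, RPW: no cleavage at R|P
#' @export
digest <- function(sequence, protease = c("trypsin", "chymotrypsin"), max_missed = 2) {
  protease <- match.arg(protease)
  residues <- check_sequence(sequence)
  n <- length(residues)
  cleave_after <- switch(protease,
    trypsin = c("K", "R"),
    chymotrypsin = c("F", "W", "Y", "L", "M")
  )
  # cut points: position i means a cut between residue i and i+1
  cuts <- which(residues[-n] %in% cleave_after & residues[-1] != "P")
  bounds <- c(0, cuts, n)
  starts <- utils::head(bounds, -1) + 1
  ends <- bounds[-1]
  pieces <- tibble::tibble(start = as.integer(starts), end = as.integer(ends))
  out <- purrr::map_dfr(seq_len(nrow(pieces)), function(i) {
    js <- seq(i, min(i + max_missed, nrow(pieces)))
    tibble::tibble(
      start = pieces$start[i],
      end = pieces$end[js],
      missed_cleavages = js - i
    )
  })
  out$peptide <- vapply(seq_len(nrow(out)), function(i) {
    paste(residues[out$start[i]:out$end[i]], collapse = "")
  }, character(1))
  out[, c("peptide", "start", "end", "missed_cleavages")]
}

# neutral monoisotopic peptide mass including modification deltas
peptide_neutral_mass <- function(peptide, modifications = NULL,
                                 modification_table = default_modification_table()) {
  residues <- check_sequence(peptide)
  delta <- 0
  if (!is.null(modifications) && nrow(modifications) > 0) {
    delta <- sum(modification_table$delta_mass[
      match(modifications$name, modification_table$name)
    ])
  }
  sum(.aa_residues[residues]) + .mass_water + delta
}

validate_modifications <- function(peptide, modifications, modification_table) {
  if (is.null(modifications) || nrow(modifications) == 0) {
    return(tibble::tibble(position = integer(0), name = character(0)))
  }
  modifications <- tibble::as_tibble(modifications)
  residues <- strsplit(peptide, "")[[1]]
  if (any(modifications$position < 1 | modifications$position > length(residues))) {
    stop("modification position outside peptide", call. = FALSE)
  }
  idx <- match(modifications$name, modification_table$name)
  if (anyNA(idx)) {
    stop("unknown modification: ",
         paste(modifications$name[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ok <- mapply(function(pos, row) {
    grepl(residues[pos], modification_table$allowed_residues[row], fixed = TRUE)
  }, modifications$position, idx)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("invalid modification: ", modifications$name[bad], " not allowed on ",
         residues[modifications$position[bad]], " at position ",
         modifications$position[bad], call. = FALSE)
  }
  if (anyDuplicated(modifications$position)) {
    stop("at most one modification per residue", call. = FALSE)
  }
  modifications
}

#' Theoretical fragment ions of a (modified) peptide
#'
#' Singly charged monoisotopic b/y/c/z ions with modification deltas applied
#' to the correct prefix or suffix. Conventions: `c = b + NH3`; z ions are
#' z-dot (`z = y - NH3 + H`) by default, plain `z = y - NH3` when
#' `z_dot = FALSE`. Fragment indices run 1..n-1.
#'
#' @param peptide Peptide sequence.
#' @param modifications A data frame with `position` (1-based in the peptide)
#'   and `name` (matching the modification table), or NULL.
#' @param series Character vector drawn from `b`, `y`, `c`, `z`.
#' @param z_dot Use z-dot (z+1) ions (default TRUE).
#' @param modification_table See [default_modification_table()].
#' @return A tibble with `series`, `index`, `label`, `mz`.
#' @examples
#' theoretical_ions("SAK", tibble::tibble(position = 1, name = "HexNAc"))
#' @export
theoretical_ions <- function(peptide, modifications = NULL,
                             series = c("b", "y", "c", "z"), z_dot = TRUE,
                             modification_table = default_modification_table()) {
  stopifnot(all(series %in% c("b", "y", "c", "z")))
  residues <- check_sequence(peptide)
  n <- length(residues)
  modifications <- validate_modifications(peptide, modifications, modification_table)
  deltas <- numeric(n)
  if (nrow(modifications) > 0) {
    deltas[modifications$position] <- modification_table$delta_mass[
      match(modifications$name, modification_table$name)
    ]
  }
  if (n < 2) {
    return(tibble::tibble(series = character(0), index = integer(0),
                          label = character(0), mz = numeric(0)))
  }
  prefix <- cumsum(.aa_residues[residues] + deltas)
  idx <- seq_len(n - 1)
  b <- prefix[idx] + .proton_mass
  y <- (prefix[n] - prefix[n - idx]) + .mass_water + .proton_mass
  z_shift <- if (z_dot) -.mass_nh3 + .elements[["H"]] else -.mass_nh3
  pieces <- list(
    b = tibble::tibble(series = "b", index = idx, mz = unname(b)),
    y = tibble::tibble(series = "y", index = idx, mz = unname(y)),
    c = tibble::tibble(series = "c", index = idx, mz = unname(b) + .mass_nh3),
    z = tibble::tibble(series = "z", index = idx, mz = unname(y) + z_shift)
  )
  out <- dplyr::bind_rows(pieces[intersect(c("b", "y", "c", "z"), series)])
  out$label <- paste0(out$series, out$index)
  out[, c("series", "index", "label", "mz")]
}
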