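#' Read an MGF peak-list file
#'
#' Parses the Mascot Generic Format dialect used throughout the package:
#' `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` (m/z and optional
#' intensity) and `CHARGE` headers honoured; unknown keys are ignored.
#'
#' @param path Path to an MGF file.
#' @return A tibble of spectra with one row per spectrum: `spectrum_id`
#'   (TITLE, or a running index), `precursor_mz`, `charge`, and a `peaks`
#'   list-column of tibbles with `mz` and `intensity`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  spectra <- purrr::map2(begins, ends, function(b, e) {
    body <- lines[(b + 1):(e - 1)]
    body <- body[nzchar(trimws(body))]
    is_header <- grepl("^[A-Za-z][A-Za-z0-9_]*=", body)
    headers <- body[is_header]
    keys <- toupper(sub("=.*$", "", headers))
    vals <- sub("^[^=]*=", "", headers)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else NA_character_
    pepmass <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]][1])
    } else NA_real_
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", trimws(vals[match("CHARGE", keys)])))
    } else NA_integer_
    peak_lines <- body[!is_header]
    peaks <- if (length(peak_lines) > 0) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[\\s\\t]+", perl = TRUE),
                                   function(x) as.numeric(x[1:2])))
      normalize_peaks(tibble::tibble(mz = mat[, 1], intensity = mat[, 2]))
    } else {
      tibble::tibble(mz = numeric(0), intensity = numeric(0))
    }
    list(title = title, precursor_mz = pepmass, charge = charge, peaks = peaks)
  })
  tibble::tibble(
    spectrum_id = purrr::imap_chr(spectra, function(s, i) {
      if (is.na(s$title)) paste0("spectrum_", i) else s$title
    }),
    precursor_mz = purrr::map_dbl(spectra, "precursor_mz"),
    charge = purrr::map_int(spectra, "charge"),
    peaks = purrr::map(spectra, "peaks")
  )
}

#' Write spectra to an MGF file
#'
#' @param spectra A tibble as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap(spectra, function(spectrum_id, precursor_mz, charge, peaks, ...) {
    header <- c(
      "BEGIN IONS",
      paste0("TITLE=", spectrum_id),
      if (!is.na(precursor_mz)) sprintf("PEPMASS=%.6f", precursor_mz),
      if (!is.na(charge)) paste0("CHARGE=", charge, "+")
    )
    body <- sprintf("%.6f %.6f", peaks$mz, peaks$intensity)
    c(header, body, "END IONS", "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Read a two-column TSV peak list
#'
#' @param path Path to a headerless or headered TSV with m/z and intensity
#'   columns.
#' @return A tibble with `mz` and `intensity`.
#' @export
read_peaks_tsv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.delim(path, header = has_header, sep = "\t")
  names(tab)[1:2] <- c("mz", "intensity")
  normalize_peaks(tab[, 1:2])
}

#' Read / write a glycan library
#'
#' TSV with columns `label`, `hex`, `hexnac`, `dhex`, `neuac` (and optionally
#' `expected_mz`; recomputed from compositions when absent), or a JSON array
#' of objects with the same fields.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @param adduct Adduct used when recomputing `expected_mz`.
#' @return A validated glycan library tibble.
#' @export
read_glycan_library <- function(path, adduct = "proton") {
  lib <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tibble::as_tibble(utils::read.delim(path, sep = "\t"))
  }
  if (!"expected_mz" %in% names(lib)) {
    lib$expected_mz <- purrr::pmap_dbl(
      lib[c("hex", "hexnac", "dhex", "neuac")],
      function(hex, hexnac, dhex, neuac) {
        permethylated_bn_mz(glycan_composition(hex, hexnac, dhex, neuac), adduct)
      }
    )
  }
  validate_glycan_library(lib)
}

#' @rdname read_glycan_library
#' @param library A glycan library tibble.
#' @export
write_glycan_library <- function(library, path) {
  library <- validate_glycan_library(library)
  utils::write.table(library, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write protein FASTA
#'
#' Thin tabular wrappers over Biostrings.
#'
#' @param path Path to a FASTA file.
#' @return `read_fasta()`: a tibble with `protein_id` (first word of the
#'   header) and `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    protein_id = vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1),
    sequence = unname(as.character(aa))
  )
}

#' @rdname read_fasta
#' @param proteins A tibble with `protein_id` and `sequence`.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, proteins$protein_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Write a glycopeptide-spectrum-match table
#'
#' @param psms A GlycoPSM tibble (see [match_spectrum()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  flat <- dplyr::mutate(
    psms,
    modifications = purrr::map_chr(.data$modifications, function(m) {
      if (nrow(m) == 0) "" else paste(sprintf("%s@%d", m$name, m$position), collapse = ";")
    }),
    candidate_sites = purrr::map_chr(.data$candidate_sites,
                                     function(s) paste(s, collapse = ";"))
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a patient cohort table
#'
#' TSV with columns `patient_id`, `stage` (Ta/T1/T2/T3/T4/MET), `grade`
#' (low/high), `intensity` (0-3), `extension` (percent, multiples of 10),
#' `location` (cytoplasm / membrane_and_cytoplasm / negative),
#' `followup_months`, `event` (0/1).
#'
#' @param path Path to the TSV.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  validate_cohort(tibble::as_tibble(utils::read.delim(path, sep = "\t")))
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  required <- c("patient_id", "stage", "grade", "intensity", "extension",
                "location", "followup_months", "event")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stages <- c("Ta", "T1", "T2", "T3", "T4", "MET")
  if (!all(cohort$stage %in% stages)) stop("unknown stage value", call. = FALSE)
  if (!all(cohort$grade %in% c("low", "high"))) stop("unknown grade value", call. = FALSE)
  if (!all(cohort$location %in% c("cytoplasm", "membrane_and_cytoplasm", "negative"))) {
    stop("unknown location value", call. = FALSE)
  }
  if (any(cohort$followup_months < 0)) stop("follow-up must be >= 0", call. = FALSE)
  tibble::as_tibble(cohort)
}
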