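#' Glycan composition
#'
#' Builds a monosaccharide composition: counts of hexose (Hex, e.g. Gal),
#' N-acetylhexosamine (HexNAc, e.g. GalNAc), deoxyhexose (dHex, fucose) and
#' N-acetylneuraminic acid (NeuAc, sialic acid). This is the unit of glycan
#' identity throughout the package: mass computation, library entries and
#' spectrum annotation all consume compositions rather than structures.
#'
#' @param hex,hexnac,dhex,neuac Non-negative integer residue counts.
#' @return An object of class `glycan_composition` (a named integer vector).
#' @examples
#' glycan_composition(hex = 1, hexnac = 1, neuac = 1)  # sialyl-T
#' @export
glycan_composition <- function(hex = 0, hexnac = 0, dhex = 0, neuac = 0) {
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != trunc(counts))) {
    stop("residue counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(counts), names = names(counts), class = "glycan_composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  lab <- c(hex = "Hex", hexnac = "HexNAc", dhex = "dHex", neuac = "NeuAc")
  nz <- x[x > 0]
  if (length(nz) == 0) return("empty")
  paste0(lab[names(nz)], nz, collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format(x), "\n", sep = "")
  invisible(x)
}

as_glycan_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    x <- as.list(x)
  }
  if (is.list(x)) {
    known <- c("hex", "hexnac", "dhex", "neuac")
    extra <- setdiff(names(x), known)
    if (length(extra) > 0) {
      stop("unsupported residue kind(s): ", paste(extra, collapse = ", "), call. = FALSE)
    }
    return(do.call(glycan_composition, x[intersect(known, names(x))]))
  }
  stop("cannot interpret as a glycan composition", call. = FALSE)
}

#' Mass increment of one permethylated residue
#'
#' The monoisotopic mass added when one fully permethylated residue extends an
#' already-permethylated glycan. The increment is linkage-independent: each
#' extension consumes one methylation site on the acceptor and brings its own
#' methylated hydroxyls, so the net gain is the dehydro residue mass plus a
#' fixed number of CH2 groups (Hex and HexNAc 3, dHex 2, NeuAc 5).
#'
#' @param kind One of `"Hex"`, `"HexNAc"`, `"dHex"`, `"NeuAc"`
#'   (case-insensitive).
#' @return Increment in Da.
#' @examples
#' permethylated_residue_increment("NeuAc")  # 361.17
#' @export
permethylated_residue_increment <- function(kind) {
  key <- tolower(kind)
  if (length(key) != 1 || !key %in% names(.glycan_residues)) {
    stop("unsupported residue kind: ", paste(kind, collapse = ", "),
         " (expected Hex, HexNAc, dHex or NeuAc)", call. = FALSE)
  }
  unname(.glycan_residues[key] + .permethyl_sites[key] * .mass_ch2)
}

# Aglycone closure of the permethylated benzyl glycoside: the benzyl cap plus
# the core residue's residual methylation site, C8H10O. Together with the
# per-residue increments this reproduces the full printed ion ladder.
.bn_aglycone_mass <- formula_mass(C = 8, H = 10, O = 1)

#' m/z of a permethylated benzyl O-glycan
#'
#' Singly charged monoisotopic m/z of the fully permethylated benzyl glycoside
#' of a composition, as observed in cellular O-glycome reporter/amplification
#' (CORA) experiments where secreted benzyl O-glycans are permethylated before
#' nanoLC-ESI-MS. Built entirely from elemental formulas.
#'
#' @param composition A [glycan_composition()] (or a named list of counts).
#'   Must contain at least one HexNAc: the benzyl tag sits on the GalNAc core.
#' @param adduct `"proton"` (default; reproduces the printed ion ladder) or
#'   `"sodium"`.
#' @return m/z in Da (singly charged).
#' @examples
#' permethylated_bn_mz(glycan_composition(hex = 1, hexnac = 1))           # T antigen, 572.3
#' permethylated_bn_mz(glycan_composition(hex = 1, hexnac = 1, neuac = 1)) # sialyl-T, 933.5
#' @export
permethylated_bn_mz <- function(composition, adduct = c("proton", "sodium")) {
  adduct <- match.arg(adduct)
  comp <- as_glycan_composition(composition)
  if (sum(comp) == 0) stop("empty composition", call. = FALSE)
  if (comp[["hexnac"]] < 1) {
    stop("invalid core: benzyl O-glycans require at least one HexNAc", call. = FALSE)
  }
  increments <- sum(vapply(
    c("Hex", "HexNAc", "dHex", "NeuAc"),
    function(k) comp[[tolower(k)]] * permethylated_residue_increment(k),
    numeric(1)
  ))
  charge_carrier <- if (adduct == "proton") .proton_mass else .elements[["Na"]]
  increments + .bn_aglycone_mass + charge_carrier
}

#' m/z of a glycan oxonium ion
#'
#' Singly charged monoisotopic m/z of the oxocarbenium fragment of a native
#' (non-permethylated) glycan: the sum of dehydro residue masses plus a
#' proton. These ions (e.g. HexNAc at 204.09, Hex-HexNAc at 366.14) are the
#' diagnostic fingerprint of glycopeptide MS/MS spectra.
#'
#' @param composition A [glycan_composition()] (or named list of counts);
#'   must be non-empty.
#' @return m/z in Da.
#' @examples
#' oxonium_mz(glycan_composition(hexnac = 1))           # 204.09
#' oxonium_mz(glycan_composition(hex = 1, hexnac = 1))  # 366.14
#' @export
oxonium_mz <- function(composition) {
  comp <- as_glycan_composition(composition)
  if (sum(comp) == 0) stop("empty composition", call. = FALSE)
  sum(comp * .glycan_residues[names(comp)]) + .proton_mass
}

#' Default O-glycan reference library
#'
#' The ten-species library of short-chain O-glycans observed in bladder cancer
#' cell line O-glycomes: Tn, T and sialylated/fucosylated T antigens plus
#' sialylated and/or fucosylated core 2 structures. Expected m/z values are
#' computed (not stored) from compositions via [permethylated_bn_mz()]. The
#' core 2 compositions are fixed by residue-increment arithmetic from the
#' observed ladder spacing.
#'
#' @param adduct Adduct passed to [permethylated_bn_mz()].
#' @return A tibble with columns `label`, `hex`, `hexnac`, `dhex`, `neuac`,
#'   `expected_mz`.
#' @examples
#' default_glycan_library()
#' @export
default_glycan_library <- function(adduct = "proton") {
  lib <- tibble::tribble(
    ~label,                    ~hex, ~hexnac, ~dhex, ~neuac,
    "Tn",                         0L,      1L,    0L,     0L,
    "T",                          1L,      1L,    0L,     0L,
    "STn",                        0L,      1L,    0L,     1L,
    "fucosyl-T",                  1L,      1L,    1L,     0L,
    "sialyl-T",                   1L,      1L,    0L,     1L,
    "sialyl-core2",               1L,      2L,    0L,     1L,
    "di-sialyl-T",                1L,      1L,    0L,     2L,
    "sialyl-core2-Hex",           2L,      2L,    0L,     1L,
    "sialyl-fucosyl-core2",       2L,      2L,    1L,     1L,
    "di-sialyl-core2",            2L,      2L,    0L,     2L
  )
  lib$expected_mz <- purrr::pmap_dbl(
    lib[c("hex", "hexnac", "dhex", "neuac")],
    function(hex, hexnac, dhex, neuac) {
      permethylated_bn_mz(glycan_composition(hex, hexnac, dhex, neuac), adduct)
    }
  )
  validate_glycan_library(lib)
}

validate_glycan_library <- function(library) {
  required <- c("label", "hex", "hexnac", "dhex", "neuac", "expected_mz")
  missing <- setdiff(required, names(library))
  if (length(missing) > 0) {
    stop("glycan library is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(library$label)) {
    stop("glycan library labels must be unique", call. = FALSE)
  }
  if (any(library$expected_mz <= 0)) stop("expected_mz must be positive", call. = FALSE)
  tibble::as_tibble(library)
}

#' Annotate an O-glycome peak list against a glycan library
#'
#' Matches each library species to the single nearest peak within `tolerance`
#' (ties broken by higher intensity, then lower m/z) and computes relative
#' abundances over the matched species. This is the relative quantification
#' underlying an O-glycome profile: matched intensity divided by the summed
#' intensity of all matched species, in percent. Unmatched species are kept
#' with zero abundance and flagged absent.
#'
#' @param peaks A peak list: a data frame with columns `mz` and `intensity`
#'   (see [read_mgf()] and [read_peaks_tsv()]), or an empty data frame.
#' @param library A glycan reference library (see [default_glycan_library()]).
#' @param tolerance Matching tolerance in Da (default 0.3, suited to
#'   one-decimal permethylated profile ions).
#' @return An `oglycome_profile`: a tibble with one row per library species
#'   and columns `label`, `expected_mz`, `matched_mz`, `intensity`,
#'   `relative_abundance` (percent; sums to 100 over matched species) and
#'   `absent`.
#' @examples
#' peaks <- tibble::tibble(mz = c(933.48, 1294.65), intensity = c(80, 20))
#' annotate_oglycome(peaks, default_glycan_library())
#' @export
annotate_oglycome <- function(peaks, library = default_glycan_library(),
                              tolerance = 0.3) {
  stopifnot(tolerance > 0)
  library <- validate_glycan_library(library)
  peaks <- normalize_peaks(peaks)

  match_one <- function(target) {
    if (nrow(peaks) == 0) return(NA_integer_)
    delta <- abs(peaks$mz - target)
    within <- which(delta <= tolerance)
    if (length(within) == 0) return(NA_integer_)
    # nearest peak; tie -> higher intensity, then lower m/z
    ord <- within[order(delta[within], -peaks$intensity[within], peaks$mz[within])]
    ord[[1]]
  }

  idx <- vapply(library$expected_mz, match_one, integer(1))
  out <- tibble::tibble(
    label = library$label,
    expected_mz = library$expected_mz,
    matched_mz = ifelse(is.na(idx), NA_real_, peaks$mz[idx]),
    intensity = ifelse(is.na(idx), 0, peaks$intensity[idx]),
    absent = is.na(idx)
  )
  total <- sum(out$intensity[!out$absent])
  out$relative_abundance <-
    if (total > 0) 100 * out$intensity / total else rep(0, nrow(out))
  out <- out[order(out$expected_mz), c("label", "expected_mz", "matched_mz",
                                       "intensity", "relative_abundance", "absent")]
  class(out) <- c("oglycome_profile", class(out))
  out
}

# canonical peak-list form: tibble(mz, intensity), mz strictly increasing,
# intensities >= 0; duplicate m/z collapsed by summed intensity
normalize_peaks <- function(peaks) {
  if (is.null(peaks) || nrow(as.data.frame(peaks)) == 0) {
    return(tibble::tibble(mz = numeric(0), intensity = numeric(0)))
  }
  peaks <- tibble::as_tibble(peaks)
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    stop("a peak list needs `mz` and `intensity` columns", call. = FALSE)
  }
  if (any(peaks$intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  agg <- dplyr::summarise(dplyr::group_by(peaks, .data$mz),
                          intensity = sum(.data$intensity), .groups = "drop")
  dplyr::arrange(agg, .data$mz)
}

#' @export
print.oglycome_profile <- function(x, ...) {
  cat("O-glycome profile:", sum(!x$absent), "of", nrow(x), "species matched\n")
  NextMethod()
}

#' @rdname annotate_oglycome
#' @param x An `oglycome_profile`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.oglycome_profile <- function(x, ...) {
  dat <- x[!x$absent, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$relative_abundance),
    y = .data$relative_abundance
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "relative abundance (%)",
                  title = "O-glycome profile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
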