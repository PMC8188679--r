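#' Curate glycoprotein candidates from a PSM table
#'
#' Groups glycopeptide-spectrum matches by protein and applies the curation
#' rule used to build the final glycoprotein list: a protein is retained when
#' it has at least one high-confidence glycopeptide, or two or more distinct
#' medium/low-confidence glycopeptides carrying HexNAc and/or HexNAc-Hex.
#' Glycopeptide multiplicity counts distinct peptide sequences, not spectra.
#'
#' @param psms A GlycoPSM tibble (see [annotate_glycopeptides()]); rows
#'   without a glycan modification are ignored.
#' @return A tibble with one row per protein: `protein_id`,
#'   `n_glyco_peptides` (distinct glycopeptide sequences),
#'   `n_high_confidence`, `glycosites` (list-column of protein coordinates)
#'   and `curated`.
#' @export
curate_proteins <- function(psms) {
  if (nrow(psms) == 0) {
    return(tibble::tibble(protein_id = character(0), n_glyco_peptides = integer(0),
                          n_high_confidence = integer(0), glycosites = list(),
                          curated = logical(0)))
  }
  is_glyco <- purrr::map_lgl(psms$modifications, function(m) {
    any(m$name %in% .glyco_mod_names)
  })
  glyco <- psms[is_glyco, , drop = FALSE]
  out <- glyco |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_glyco_peptides = dplyr::n_distinct(.data$peptide),
      n_high_confidence = dplyr::n_distinct(
        .data$peptide[.data$confidence == "high"]),
      glycosites = list(sort(unique(unlist(.data$candidate_sites)))),
      .groups = "drop"
    )
  out$curated <- out$n_high_confidence >= 1 | out$n_glyco_peptides >= 2
  dplyr::arrange(out, .data$protein_id)
}

#' Set arithmetic over per-source identification lists
#'
#' Union, intersection (identifiers common to every source), per-source
#' exclusive counts, and the percentage shared: the intersection over the
#' union, rounded to the nearest whole percent.
#'
#' @param sets A named list (length >= 2) of character vectors of protein
#'   identifiers.
#' @return A list with `union`, `intersection`, `per_source` (tibble with
#'   `source`, `n`, `exclusive`) and `percent_shared`.
#' @examples
#' venn_counts(list(T24 = as.character(1:607),
#'                  c5637 = as.character(c(1:257, 1000:1295))))
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2) stop("need at least two sources", call. = FALSE)
  sets <- purrr::map(sets, unique)
  all_ids <- unique(unlist(sets))
  inter <- purrr::reduce(sets, intersect)
  per_source <- tibble::tibble(
    source = names(sets),
    n = unname(lengths(sets)),
    exclusive = unname(purrr::imap_int(sets, function(s, nm) {
      others <- unlist(sets[setdiff(names(sets), nm)])
      length(setdiff(s, others))
    }))
  )
  list(
    union = length(all_ids),
    intersection = length(inter),
    per_source = per_source,
    percent_shared = round_half_up(100 * length(inter) / max(length(all_ids), 1))
  )
}

#' Differential-expression filter
#'
#' Annotates candidates with their tumour-vs-normal differential-expression
#' status. A gene passes when its linear fold change is at least `min_fold`
#' and its p-value at most `max_p` (both boundaries inclusive). Identifiers
#' absent from the table are `unknown`.
#'
#' @param candidates A tibble with a `protein_id` column.
#' @param de_table A tibble with `protein_id`, `fold_change`, `p_value` and
#'   optionally `cohort` (`"MIBC"` or `"both"`; defaults to `"MIBC"`).
#' @param min_fold Minimum linear fold change (default 2).
#' @param max_p Maximum p-value (default 0.05).
#' @return `candidates` with `de_status` (`up_MIBC`/`up_both`/`not_up`/
#'   `unknown`), `fold_change` and `p_value` columns added.
#' @export
apply_de_filter <- function(candidates, de_table, min_fold = 2, max_p = 0.05) {
  stopifnot(min_fold > 1, max_p > 0, max_p < 1)
  de_table <- tibble::as_tibble(de_table)
  required <- c("protein_id", "fold_change", "p_value")
  missing <- setdiff(required, names(de_table))
  if (length(missing) > 0) {
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(de_table$fold_change) | is.na(de_table$p_value) |
                 de_table$fold_change <= 0 |
                 de_table$p_value < 0 | de_table$p_value > 1)
  if (length(bad) > 0) {
    stop("malformed DE table row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!"cohort" %in% names(de_table)) de_table$cohort <- "MIBC"
  idx <- match(candidates$protein_id, de_table$protein_id)
  fold <- de_table$fold_change[idx]
  p <- de_table$p_value[idx]
  up <- !is.na(fold) & fold >= min_fold & p <= max_p
  candidates$de_status <- dplyr::case_when(
    is.na(idx) ~ "unknown",
    up & de_table$cohort[idx] == "both" ~ "up_both",
    up ~ "up_MIBC",
    TRUE ~ "not_up"
  )
  candidates$fold_change <- fold
  candidates$p_value <- p
  candidates
}

#' Bin tumour expression by percent of positive patients
#'
#' Partition used for tumour immunohistochemistry prevalence: 80-100% of
#' patients positive is `high`, 40-79% `moderate`, 1-39% `low`, 0%
#' `negative`; proteins not addressed in tumours are `unknown`.
#'
#' @param percent_positive Percent of patients expressing the protein, in
#'   `[0, 100]`, or `NA` for not addressed. Vectorized.
#' @return Character vector of bins.
#' @examples
#' bin_tumour_expression(c(85, 40, 39, 0, NA))
#' @export
bin_tumour_expression <- function(percent_positive) {
  if (any(percent_positive < 0 | percent_positive > 100, na.rm = TRUE)) {
    stop("percent must be in [0, 100]", call. = FALSE)
  }
  dplyr::case_when(
    is.na(percent_positive) ~ "unknown",
    percent_positive >= 80 ~ "high",
    percent_positive >= 40 ~ "moderate",
    percent_positive >= 1 ~ "low",
    TRUE ~ "negative"
  )
}

#' Default target-score rubric
#'
#' The package's declared point allocation for the 0-15 target score. Each
#' component is exposed so alternative weightings are drop-in:
#' healthy-tissue absence (0-5, from a weighted burden of healthy-tissue
#' expression levels), absence from healthy urothelium (0-2), tumour
#' expression bin (0-3), plasma-membrane localization in cancer (0-2),
#' prognosis association (0-1), differential up-regulation (0-2), and a
#' lymphoid/gamete expression penalty of -3, with the total clamped to
#' `[0, 15]`. Unknown annotations score as worst case.
#'
#' @return A named list of rubric parameters.
#' @export
default_rubric <- function() {
  list(
    # weight of one healthy tissue expressed at each level
    tissue_level_weights = c(high = 2, moderate = 1, low = 0.5,
                             negative = 0, not_available = 0),
    # healthy-tissue points by maximum tolerated burden (first threshold met)
    tissue_burden_points = c(`0` = 5, `1` = 4, `2` = 3, `4` = 2, `8` = 1),
    urothelium_points = c(negative = 2, not_available = 2, low = 1,
                          moderate = 0, high = 0),
    tumour_bin_points = c(high = 3, moderate = 2, low = 1,
                          negative = 0, unknown = 0),
    membrane_points = 2,
    prognosis_points = 1,
    de_points = c(up_MIBC = 2, up_both = 2, not_up = 0, unknown = 0),
    lymphoid_gamete_penalty = 3,
    max_score = 15
  )
}

healthy_tissue_points <- function(profile, rubric) {
  levels <- unlist(profile)
  levels <- levels[!is.na(levels)]
  # no healthy-tissue data at all scores as worst case
  if (length(levels) == 0) return(0)
  weights <- rubric$tissue_level_weights[levels]
  # unrecognized levels are treated as the worst observed burden
  weights[is.na(weights)] <- max(rubric$tissue_level_weights)
  burden <- sum(weights)
  thresholds <- as.numeric(names(rubric$tissue_burden_points))
  ok <- which(burden <= thresholds)
  if (length(ok) == 0) 0 else unname(rubric$tissue_burden_points[ok[1]])
}

#' Target score of a candidate glycoprotein
#'
#' Ranks a glycoprotein for targeted-therapeutics potential on a 0-15 scale:
#' high scores require over-expression in bladder tumours, absence from
#' healthy urothelium and other healthy tissues, plasma-membrane localization
#' in cancer, an association with poor prognosis and transcriptomic
#' up-regulation, while expression in lymphoid tissues or gametes is
#' penalized to limit immune and reproductive off-target effects.
#'
#' @param healthy_tissue_profile Named character vector/list of healthy-tissue
#'   expression levels (`high`/`moderate`/`low`/`negative`/`not_available`),
#'   excluding urothelium.
#' @param urothelium Expression level in healthy urothelium.
#' @param tumour_bin Tumour expression bin from [bin_tumour_expression()].
#' @param membrane `TRUE` when the protein sits at the cancer-cell plasma
#'   membrane.
#' @param prognosis `TRUE` when associated with poor prognosis.
#' @param de_status Differential-expression status from [apply_de_filter()].
#' @param lymphoid_or_gamete `TRUE` when expressed in lymphoid tissue or
#'   gametes.
#' @param rubric A rubric list, see [default_rubric()].
#' @return Integer score in `[0, 15]`.
#' @examples
#' target_score(
#'   healthy_tissue_profile = c(brain = "negative", skin = "negative"),
#'   urothelium = "negative", tumour_bin = "high", membrane = TRUE,
#'   prognosis = TRUE, de_status = "up_MIBC", lymphoid_or_gamete = FALSE
#' )
#' @export
target_score <- function(healthy_tissue_profile = character(0),
                         urothelium = "unknown",
                         tumour_bin = "unknown",
                         membrane = FALSE,
                         prognosis = FALSE,
                         de_status = "unknown",
                         lymphoid_or_gamete = FALSE,
                         rubric = default_rubric()) {
  uro <- if (urothelium %in% names(rubric$urothelium_points)) {
    rubric$urothelium_points[[urothelium]]
  } else 0
  tum <- if (tumour_bin %in% names(rubric$tumour_bin_points)) {
    rubric$tumour_bin_points[[tumour_bin]]
  } else 0
  de <- if (de_status %in% names(rubric$de_points)) {
    rubric$de_points[[de_status]]
  } else 0
  score <- healthy_tissue_points(healthy_tissue_profile, rubric) +
    uro + tum +
    (if (isTRUE(membrane)) rubric$membrane_points else 0) +
    (if (isTRUE(prognosis)) rubric$prognosis_points else 0) +
    de -
    (if (isTRUE(lymphoid_or_gamete)) rubric$lymphoid_gamete_penalty else 0)
  as.integer(max(0, min(rubric$max_score, score)))
}

#' Score and rank candidate glycoproteins
#'
#' Applies [target_score()] to every row of an annotated candidate table and
#' orders the result: descending score, ties broken by tumour expression bin
#' (high first), then lexicographic protein id; stable and deterministic.
#'
#' @param candidates A tibble with columns `protein_id`,
#'   `healthy_tissue_profile` (list-column), `urothelium`, `tumour_bin`,
#'   `membrane`, `prognosis`, `de_status`, `lymphoid_or_gamete`.
#' @param rubric See [default_rubric()].
#' @param require_tumour_data Drop candidates whose `tumour_bin` is `unknown`
#'   before ranking (mirrors restricting the ranking to proteins with tumour
#'   expression data).
#' @return The input with a `target_score` column, ordered; class
#'   `ranked_candidates`.
#' @export
rank_candidates <- function(candidates, rubric = default_rubric(),
                            require_tumour_data = FALSE) {
  if (nrow(candidates) == 0) {
    out <- dplyr::mutate(candidates, target_score = integer(0))
    class(out) <- c("ranked_candidates", class(out))
    return(out)
  }
  if (require_tumour_data) {
    candidates <- candidates[candidates$tumour_bin != "unknown", , drop = FALSE]
  }
  candidates$target_score <- purrr::pmap_int(
    candidates[c("healthy_tissue_profile", "urothelium", "tumour_bin",
                 "membrane", "prognosis", "de_status", "lymphoid_or_gamete")],
    function(healthy_tissue_profile, urothelium, tumour_bin, membrane,
             prognosis, de_status, lymphoid_or_gamete) {
      target_score(healthy_tissue_profile, urothelium, tumour_bin, membrane,
                   prognosis, de_status, lymphoid_or_gamete, rubric)
    }
  )
  bin_rank <- match(candidates$tumour_bin,
                    c("high", "moderate", "low", "negative", "unknown"))
  out <- candidates[order(-candidates$target_score, bin_rank,
                          candidates$protein_id), , drop = FALSE]
  class(out) <- c("ranked_candidates", class(out))
  out
}

#' Write a ranked candidate table with provenance
#'
#' Writes the ranked TSV plus a JSON provenance sidecar (counts at each
#' filter stage, seed and config digest) so a ranking can be reproduced and
#' audited.
#'
#' @param ranked A `ranked_candidates` tibble.
#' @param path Output TSV path; the sidecar is written to `paste0(path,
#'   ".provenance.json")`.
#' @param seed Seed recorded in the sidecar.
#' @param stage_counts Optional named list of counts at each pipeline stage.
#' @return `path`, invisibly.
#' @export
write_ranked_candidates <- function(ranked, path, seed = NA_integer_,
                                    stage_counts = list()) {
  flat <- dplyr::mutate(
    tibble::as_tibble(ranked),
    healthy_tissue_profile = purrr::map_chr(
      .data$healthy_tissue_profile,
      function(p) paste(sprintf("%s=%s", names(p), unlist(p)), collapse = ";")
    )
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(
    seed = seed,
    n_ranked = nrow(ranked),
    stage_counts = stage_counts
  )
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname rank_candidates
#' @param x A `ranked_candidates` tibble.
#' @param ... Unused.
#' @export
autoplot.ranked_candidates <- function(x, ...) {
  dat <- tibble::as_tibble(x)
  dat$protein_id <- factor(dat$protein_id, levels = rev(dat$protein_id))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$target_score, y = .data$protein_id)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::scale_x_continuous(limits = c(0, 15.5), expand = c(0, 0)) +
    ggplot2::labs(x = "target score (0-15)", y = NULL,
                  title = "Candidate glycoprotein ranking") +
    ggplot2::theme_minimal()
}
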