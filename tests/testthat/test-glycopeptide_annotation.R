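test_that("digestion follows protease dialects and missed-cleavage bounds", {
  # trypsin: no cleavage at R|P
  d <- digest("AKRPW", "trypsin", max_missed = 0)
  expect_equal(d$peptide, c("AK", "RPW"))
  expect_equal(d$start, c(1, 3))
  expect_equal(d$end, c(2, 5))
  # chymotrypsin after F/W/Y/L/M
  expect_equal(digest("AWGF", "chymotrypsin", 0)$peptide, c("AW", "GF"))
  # enough missed cleavages always includes the full sequence
  seqs <- c("AKRK", "GASPKLMR", "SSTTK")
  for (s in seqs) {
    expect_true(s %in% digest(s, "trypsin", max_missed = nchar(s))$peptide)
  }
  expect_error(digest("ABZ", "trypsin"), "illegal residue")
})

test_that("0-missed-cleavage peptides tile the protein exactly", {
  proteins <- simulate_proteome(10, seed = 42)
  for (s in proteins$sequence) {
    for (protease in c("trypsin", "chymotrypsin")) {
      d <- digest(s, protease, max_missed = 0)
      expect_equal(paste(d$peptide, collapse = ""), s)
      expect_equal(d$start[-1], d$end[-nrow(d)] + 1)
    }
  }
})

test_that("theoretical ions follow declared conventions and mass arithmetic", {
  proton <- 1.00727646688
  water <- 18.0105646
  # y1 of "AG" is glycine residue + water + proton (closed-form)
  ions <- theoretical_ions("AG", series = c("b", "y"))
  expect_equal(ions$mz[ions$label == "y1"], 57.02146372 + water + proton,
               tolerance = 1e-6)
  # no b0; series restriction honoured
  expect_false("b0" %in% ions$label)
  only_y <- theoretical_ions("AG", series = "y")
  expect_true(all(only_y$series == "y"))
  # c = b + NH3, z-dot = y - NH3 + H
  full <- theoretical_ions("SAMPLER", series = c("b", "y", "c", "z"))
  b <- full$mz[full$series == "b"]; cc <- full$mz[full$series == "c"]
  y <- full$mz[full$series == "y"]; z <- full$mz[full$series == "z"]
  expect_equal(cc - b, rep(17.02654910, length(b)), tolerance = 1e-6)
  expect_equal(y - z, rep(17.02654910 - 1.0078250319, length(y)),
               tolerance = 1e-6)
  # modification delta shifts the precursor by exactly the residue mass
  m0 <- glycorank:::peptide_neutral_mass("SA")
  m1 <- glycorank:::peptide_neutral_mass(
    "SA", tibble::tibble(position = 1L, name = "HexNAc"))
  expect_equal(m1 - m0, 203.0793725, tolerance = 1e-6)
  # modifications on disallowed residues are rejected
  expect_error(
    theoretical_ions("AG", tibble::tibble(position = 1L, name = "HexNAc")),
    "invalid modification")
})

test_that("complementary b/y pairs reconstruct the precursor mass", {
  proton <- 1.00727646688
  peptides <- c("SAMPLER", "GASTKK", "TINYPEPTIDES")
  for (pep in peptides) {
    n <- nchar(pep)
    mods <- if (grepl("S", pep)) {
      tibble::tibble(position = as.integer(regexpr("S", pep)), name = "HexNAc")
    } else NULL
    ions <- theoretical_ions(pep, mods, series = c("b", "y"))
    M <- glycorank:::peptide_neutral_mass(pep, mods)
    b <- ions$mz[ions$series == "b"]
    y <- ions$mz[ions$series == "y"]
    for (i in seq_len(n - 1)) {
      expect_equal(b[i] + y[n - i], M + 2 * proton, tolerance = 1e-6)
    }
  }
})

test_that("match_spectrum self-matches, respects tolerance, and gates confidence", {
  proton <- 1.00727646688
  pep <- "SAMPTLER"
  mods <- tibble::tibble(position = 1L, name = "HexNAc")
  theo <- theoretical_ions(pep, mods)
  M <- glycorank:::peptide_neutral_mass(pep, mods)
  prec <- (M + 2 * proton) / 2
  peaks <- tibble::tibble(mz = theo$mz, intensity = 100)
  oxo <- tibble::tibble(mz = c(204.0867, 366.1396), intensity = 50)

  psm <- match_spectrum(make_spectrum(dplyr::bind_rows(peaks, oxo), prec),
                        pep, mods, protein_id = "P1")
  expect_equal(psm$matched_fraction, 1.0)
  expect_true(psm$oxonium_present)
  expect_equal(psm$confidence, "high")

  # shifting every peak by +1 Da kills all matches at 0.1 Da tolerance
  shifted <- tibble::tibble(mz = peaks$mz + 1.0, intensity = 100)
  psm2 <- match_spectrum(make_spectrum(shifted, prec), pep, mods)
  expect_equal(psm2$matched_fraction, 0)
  expect_equal(psm2$confidence, "medium_low")

  # glyco PSM without oxonium evidence is demoted despite a perfect match
  psm3 <- match_spectrum(make_spectrum(peaks, prec), pep, mods)
  expect_false(psm3$oxonium_present)
  expect_equal(psm3$confidence, "medium_low")

  # non-glyco PSM does not require oxonium evidence
  theo0 <- theoretical_ions(pep)
  M0 <- glycorank:::peptide_neutral_mass(pep)
  psm4 <- match_spectrum(
    make_spectrum(tibble::tibble(mz = theo0$mz, intensity = 1),
                  (M0 + 2 * proton) / 2), pep)
  expect_equal(psm4$confidence, "high")

  # precursor outside 5 ppm -> rejected; missing metadata -> error
  off <- make_spectrum(peaks, prec * (1 + 20e-6))
  expect_equal(nrow(match_spectrum(off, pep, mods)), 0)
  expect_error(match_spectrum(list(peaks = peaks), pep, mods),
               "missing precursor")
})

test_that("removing matched peaks never increases the matched fraction", {
  proton <- 1.00727646688
  pep <- "GLYCSITES"
  mods <- tibble::tibble(position = 5L, name = "HexNAc-Hex")
  theo <- theoretical_ions(pep, mods)
  M <- glycorank:::peptide_neutral_mass(pep, mods)
  prec <- (M + 2 * proton) / 2
  peaks <- tibble::tibble(mz = theo$mz, intensity = 10)
  withr::with_seed(99, {
    for (k in 1:10) {
      keep <- sample(nrow(peaks), sample(nrow(peaks), 1))
      sub <- peaks[keep, , drop = FALSE]
      mf_full <- match_spectrum(make_spectrum(peaks, prec), pep, mods)$matched_fraction
      mf_sub <- match_spectrum(make_spectrum(sub, prec), pep, mods)$matched_fraction
      expect_lte(mf_sub, mf_full)
    }
  })
})

test_that("glycosite localization recovers planted sites from c/z ions", {
  # two-site peptide; spectrum generated from the site-2 hypothesis
  pep <- "GASAGTAGKR"  # S at 3, T at 6
  mods2 <- tibble::tibble(position = 6L, name = "HexNAc")
  ladder <- theoretical_ions(pep, mods2, series = c("c", "z"))
  peaks <- tibble::tibble(mz = ladder$mz, intensity = 10)
  loc <- localize_glycosite(pep, "HexNAc", peaks, peptide_start = 101L)
  expect_equal(loc$localization, "unique")
  expect_equal(loc$sites, 106L)  # protein coordinates

  # exhaustive two-hypothesis oracle: count matched site-determining c ions by
  # hand: c3..c5 differ between the two placements
  lad3 <- theoretical_ions(pep, tibble::tibble(position = 3L, name = "HexNAc"),
                           series = c("c", "z"))
  determining <- abs(lad3$mz - ladder$mz) > 1e-9
  hand_counts <- c(
    site3 = sum(vapply(lad3$mz[determining],
                       function(m) any(abs(peaks$mz - m) <= 0.1), logical(1))),
    site6 = sum(vapply(ladder$mz[determining],
                       function(m) any(abs(peaks$mz - m) <= 0.1), logical(1)))
  )
  expect_true(hand_counts["site6"] > hand_counts["site3"])
  expect_equal(loc$evidence$matched_site_determining, unname(hand_counts))

  # only shared (non-site-determining) ions -> ambiguous, both sites retained
  shared <- tibble::tibble(mz = ladder$mz[!determining], intensity = 10)
  amb <- localize_glycosite(pep, "HexNAc", shared)
  expect_equal(amb$localization, "ambiguous")
  expect_equal(amb$sites, c(3L, 6L))

  # single-site peptide is unique by construction
  one <- localize_glycosite("AGSAGK", "HexNAc",
                            tibble::tibble(mz = numeric(0), intensity = numeric(0)))
  expect_equal(one$localization, "unique")
  expect_equal(one$sites, 3L)

  expect_error(localize_glycosite("AGAGK", "HexNAc", shared), "no candidate")
})

test_that("end-to-end annotation localizes all planted sites on clean spectra", {
  proteins <- simulate_proteome(12, seed = 8)
  sim <- simulate_glycopeptide_spectra(proteins, seed = 8, ion_dropout = 0,
                                       n_noise = 8)
  psms <- annotate_glycopeptides(sim$spectra, proteins)
  joined <- dplyr::inner_join(psms, sim$truth, by = "spectrum_id")
  expect_equal(nrow(joined), nrow(sim$truth))
  expect_true(all(joined$localization == "unique"))
  expect_true(all(purrr::map2_lgl(joined$candidate_sites, joined$site_protein,
                                  function(s, t) identical(s, t))))
  expect_true(all(joined$confidence == "high"))
})

test_that("suppressing oxonium ions demotes every glyco PSM", {
  proteins <- simulate_proteome(6, seed = 13)
  sim <- simulate_glycopeptide_spectra(proteins, seed = 13, omit_oxonium = TRUE,
                                       n_noise = 0)
  psms <- annotate_glycopeptides(sim$spectra, proteins)
  expect_gt(nrow(psms), 0)
  expect_true(all(psms$confidence == "medium_low"))
})
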