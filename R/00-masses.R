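# Monoisotopic elemental masses: the single source of truth for every mass in
# the package. No ion value is hard-coded outside test fixtures.
.elements <- c(
  C  = 12,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  Na = 22.98976928
)

.proton_mass <- 1.00727646688

#' Monoisotopic mass of a molecular formula
#'
#' Sums monoisotopic elemental masses for a formula given as element counts.
#' Used internally to derive every residue, fragment and adduct mass.
#'
#' @param C,H,N,O,S,Na Element counts (non-negative integers).
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(H = 2, O = 1)  # water
#' @export
formula_mass <- function(C = 0, H = 0, N = 0, O = 0, S = 0, Na = 0) {
  counts <- c(C = C, H = H, N = N, O = O, S = S, Na = Na)
  if (any(counts < 0)) stop("element counts must be non-negative", call. = FALSE)
  sum(counts * .elements[names(counts)])
}

.mass_water <- formula_mass(H = 2, O = 1)
.mass_nh3   <- formula_mass(N = 1, H = 3)
.mass_ch2   <- formula_mass(C = 1, H = 2)

# Dehydro (residue) masses of the four supported monosaccharides, native
# chemistry, from elemental formulas.
.glycan_residues <- c(
  hex    = formula_mass(C = 6,  H = 10, O = 5),
  hexnac = formula_mass(C = 8,  H = 13, N = 1, O = 5),
  dhex   = formula_mass(C = 6,  H = 10, O = 4),
  neuac  = formula_mass(C = 11, H = 17, N = 1, O = 8)
)

# Methylation sites gained per residue when the glycan is fully permethylated
# (linkage-independent bookkeeping; the core residue's extra site is folded
# into the aglycone closure constant).
.permethyl_sites <- c(hex = 3, hexnac = 3, dhex = 2, neuac = 5)

# Amino-acid residue (dehydro) masses from elemental formulas.
.aa_residues <- c(
  G = formula_mass(C = 2,  H = 3,  N = 1, O = 1),
  A = formula_mass(C = 3,  H = 5,  N = 1, O = 1),
  S = formula_mass(C = 3,  H = 5,  N = 1, O = 2),
  P = formula_mass(C = 5,  H = 7,  N = 1, O = 1),
  V = formula_mass(C = 5,  H = 9,  N = 1, O = 1),
  T = formula_mass(C = 4,  H = 7,  N = 1, O = 2),
  C = formula_mass(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = formula_mass(C = 6,  H = 11, N = 1, O = 1),
  I = formula_mass(C = 6,  H = 11, N = 1, O = 1),
  N = formula_mass(C = 4,  H = 6,  N = 2, O = 2),
  D = formula_mass(C = 4,  H = 5,  N = 1, O = 3),
  Q = formula_mass(C = 5,  H = 8,  N = 2, O = 2),
  K = formula_mass(C = 6,  H = 12, N = 2, O = 1),
  E = formula_mass(C = 5,  H = 7,  N = 1, O = 3),
  M = formula_mass(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = formula_mass(C = 6,  H = 7,  N = 3, O = 1),
  F = formula_mass(C = 9,  H = 9,  N = 1, O = 1),
  R = formula_mass(C = 6,  H = 12, N = 4, O = 1),
  Y = formula_mass(C = 9,  H = 9,  N = 1, O = 2),
  W = formula_mass(C = 11, H = 10, N = 2, O = 1)
)

# round-half-up, the rounding contract used against printed m/z values
# (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}
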