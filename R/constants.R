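# Embedded physical constants.  Monoisotopic masses and natural isotopic
# abundances are stated to six decimals so that all downstream masses are
# reproducible without an external table.

ELEMENTS <- c("C", "H", "N", "O", "S")

# Per-element isotope tables: mass (Da), natural abundance (fraction).
# Offsets (nominal mass above the lightest isotope) are derived, not stored.
ISOTOPE_TABLE <- list(
  C = data.frame(mass = c(12.000000, 13.003355), abundance = c(0.9893, 0.0107)),
  H = data.frame(mass = c(1.007825, 2.014102), abundance = c(0.999885, 0.000115)),
  N = data.frame(mass = c(14.003074, 15.000109), abundance = c(0.996360, 0.003640)),
  O = data.frame(mass = c(15.994915, 16.999132, 17.999160),
                 abundance = c(0.995700, 0.000380, 0.002050)),
  S = data.frame(mass = c(31.972071, 32.971459, 33.967867, 35.967081),
                 abundance = c(0.949900, 0.007500, 0.042500, 0.000100))
)

MONO_MASS <- vapply(ISOTOPE_TABLE, function(x) x$mass[1], numeric(1))

PROTON_MASS <- 1.007276
N15_N14_DELTA <- 15.000109 - 14.003074 # 0.997035 Da per nitrogen

# Residue (not free amino acid) elemental compositions, canonical 20.
# Columns follow ELEMENTS order: C, H, N, O, S.
RESIDUE_COMPOSITIONS <- rbind(
  G = c(2, 3, 1, 1, 0),
  A = c(3, 5, 1, 1, 0),
  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),
  V = c(5, 9, 1, 1, 0),
  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),
  L = c(6, 11, 1, 1, 0),
  I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),
  D = c(4, 5, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0),
  E = c(5, 7, 1, 3, 0),
  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),
  F = c(9, 9, 1, 1, 0),
  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),
  W = c(11, 10, 2, 1, 0)
)
colnames(RESIDUE_COMPOSITIONS) <- ELEMENTS

WATER_COMPOSITION <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

# Carbamidomethylation of cysteine (iodoacetamide alkylation), fixed mod.
CARBAMIDOMETHYL_COMPOSITION <- c(C = 2, H = 3, N = 1, O = 1, S = 0)

CANONICAL_RESIDUES <- rownames(RESIDUE_COMPOSITIONS)
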