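# Element data used across the package: standard atomic weights (IUPAC 2021,
# abridged), Bondi-style van der Waals radii, default valences for the
# implicit-hydrogen model, and the set of metals recognised for the
# metal-coordination channel.

.ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, Br = 79.904, I = 126.904
)

.VDW_RADII <- c(
  H = 1.10, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
  S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Zn = 1.39, Mg = 1.73,
  Fe = 1.63, Mn = 1.61, Ca = 2.31, Na = 2.27, K = 2.75
)

# Default valences for neutral atoms; the implicit hydrogen count of an atom
# is max(0, valence + charge_adjustment - sum of bond orders).
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

.METAL_ELEMENTS <- c("Zn", "Mg", "Mn", "Fe", "Co", "Ni", "Cu", "Ca", "Na", "K")

.norm_element <- function(e) {
  e <- sub("^\\s+|\\s+$", "", e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}

.atomic_weight <- function(elem) {
  w <- .ATOMIC_WEIGHTS[.norm_element(elem)]
  if (anyNA(w)) stop("unknown element(s): ",
                     paste(unique(elem[is.na(w)]), collapse = ", "))
  unname(w)
}

.vdw_radius <- function(elem) {
  r <- .VDW_RADII[.norm_element(elem)]
  r[is.na(r)] <- 1.70
  unname(r)
}
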