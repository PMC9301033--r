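# Gaussian shape and electrostatic similarity on posed molecules, combined
# on the usual 0-2 scale (shape Tanimoto + electrostatic Tanimoto). An
# openly declared substitute for commercial field-similarity packages:
# same scale and best-versus-references protocol, no claim of numerical
# agreement with any particular program. Poses are compared in the frame
# they arrive in; no overlay optimization is performed.

# Grant-Pickup style atom Gaussians: rho(r) = p * exp(-alpha r^2) with
# p = 2.7 and alpha = pi * (3p / (4 pi R^3))^(2/3), which reproduces the
# hard-sphere volume of radius R.
.GAUSS_P <- 2.7

.gauss_alpha <- function(radii)
  pi * (3 * .GAUSS_P / (4 * pi * radii^3))^(2 / 3)

# Pairwise first-order Gaussian overlap matrix between atom sets A and B.
.gauss_overlap <- function(xyzA, alphaA, xyzB, alphaB) {
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") - 2 * xyzA %*% t(xyzB)
  d2 <- pmax(d2, 0)
  asum <- outer(alphaA, alphaB, "+")
  aprod <- outer(alphaA, alphaB, "*")
  .GAUSS_P^2 * (pi / asum)^1.5 * exp(-aprod * d2 / asum)
}

#' Gaussian shape Tanimoto
#'
#' Volume-overlap Tanimoto `V_ab / (V_aa + V_bb - V_ab)` over heavy atoms,
#' each represented by a spherical Gaussian parameterized from its van der
#' Waals radius. Equals 1 for a molecule against itself and decays to 0
#' with increasing separation.
#'
#' @param a,b posed `mol_record`s.
#' @return shape similarity in [0, 1].
#' @export
shape_tanimoto <- function(a, b) {
  if (!has_conformer(a) || !has_conformer(b))
    stop("shape similarity requires conformers for both molecules")
  xa <- coords(a, heavy_only = TRUE); xb <- coords(b, heavy_only = TRUE)
  aa <- .gauss_alpha(.vdw_radius(a$atoms$elem[heavy_idx(a)]))
  ab <- .gauss_alpha(.vdw_radius(b$atoms$elem[heavy_idx(b)]))
  vab <- sum(.gauss_overlap(xa, aa, xb, ab))
  vaa <- sum(.gauss_overlap(xa, aa, xa, aa))
  vbb <- sum(.gauss_overlap(xb, ab, xb, ab))
  vab / (vaa + vbb - vab)
}

#' Gaussian electrostatic Tanimoto
#'
#' Charge-weighted Gaussian-overlap Tanimoto on signed partial charges
#' (all atoms, hydrogens included). Anti-correlated fields give negative
#' raw values, which are clamped to 0; two molecules with all-zero charges
#' score 0 by convention.
#'
#' @param a,b posed `mol_record`s with partial charges.
#' @return electrostatic similarity in [0, 1].
#' @export
electrostatic_tanimoto <- function(a, b) {
  if (!has_conformer(a) || !has_conformer(b))
    stop("electrostatic similarity requires conformers")
  qa <- a$atoms$partial; qb <- b$atoms$partial
  if (all(is.na(qa)) || all(is.na(qb)))
    stop("partial charges missing; assign them first (assign_gasteiger)")
  qa[is.na(qa)] <- 0; qb[is.na(qb)] <- 0
  if (all(qa == 0) && all(qb == 0)) return(0)
  xa <- coords(a); xb <- coords(b)
  aa <- .gauss_alpha(.vdw_radius(a$atoms$elem))
  ab <- .gauss_alpha(.vdw_radius(b$atoms$elem))
  eab <- sum(outer(qa, qb) * .gauss_overlap(xa, aa, xb, ab))
  eaa <- sum(outer(qa, qa) * .gauss_overlap(xa, aa, xa, aa))
  ebb <- sum(outer(qb, qb) * .gauss_overlap(xb, ab, xb, ab))
  denom <- eaa + ebb - eab
  if (denom <= 0) return(0)
  max(0, min(1, eab / denom))
}

#' Combined shape + electrostatic score against one reference
#' @param query,reference posed `mol_record`s with partial charges.
#' @return list with `shape`, `electrostatic` and `et_combo` (their sum,
#'   on the 0-2 scale).
#' @export
et_combo <- function(query, reference) {
  s <- shape_tanimoto(query, reference)
  e <- electrostatic_tanimoto(query, reference)
  list(shape = s, electrostatic = e, et_combo = s + e)
}

#' Best combined similarity over a reference set
#'
#' Scores the query against every reference and keeps the best (highest
#' combined) value, recording which reference achieved it.
#'
#' @param query a posed `mol_record` with partial charges.
#' @param references non-empty list of posed reference `mol_record`s.
#' @return a `combo_score`: `shape`, `electrostatic`, `et_combo`,
#'   `best_ref` (name) and `best_ref_index`.
#' @export
best_combo <- function(query, references) {
  if (!length(references)) stop("reference list is empty")
  best <- NULL
  for (i in seq_along(references)) {
    sc <- et_combo(query, references[[i]])
    if (is.null(best) || sc$et_combo > best$et_combo) {
      best <- sc
      best$best_ref <- references[[i]]$name
      best$best_ref_index <- i
    }
  }
  structure(best, class = "combo_score")
}
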