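# Shared in-code fixtures.

# idealized benzene conformer (kekulized, no hydrogens)
benzene_conf <- function(name = "benzene") {
  ang <- (0:5) * pi / 3
  mol_record(name,
             data.frame(elem = "C", charge = 0L, partial = 0,
                        x = 1.396 * cos(ang), y = 1.396 * sin(ang), z = 0),
             data.frame(a1 = 1:6, a2 = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)))
}

rotate_z <- function(mol, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  ifpgrow:::transform_mol(mol, R, c(0, 0, 0))
}

translate <- function(mol, v) ifpgrow:::transform_mol(mol, diag(3), v)

# a random (seeded) proper rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# toy complex shorthand
mk_complex <- function(channels, sigma = 0, seed = 1, n_spectators = 0) {
  make_toy_complex(fixture_spec(
    data.frame(residue = seq_along(channels) - 1L, channel = channels),
    sigma = sigma, seed = seed, n_spectators = n_spectators))
}

contacts_as_pairs <- function(ct) sort(paste(ct$residue, ct$channel))

truth_as_pairs <- function(cx) sort(paste(cx$truth$residue, cx$truth$channel))

# two-residue minimal PDB (ALA-GLY) and an ALA + water variant
minimal_pdb <- function(path, with_water = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.100   1.300   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.500   2.380   0.000  1.00  0.00           O")
  if (!with_water)
    lines <- c(lines,
    "ATOM      5  N   GLY A   2       3.450   1.300   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.200   2.500   0.000  1.00  0.00           C")
  else
    lines <- c(lines,
    "HETATM    5  O   HOH A 101      8.000   8.000   8.000  1.00  0.00           O")
  writeLines(c(lines, "END"), path)
  path
}

smiles_mol <- function(smi, name = smi) ifpgrow:::mol_from_smiles(smi, name)[[1]]
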