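# Synthetic toy complexes with planted interactions, and a seeded fragment
# library. The ligand is a substituted benzene built at idealized internal
# geometry; for every planted (residue, channel) pair a residue template is
# placed at ideal interaction geometry around the matching ligand group.
# Ground truth therefore equals the planted list exactly and the default
# contact parameters must recover it.

.CHANNEL_TEMPLATE <- c("0" = "LEU", "1" = "PHE", "2" = "PHE", "3" = "GLY",
                       "4" = "GLY", "5" = "LYS", "6" = "ASP", "7" = "ZN")

#' Specify a toy complex
#'
#' @param planted data.frame with 0-based `residue` and `channel` (0-7)
#'   columns: the interactions to plant. At most one channel per residue;
#'   at most two aromatic-stacking plantings (the second engages a phenyl
#'   substituent); at most six substituent-consuming plantings.
#' @param sigma Gaussian coordinate noise applied to receptor atoms,
#'   Angstrom.
#' @param seed seed for the noise.
#' @param n_spectators extra non-interacting residues appended far from
#'   the ligand.
#' @param templates optional residue-template names (one per planted row);
#'   a template unable to realize its channel is an error.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(planted, sigma = 0, seed = 1, n_spectators = 0,
                         templates = NULL) {
  stopifnot(is.data.frame(planted), nrow(planted) >= 1,
            all(c("residue", "channel") %in% names(planted)))
  if (any(planted$channel < 0 | planted$channel > 7))
    stop("channels must be in 0..7")
  if (any(planted$residue < 0)) stop("residue indices must be >= 0")
  if (anyDuplicated(planted$residue))
    stop("fixtures support one planted channel per residue")
  expected <- .CHANNEL_TEMPLATE[as.character(planted$channel)]
  if (!is.null(templates)) {
    if (length(templates) != nrow(planted))
      stop("templates must have one entry per planted interaction")
    bad <- templates != expected
    if (any(bad))
      stop("template '", templates[which(bad)[1]],
           "' cannot realize channel ", planted$channel[which(bad)[1]],
           " (needs ", expected[which(bad)[1]], ")")
  }
  if (sum(planted$channel %in% c(1, 2)) > 2)
    stop("at most two aromatic-stacking plantings are supported")
  if (sum(!planted$channel %in% c(1, 2)) +
      max(0, sum(planted$channel %in% c(1, 2)) - 1) > 6)
    stop("too many substituent-consuming plantings (max 6 ring positions)")
  structure(list(planted = planted[order(planted$residue), , drop = FALSE],
                 sigma = sigma, seed = seed, n_spectators = n_spectators),
            class = "fixture_spec")
}

# rotate u (unit, in xy-plane) by `deg` degrees toward +z
.tilt <- function(u, deg) {
  a <- deg * pi / 180
  c(cos(a) * u[1], cos(a) * u[2], sin(a))
}

#' Build a toy protein-ligand complex with planted interactions
#'
#' @param spec a [fixture_spec()].
#' @return a `toy_complex`: `receptor` (a `receptor_structure`), `ligand`
#'   (a posed `mol_record` with template partial charges), `truth` (the
#'   planted (residue, channel) table) and `spec`.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  planted <- spec$planted
  RING <- 1.396
  ring_u <- lapply(0:5, function(k) c(cos(k * pi / 3), sin(k * pi / 3), 0))

  atoms <- data.frame(elem = character(0), charge = integer(0),
                      partial = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0))
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  add_atom <- function(elem, p, charge = 0L, partial = 0) {
    atoms[nrow(atoms) + 1L, ] <<- list(elem, as.integer(charge), partial,
                                       p[1], p[2], p[3])
    nrow(atoms)
  }
  add_bond <- function(a, b, order = 1)
    bonds[nrow(bonds) + 1L, ] <<- list(a, b, order)

  # benzene core, kekulized
  core <- integer(6)
  for (k in 1:6) core[k] <- add_atom("C", RING * ring_u[[k]], partial = -0.06)
  for (k in 1:6) add_bond(core[k], core[k %% 6 + 1L],
                          if (k %% 2 == 1) 2 else 1)

  residues <- list()
  truth <- list()
  # position bookkeeping
  free_pos <- 1:6
  take_pos <- function() {
    k <- free_pos[1]; free_pos <<- free_pos[-1]; k
  }
  aromatic_count <- 0L
  phenyl_centroid <- NULL

  res_slot <- vector("list", max(planted$residue) + 1L)

  mk_res <- function(resname, names, elems, xyz) {
    list(resname = resname,
         atoms = data.frame(name = names, elem = elems,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  }

  for (row in seq_len(nrow(planted))) {
    ch <- planted$channel[row]
    ri <- planted$residue[row]
    if (ch == 0) {                      # hydrophobic: methyl + LEU carbons
      k <- take_pos(); u <- ring_u[[k]]
      cme <- add_atom("C", (RING + 1.50) * u, partial = -0.2)
      add_bond(core[k], cme)
      for (tl in c(35, 145, -110))
        add_bond(cme, add_atom("H", (RING + 1.50) * u + 1.09 * .tilt(u, tl),
                               partial = 0.065))
      base <- (RING + 1.50) * u
      res_slot[[ri + 1L]] <- mk_res("LEU", c("CG", "CB", "CA"),
        c("C", "C", "C"),
        rbind(base + 3.8 * u, base + (3.8 + 1.53) * u,
              base + 3.8 * u + 1.53 * .tilt(u, 55) + c(0, 0, 1.0)))
    } else if (ch %in% c(1, 2)) {       # aromatic stacking
      aromatic_count <- aromatic_count + 1L
      if (aromatic_count == 1L) {
        target_ctr <- c(0, 0, 0); target_normal <- c(0, 0, 1)
      } else {
        # second stacking engages a phenyl substituent
        k <- take_pos(); u <- ring_u[[k]]
        ipso <- add_atom("C", (RING + 1.48) * u, partial = -0.06)
        add_bond(core[k], ipso)
        ctr2 <- (RING + 1.48 + RING) * u
        ph <- integer(6)
        w <- c(-u[2], u[1], 0)          # in-plane perpendicular
        for (j in 1:6) {
          ang <- (j - 1) * pi / 3 + pi   # atom 1 coincides with ipso
          pos <- ctr2 + RING * (cos(ang) * u + sin(ang) * w)
          if (j == 1) ph[j] <- ipso
          else {
            ph[j] <- add_atom("C", pos, partial = -0.06)
            add_bond(ph[j], add_atom("H", ctr2 + (RING + 1.08) *
                                       (cos(ang) * u + sin(ang) * w),
                                     partial = 0.06))
          }
        }
        for (j in 1:6) add_bond(ph[j], ph[j %% 6 + 1L],
                                if (j %% 2 == 1) 2 else 1)
        target_ctr <- ctr2; target_normal <- c(0, 0, 1)
      }
      ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      if (ch == 1) {                    # face-to-face, parallel above
        ctr <- target_ctr + 4.3 * target_normal
        e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
      } else {                          # edge-to-face, perpendicular below
        ctr <- target_ctr - 4.7 * target_normal
        e1 <- c(1, 0, 0); e2 <- c(0, 0, 1)   # plane contains z: normal = y
      }
      xyz <- t(vapply(1:6, function(j) {
        ang <- (j - 1) * pi / 3
        ctr + RING * (cos(ang) * e1 + sin(ang) * e2)
      }, numeric(3)))
      far <- ctr + 3.2 * (if (ch == 1) target_normal else -target_normal)
      res_slot[[ri + 1L]] <- mk_res("PHE", c(ring_names, "CA"),
                                    c(rep("C", 6), "C"), rbind(xyz, far))
    } else if (ch == 3) {               # protein donor -> ligand aldehyde O
      k <- take_pos(); u <- ring_u[[k]]
      ca <- add_atom("C", (RING + 1.50) * u, partial = 0.25)
      add_bond(core[k], ca)
      o <- add_atom("O", (RING + 1.50 + 1.23) * u, partial = -0.40)
      add_bond(ca, o, 2)
      add_bond(ca, add_atom("H", (RING + 1.50) * u + 1.09 * .tilt(u, 125),
                            partial = 0.10))
      n_pos <- (RING + 1.50 + 1.23 + 2.9) * u
      res_slot[[ri + 1L]] <- mk_res("GLY", c("N", "H", "CA", "C", "O"),
        c("N", "H", "C", "C", "O"),
        rbind(n_pos, n_pos - 1.01 * u, n_pos + 1.45 * .tilt(u, 70),
              n_pos + 1.45 * .tilt(u, 70) + c(0, 0, 1.52),
              n_pos + 1.45 * .tilt(u, 70) + c(0, 0, 2.75)))
    } else if (ch == 4) {               # ligand amine -> protein acceptor
      k <- take_pos(); u <- ring_u[[k]]
      nn <- add_atom("N", (RING + 1.40) * u, partial = -0.6)
      add_bond(core[k], nn)
      add_bond(nn, add_atom("H", (RING + 1.40) * u + 1.01 * u,
                            partial = 0.30))
      add_bond(nn, add_atom("H", (RING + 1.40) * u + 1.01 * .tilt(u, 115),
                            partial = 0.30))
      o_pos <- (RING + 1.40 + 2.91) * u
      res_slot[[ri + 1L]] <- mk_res("GLY", c("O", "C", "CA", "N"),
        c("O", "C", "C", "N"),
        rbind(o_pos, o_pos + 1.23 * u,
              o_pos + 1.23 * u + 1.52 * .tilt(u, 65),
              o_pos + 1.23 * u + 1.52 * .tilt(u, 65) + c(0, 0, 1.45)))
    } else if (ch == 5) {               # ligand carboxylate -> LYS
      k <- take_pos(); u <- ring_u[[k]]
      w <- c(-u[2], u[1], 0)
      cc <- add_atom("C", (RING + 1.50) * u, partial = 0.40)
      add_bond(core[k], cc)
      o1 <- add_atom("O", (RING + 1.50) * u + 1.25 * (cos(pi / 6) * u +
                                                        sin(pi / 6) * w),
                     partial = -0.55)
      o2 <- add_atom("O", (RING + 1.50) * u + 1.25 * (cos(pi / 6) * u -
                                                        sin(pi / 6) * w),
                     charge = -1L, partial = -0.55)
      add_bond(cc, o1, 2); add_bond(cc, o2, 1)
      octr <- (RING + 1.50 + 1.25 * cos(pi / 6)) * u
      nz <- octr + 3.8 * u
      res_slot[[ri + 1L]] <- mk_res("LYS", c("NZ", "CE", "CD"),
        c("N", "C", "C"),
        rbind(nz, nz + 1.47 * u, nz + 1.47 * u + 1.53 * .tilt(u, 60)))
    } else if (ch == 6) {               # ligand ammonium -> ASP
      k <- take_pos(); u <- ring_u[[k]]
      w <- c(-u[2], u[1], 0)
      np <- add_atom("N", (RING + 1.47) * u, charge = 1L, partial = 0.10)
      add_bond(core[k], np)
      add_bond(np, add_atom("H", (RING + 1.47) * u + 1.01 * u,
                            partial = 0.30))
      add_bond(np, add_atom("H", (RING + 1.47) * u + 1.01 * .tilt(u, 110),
                            partial = 0.30))
      add_bond(np, add_atom("H", (RING + 1.47) * u + 1.01 * .tilt(u, -110),
                            partial = 0.30))
      cg <- (RING + 1.47 + 3.8 + 1.25 * cos(pi / 6)) * u
      od1 <- cg - 1.25 * (cos(pi / 6) * u + sin(pi / 6) * w)
      od2 <- cg - 1.25 * (cos(pi / 6) * u - sin(pi / 6) * w)
      res_slot[[ri + 1L]] <- mk_res("ASP", c("CG", "OD1", "OD2", "CB", "CA"),
        c("C", "O", "O", "C", "C"),
        rbind(cg, od1, od2, cg + 1.52 * u,
              cg + 1.52 * u + 1.53 * .tilt(u, 55)))
    } else if (ch == 7) {               # ligand methoxy O -> metal
      k <- take_pos(); u <- ring_u[[k]]
      o <- add_atom("O", (RING + 1.36) * u, partial = -0.35)
      add_bond(core[k], o)
      cm <- add_atom("C", (RING + 1.36) * u + 1.41 * .tilt(u, 60),
                     partial = 0.05)
      add_bond(o, cm)
      for (tl in c(20, 100, 170))
        add_bond(cm, add_atom("H", (RING + 1.36) * u + 1.41 * .tilt(u, 60) +
                                1.09 * .tilt(u, tl) + c(0, 0, 0.4),
                              partial = 0.06))
      res_slot[[ri + 1L]] <- mk_res("ZN", "ZN", "Zn",
        matrix((RING + 1.36 + 2.1) * u, nrow = 1))
    }
    truth[[length(truth) + 1L]] <- data.frame(residue = ri, channel = ch)
  }

  # ring hydrogens on unused positions
  for (k in free_pos)
    add_bond(core[k], add_atom("H", (RING + 1.08) * ring_u[[k]],
                               partial = 0.06))

  # spectators fill unplanted residue slots and append extras
  spectator <- function(i) {
    base <- c(28 + 6 * i, 30, 25)
    mk_res("GLY", c("N", "CA", "C", "O"), c("N", "C", "C", "O"),
           rbind(base, base + c(1.45, 0, 0), base + c(2.3, 1.2, 0),
                 base + c(2.3, 2.43, 0)))
  }
  for (i in seq_along(res_slot))
    if (is.null(res_slot[[i]])) res_slot[[i]] <- spectator(i)
  if (spec$n_spectators > 0)
    for (i in seq_len(spec$n_spectators))
      res_slot[[length(res_slot) + 1L]] <- spectator(length(res_slot) + i)

  residues <- lapply(seq_along(res_slot), function(i) {
    rs <- res_slot[[i]]
    list(chain = "A", resno = i, icode = "", resname = rs$resname,
         atoms = rs$atoms)
  })

  if (spec$sigma > 0) {
    with_seed(spec$seed, {
      for (i in seq_along(residues)) {
        na <- nrow(residues[[i]]$atoms)
        residues[[i]]$atoms$x <- residues[[i]]$atoms$x +
          stats::rnorm(na, 0, spec$sigma)
        residues[[i]]$atoms$y <- residues[[i]]$atoms$y +
          stats::rnorm(na, 0, spec$sigma)
        residues[[i]]$atoms$z <- residues[[i]]$atoms$z +
          stats::rnorm(na, 0, spec$sigma)
      }
    })
  }

  ligand <- mol_record("toy_ligand", atoms, bonds, has3d = TRUE)
  structure(list(receptor = new_receptor(residues,
                                         source = "synthetic_toy_complex"),
                 ligand = ligand,
                 truth = do.call(rbind, truth),
                 spec = spec),
            class = "toy_complex")
}

#' Write a toy complex to disk (PDB receptor + SDF ligand)
#' @param cx a `toy_complex`.
#' @param dir output directory.
#' @return paths of the written files.
#' @export
write_fixture <- function(cx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, "receptor.pdb")
  sdf <- file.path(dir, "ligand.sdf")
  write_receptor(cx$receptor, pdb)
  write_molecules(cx$ligand, sdf)
  c(receptor = pdb, ligand = sdf)
}

# Curated fragment pool: drug-like fragments spanning roughly 100-150 Da
# with a mix of donors, acceptors and aromatic systems.
.FRAGMENT_POOL <- c(
  "NC(=O)c1ccccc1",      "COc1ccccc1",          "OC(=O)c1ccccc1",
  "Cc1ccccc1N",          "c1ccc2[nH]ccc2c1",    "Cc1c[nH]c2ccccc12",
  "c1ccc2ncccc2c1",      "c1ccc2cnccc2c1",      "c1ccc2ccccc2c1",
  "c1ccc2[nH]cnc2c1",    "c1ccc2occc2c1",       "c1ccc2sccc2c1",
  "Oc1ccccc1O",          "Oc1cccc(O)c1",        "Oc1ccc(O)cc1",
  "O=Cc1ccccc1O",        "NC(=O)c1ccccn1",      "Nc1ccccc1C(O)=O",
  "COc1ccc(N)cc1",       "CC(=O)Nc1ccccc1",     "OC(=O)Cc1ccccc1",
  "O=C/C=C/c1ccccc1",    "O=c1ccc2ccccc2o1",    "O=c1ccoc2ccccc12",
  "c1ccc2c(c1)OCO2",     "O=Cc1ccc2OCOc2c1",    "COC(=O)c1ccccc1",
  "NCc1ccccc1",          "NCCc1ccccc1",         "NCCc1ccc(O)cc1",
  "NCCc1c[nH]cn1",       "OC(=O)Cc1c[nH]cn1",   "OC(=O)c1cccnc1",
  "NC(=O)c1ccncc1",      "Cc1ccnc(N)c1",        "Nc1nc2ccccc2[nH]1",
  "Cc1ccc2[nH]cnc2c1",   "c1ccc2[nH]ncc2c1",    "c1ccc2[nH]cnc2n1",
  "c1ncc2[nH]cnc2n1",    "Nc1ncnc2[nH]cnc12",   "O=c1cc[nH]c(=O)[nH]1",
  "Cc1c[nH]c(=O)[nH]c1=O", "Nc1cc[nH]c(=O)n1",  "CN1CC(=O)N=C1N",
  "NC(=O)Nc1ccccc1",     "Nc1ccc(F)cc1",        "Nc1ccc(Cl)cc1",
  "Oc1ccc(Cl)cc1",       "c1cc(Cl)cnc1",        "COc1ccc(O)cc1",
  "CC(=O)c1ccccn1",      "CC(=O)c1ccccc1",      "O=Cc1ccccc1",
  "N#Cc1ccccc1",         "c1ccc2nccnc2c1",      "c1ccc2nnccc2c1",
  "c1ccc2cnncc2c1",      "c1ccc2ncncc2c1",      "Oc1cccc2ncccc12",
  "Cc1ccc2ncccc2c1",     "C1Cc2ccccc2N1",       "C1Cc2ccccc2NC1",
  "c1ccc2[nH]nnc2c1",    "Nc1nccs1",            "Cc1csc(N)n1",
  "Cn1ccnc1S",           "OC(=O)c1cccs1",       "OC(=O)c1ccco1",
  "Cc1ccc(C=O)o1",       "OC(=O)c1cc[nH]c1")

#' Generate a seeded fragment library
#'
#' Draws `n` valid fragments from a curated pool, optionally gated to a
#' molecular-weight window (default 100-150 Da, the usual range for
#' de novo seed fragments). Deterministic under the seed; draws with
#' replacement when `n` exceeds the pool.
#'
#' @param n number of fragments (>= 1).
#' @param seed integer seed.
#' @param mw_range molecular-weight window, Da; `NULL` disables the gate.
#' @return list of `n` topology `mol_record`s with canonical SMILES.
#' @export
make_fragment_library <- function(n, seed = 1, mw_range = c(100, 150)) {
  stopifnot(n >= 1)
  pool <- mol_from_smiles(.FRAGMENT_POOL,
                          sprintf("pool%02d", seq_along(.FRAGMENT_POOL)))
  pool <- pool[!vapply(pool, is.null, logical(1))]
  if (!is.null(mw_range)) {
    mw <- vapply(pool, molecular_weight, numeric(1))
    pool <- pool[mw >= mw_range[1] & mw <= mw_range[2]]
  }
  idx <- with_seed(seed,
                   sample.int(length(pool), n, replace = n > length(pool)))
  out <- lapply(seq_len(n), function(j) {
    m <- pool[[idx[j]]]
    m$name <- sprintf("frag%03d", j)
    m
  })
  out
}
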