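# Geometric detection of the eight protein-ligand interaction classes that
# define fingerprint channels:
#   0 hydrophobic contact          1 aromatic face-to-face
#   2 aromatic edge-to-face        3 H-bond, protein donor
#   4 H-bond, protein acceptor     5 salt bridge, protein positive
#   6 salt bridge, protein negative 7 metal coordination

.CHANNEL_NAMES <- c("hydrophobic", "aromatic_f2f", "aromatic_e2f",
                    "hbond_protein_donor", "hbond_protein_acceptor",
                    "salt_protein_positive", "salt_protein_negative",
                    "metal")

#' Channel names of the interaction fingerprint
#' @return character vector of the eight channel names, in fixed order
#'   (channel index 0..7).
#' @export
channel_names <- function() .CHANNEL_NAMES

#' Geometric contact parameters
#'
#' Distance cutoffs in Angstroms, angles in degrees. Defaults follow
#' common interaction-fingerprint practice: hydrophobic aliphatic C/S pairs
#' within 4.0; aromatic ring centroids within 5.0 with interplane angle
#' <= 30 (face-to-face) or in [60, 90] (edge-to-face); hydrogen-bond
#' donor-acceptor heavy-atom distance <= 3.5 with a D-H...A angle >= 120
#' when the donor hydrogen is explicit (distance-only otherwise);
#' charged-group centroid distance <= 4.0 for salt bridges; metal to
#' coordinating atom <= 2.8.
#'
#' @param hydrophobic_dist,aromatic_dist,hbond_dist,salt_dist,metal_dist
#'   distance cutoffs (Angstrom).
#' @param f2f_angle_max,e2f_angle_min,e2f_angle_max,hbond_angle_min angle
#'   bounds (degrees).
#' @return a `contact_params` object.
#' @export
contact_params <- function(hydrophobic_dist = 4.0, aromatic_dist = 5.0,
                           f2f_angle_max = 30, e2f_angle_min = 60,
                           e2f_angle_max = 90, hbond_dist = 3.5,
                           hbond_angle_min = 120, salt_dist = 4.0,
                           metal_dist = 2.8) {
  p <- list(hydrophobic_dist = hydrophobic_dist, aromatic_dist = aromatic_dist,
            f2f_angle_max = f2f_angle_max, e2f_angle_min = e2f_angle_min,
            e2f_angle_max = e2f_angle_max, hbond_dist = hbond_dist,
            hbond_angle_min = hbond_angle_min, salt_dist = salt_dist,
            metal_dist = metal_dist)
  dists <- p[grep("_dist$", names(p))]
  if (any(unlist(dists) <= 0)) stop("all distance cutoffs must be > 0")
  angs <- unlist(p[grep("angle", names(p))])
  if (any(angs < 0 | angs > 180)) stop("angle bounds must be in [0, 180]")
  structure(p, class = "contact_params")
}

# ---- role perception ------------------------------------------------------

#' Perceive interaction roles
#'
#' Assigns, per monomer, the atom sets and geometric anchors used by
#' contact detection: hydrophobic atoms (aliphatic C/S with no polar heavy
#' neighbor), aromatic rings (atom set, centroid, unit normal), hydrogen
#' bond donors (N/O bearing hydrogen) and acceptors (N/O with a lone
#' pair), charged groups (formal charges plus carboxylate / ammonium /
#' guanidinium templates), and metal ions. Aromatic-ring carbons are not
#' counted as hydrophobic so that stacking and hydrophobic channels stay
#' disjoint.
#'
#' @param x a `mol_record` with a conformer, or a `receptor_structure`.
#' @param ... unused.
#' @return for a molecule, a `role_assignment` list; for a receptor, a
#'   list of `role_assignment`s, one per residue in file order.
#' @export
assign_roles <- function(x, ...) UseMethod("assign_roles")

#' @export
assign_roles.mol_record <- function(x, ...) {
  if (!has_conformer(x)) stop("molecule '", x$name, "' has no conformer")
  a <- x$atoms
  nb <- neighbors(x)
  imph <- implicit_h(x)
  arings <- aromatic_rings(x)
  aro_atoms <- unique(unlist(arings))
  polar <- c("N", "O", "P", "F", "Cl", "Br", "I")
  hyd <- which(vapply(seq_len(nrow(a)), function(i) {
    a$elem[i] %in% c("C", "S") && !(i %in% aro_atoms) && a$charge[i] == 0 &&
      !any(a$elem[nb[[i]]] %in% polar)
  }, logical(1)))
  rings <- lapply(arings, function(r) {
    cn <- ring_centroid_normal(x, r)
    list(atoms = r, centroid = cn$centroid, normal = cn$normal)
  })
  donors <- list(); acceptors <- integer(0)
  for (i in seq_len(nrow(a))) {
    if (!a$elem[i] %in% c("N", "O")) next
    hs <- nb[[i]][a$elem[nb[[i]]] == "H"]
    n_h <- length(hs) + imph[i]
    if (n_h >= 1 && a$charge[i] >= 0)
      donors[[length(donors) + 1L]] <- list(heavy = i, hs = hs)
    if (a$charge[i] <= 0) {
      if (a$elem[i] == "O") acceptors <- c(acceptors, i)
      else if (bond_order_sum(x)[i] <= 3 &&
               !(i %in% aro_atoms && n_h >= 1))
        acceptors <- c(acceptors, i)
    }
  }
  pos <- list(); neg <- list()
  done_neg <- integer(0)
  for (i in which(a$charge > 0)) {
    grp <- i
    pos[[length(pos) + 1L]] <-
      list(atoms = grp, centroid = colMeans(a[grp, c("x", "y", "z"),
                                              drop = FALSE]))
  }
  for (i in which(a$charge < 0)) {
    if (i %in% done_neg) next
    grp <- i
    if (a$elem[i] == "O") {
      # carboxylate template: sibling oxygen on the same carbon
      for (c_at in nb[[i]][a$elem[nb[[i]]] == "C"]) {
        sib <- setdiff(nb[[c_at]][a$elem[nb[[c_at]]] == "O"], i)
        if (length(sib)) grp <- c(i, sib[1])
      }
    }
    done_neg <- c(done_neg, grp)
    neg[[length(neg) + 1L]] <-
      list(atoms = grp, centroid = colMeans(a[grp, c("x", "y", "z"),
                                              drop = FALSE]))
  }
  metals <- which(a$elem %in% .METAL_ELEMENTS)
  structure(list(hydrophobic = hyd, rings = rings, donors = donors,
                 acceptors = acceptors, positive = pos, negative = neg,
                 metals = metals, source = "mol"),
            class = "role_assignment")
}

# Residue-template tables keyed on PDB residue and atom names.
.RES_AROMATIC <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")))

.RES_DONOR <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                   GLN = "NE2", TRP = "NE1", LYS = "NZ",
                   ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))

.RES_ACCEPTOR <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1",
                      GLN = "OE1", ASP = c("OD1", "OD2"),
                      GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"))

.RES_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.RES_POSITIVE <- list(LYS = "NZ", ARG = c("CZ", "NE", "NH1", "NH2"))
# Carbons excluded from the hydrophobic set because they belong to polar
# or charged functional groups.
.RES_POLAR_C <- list(ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD",
                     ARG = "CZ")

residue_roles <- function(rr) {
  at <- rr$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  nm <- at$name
  resn <- rr$resname
  pick <- function(names) which(nm %in% names)
  aro_names <- unlist(.RES_AROMATIC[[resn]])
  hyd <- which(at$elem %in% c("C", "S") &
                 !nm %in% c("N", "CA", "C", "O", "OXT") &
                 !nm %in% aro_names &
                 !nm %in% .RES_POLAR_C[[resn]])
  rings <- list()
  for (rn in .RES_AROMATIC[[resn]]) {
    idx <- pick(rn)
    if (length(idx) == length(rn)) {
      ctr <- colMeans(xyz[idx, , drop = FALSE])
      sv <- svd(sweep(xyz[idx, , drop = FALSE], 2, ctr))
      nrm <- sv$v[, 3]; nrm <- nrm / sqrt(sum(nrm^2))
      rings[[length(rings) + 1L]] <- list(atoms = idx, centroid = ctr,
                                          normal = nrm)
    }
  }
  don_heavy <- c(pick("N"), pick(.RES_DONOR[[resn]]))   # backbone N + side chain
  donors <- lapply(don_heavy, function(i) {
    # attached hydrogens, matched by distance (< 1.3 A)
    hs <- which(at$elem == "H")
    if (length(hs)) {
      d <- sqrt(colSums((t(xyz[hs, , drop = FALSE]) - xyz[i, ])^2))
      hs <- hs[d < 1.3]
    }
    list(heavy = i, hs = hs)
  })
  acceptors <- c(pick(c("O", "OXT")), pick(.RES_ACCEPTOR[[resn]]))
  neg <- list(); pos <- list()
  nn <- pick(.RES_NEGATIVE[[resn]])
  if (length(nn) >= 2)
    neg[[1]] <- list(atoms = nn, centroid = colMeans(xyz[nn, , drop = FALSE]))
  pp <- pick(.RES_POSITIVE[[resn]])
  if (length(pp))
    pos[[1]] <- list(atoms = pp, centroid = colMeans(xyz[pp, , drop = FALSE]))
  metals <- which(at$elem %in% .METAL_ELEMENTS & resn == toupper(at$elem))
  structure(list(hydrophobic = hyd, rings = rings, donors = donors,
                 acceptors = unique(acceptors), positive = pos,
                 negative = neg, metals = metals, source = "residue"),
            class = "role_assignment")
}

#' @export
assign_roles.receptor_structure <- function(x, ...)
  lapply(x$residues, residue_roles)

# ---- contact detection ----------------------------------------------------

.angle_deg <- function(v1, v2) {
  cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

# interplane angle folded to [0, 90]
.plane_angle <- function(n1, n2) {
  a <- .angle_deg(n1, n2)
  min(a, 180 - a)
}

# D-H...A angle at the hydrogen; 180 = collinear
.hba_angle <- function(d_xyz, h_xyz, a_xyz)
  .angle_deg(d_xyz - h_xyz, a_xyz - h_xyz)

#' Detect protein-ligand contacts
#'
#' Evaluates the eight channel predicates for every residue of the
#' receptor against a posed ligand sharing its coordinate frame. Multiple
#' atom pairs satisfying the same (residue, channel) predicate collapse to
#' a single contact (the closest pair is reported).
#'
#' @param receptor a `receptor_structure`.
#' @param pose a `mol_record` with a conformer.
#' @param params a [contact_params()] object.
#' @param receptor_roles optional precomputed [assign_roles()] output for
#'   the receptor (caching for repeated scoring).
#' @return a `contact_set` data.frame with columns `residue` (0-based),
#'   `channel` (0-7), `channel_name`, `res_atoms`, `lig_atoms`, `distance`
#'   and `angle`; attribute `r` holds the residue count.
#' @export
detect_contacts <- function(receptor, pose, params = contact_params(),
                            receptor_roles = NULL) {
  stopifnot(inherits(receptor, "receptor_structure"))
  lig <- assign_roles(pose)
  if (is.null(receptor_roles)) receptor_roles <- assign_roles(receptor)
  la <- pose$atoms
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  rows <- list()
  add <- function(res_i, ch, ratoms, latoms, dist, ang = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      residue = res_i - 1L, channel = ch,
      channel_name = .CHANNEL_NAMES[ch + 1L],
      res_atoms = paste(ratoms, collapse = "+"),
      lig_atoms = paste(latoms, collapse = "+"),
      distance = dist, angle = ang)
  }
  for (i in seq_along(receptor$residues)) {
    rr <- receptor$residues[[i]]
    rxyz <- as.matrix(rr$atoms[, c("x", "y", "z")])
    roles <- receptor_roles[[i]]
    # channel 0: hydrophobic
    if (length(roles$hydrophobic) && length(lig$hydrophobic)) {
      dm <- .pair_dists(rxyz[roles$hydrophobic, , drop = FALSE],
                        lxyz[lig$hydrophobic, , drop = FALSE])
      if (min(dm) <= params$hydrophobic_dist) {
        w <- which(dm == min(dm), arr.ind = TRUE)[1, ]
        add(i, 0L, rr$atoms$name[roles$hydrophobic[w[1]]],
            lig$hydrophobic[w[2]], min(dm))
      }
    }
    # channels 1/2: aromatic stacking
    if (length(roles$rings) && length(lig$rings)) {
      best <- list(f2f = NULL, e2f = NULL)
      for (pr in roles$rings) for (ql in lig$rings) {
        d <- sqrt(sum((pr$centroid - ql$centroid)^2))
        if (d > params$aromatic_dist) next
        ang <- .plane_angle(pr$normal, ql$normal)
        if (ang <= params$f2f_angle_max &&
            (is.null(best$f2f) || d < best$f2f$d))
          best$f2f <- list(d = d, ang = ang, pr = pr, ql = ql)
        if (ang >= params$e2f_angle_min && ang <= params$e2f_angle_max &&
            (is.null(best$e2f) || d < best$e2f$d))
          best$e2f <- list(d = d, ang = ang, pr = pr, ql = ql)
      }
      if (!is.null(best$f2f))
        add(i, 1L, rr$atoms$name[best$f2f$pr$atoms],
            best$f2f$ql$atoms, best$f2f$d, best$f2f$ang)
      if (!is.null(best$e2f))
        add(i, 2L, rr$atoms$name[best$e2f$pr$atoms],
            best$e2f$ql$atoms, best$e2f$d, best$e2f$ang)
    }
    # channel 3: protein donor -> ligand acceptor
    hb <- .best_hbond(roles$donors, rxyz, lig$acceptors, lxyz, params)
    if (!is.null(hb))
      add(i, 3L, rr$atoms$name[hb$d], hb$a, hb$dist, hb$ang)
    # channel 4: ligand donor -> protein acceptor
    hb <- .best_hbond(lig$donors, lxyz, roles$acceptors, rxyz, params)
    if (!is.null(hb))
      add(i, 4L, rr$atoms$name[hb$a], hb$d, hb$dist, hb$ang)
    # channels 5/6: salt bridges
    sb <- .best_pair_centroid(roles$positive, lig$negative)
    if (!is.null(sb) && sb$d <= params$salt_dist)
      add(i, 5L, rr$atoms$name[sb$ga], sb$gb, sb$d)
    sb <- .best_pair_centroid(roles$negative, lig$positive)
    if (!is.null(sb) && sb$d <= params$salt_dist)
      add(i, 6L, rr$atoms$name[sb$ga], sb$gb, sb$d)
    # channel 7: metal coordination (protein-side metal to ligand N/O)
    if (length(roles$metals) && length(lig$acceptors)) {
      dm <- .pair_dists(rxyz[roles$metals, , drop = FALSE],
                        lxyz[lig$acceptors, , drop = FALSE])
      if (min(dm) <= params$metal_dist) {
        w <- which(dm == min(dm), arr.ind = TRUE)[1, ]
        add(i, 7L, rr$atoms$name[roles$metals[w[1]]],
            lig$acceptors[w[2]], min(dm))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(residue = integer(0), channel = integer(0),
                  channel_name = character(0), res_atoms = character(0),
                  lig_atoms = character(0), distance = numeric(0),
                  angle = numeric(0))
  attr(out, "r") <- n_residues(receptor)
  class(out) <- c("contact_set", "data.frame")
  out
}

.pair_dists <- function(A, B) {
  # |A_i - B_j| distance matrix
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

# Best donor->acceptor hydrogen bond between donor list (with coordinates
# dxyz) and acceptor indices (coordinates axyz). Distance-only when no
# explicit hydrogen is attached to the donor heavy atom.
.best_hbond <- function(donors, dxyz, acceptors, axyz, params) {
  if (!length(donors) || !length(acceptors)) return(NULL)
  best <- NULL
  for (dn in donors) for (ai in acceptors) {
    d <- sqrt(sum((dxyz[dn$heavy, ] - axyz[ai, ])^2))
    if (d > params$hbond_dist || d < 0.5) next
    ang <- NA_real_
    if (length(dn$hs)) {
      ang <- max(vapply(dn$hs, function(h)
        .hba_angle(dxyz[dn$heavy, ], dxyz[h, ], axyz[ai, ]), numeric(1)))
      if (ang < params$hbond_angle_min) next
    }
    if (is.null(best) || d < best$dist)
      best <- list(d = dn$heavy, a = ai, dist = d, ang = ang)
  }
  best
}

.best_pair_centroid <- function(groups_a, groups_b) {
  if (!length(groups_a) || !length(groups_b)) return(NULL)
  best <- NULL
  for (ga in groups_a) for (gb in groups_b) {
    d <- sqrt(sum((ga$centroid - gb$centroid)^2))
    if (is.null(best) || d < best$d)
      best <- list(d = d, ga = ga$atoms, gb = gb$atoms)
  }
  best
}

#' Export contacts as CSV
#' @param contacts a `contact_set`.
#' @param path output path.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.csv(as.data.frame(contacts), path, row.names = FALSE)
  invisible(path)
}
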