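#' Molecule records
#'
#' A `mol_record` is the package's molecule container: a name, an atom table
#' (element, formal charge, optional partial charge, optional coordinates in
#' Angstroms), a bond table (1-based atom indices and integer bond orders,
#' with 4 denoting an aromatic bond as in SDF V2000), a canonical SMILES
#' string when known, and a free-form property list. Hydrogens may be
#' explicit (atom rows with element "H") or implicit; the implicit count is
#' derived from a standard valence model.
#'
#' @param name molecule name.
#' @param atoms data.frame with columns `elem`, `charge`, `partial`, `x`,
#'   `y`, `z`. `partial` and the coordinates may be `NA`.
#' @param bonds data.frame with columns `a1`, `a2`, `order`.
#' @param smiles canonical SMILES, or `NULL` if not yet computed.
#' @param props named list of free-form properties.
#' @param has3d logical; whether the coordinates form a real conformer.
#' @return an object of class `mol_record`.
#' @export
mol_record <- function(name, atoms, bonds, smiles = NULL, props = list(),
                       has3d = NA) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  need <- c("elem", "charge", "partial", "x", "y", "z")
  for (col in setdiff(need, names(atoms))) {
    atoms[[col]] <- if (col == "elem") stop("atoms need an 'elem' column")
                    else if (col == "charge") 0L else NA_real_
  }
  atoms$elem <- .norm_element(atoms$elem)
  atoms$charge <- as.integer(atoms$charge)
  if (nrow(bonds)) {
    if (any(bonds$a1 < 1 | bonds$a2 < 1 | bonds$a1 > nrow(atoms) |
            bonds$a2 > nrow(atoms)))
      stop("bond indices out of range in molecule '", name, "'")
    if (any(bonds$a1 == bonds$a2))
      stop("self-bond in molecule '", name, "'")
  }
  if (is.na(has3d))
    has3d <- !all(is.na(atoms$x)) && any(abs(c(atoms$x, atoms$y, atoms$z)) > 1e-8)
  m <- structure(list(name = as.character(name), atoms = atoms,
                      bonds = bonds[, c("a1", "a2", "order"), drop = FALSE],
                      smiles = smiles, props = props, has3d = isTRUE(has3d)),
                 class = "mol_record")
  .check_valences(m)
  m
}

#' @export
print.mol_record <- function(x, ...) {
  cat("<mol_record> ", x$name, ": ", sum(x$atoms$elem != "H"),
      " heavy atoms, ", nrow(x$bonds), " bonds, ",
      if (x$has3d) "3D" else "no conformer",
      if (!is.null(x$smiles)) paste0("\n  SMILES: ", x$smiles) else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname mol_record
#' @param mol a `mol_record`.
#' @export
has_conformer <- function(mol) isTRUE(mol$has3d)

heavy_idx <- function(mol) which(mol$atoms$elem != "H")

n_heavy <- function(mol) sum(mol$atoms$elem != "H")

coords <- function(mol, heavy_only = FALSE) {
  i <- if (heavy_only) heavy_idx(mol) else seq_len(nrow(mol$atoms))
  as.matrix(mol$atoms[i, c("x", "y", "z")])
}

# Sum of bond orders per atom; aromatic SDF order 4 counts 1.5.
bond_order_sum <- function(mol) {
  s <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    o <- ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$a1[k]] <- s[mol$bonds$a1[k]] + o[k]
      s[mol$bonds$a2[k]] <- s[mol$bonds$a2[k]] + o[k]
    }
  }
  s
}

# Implicit hydrogen counts under the default valence model with simple
# charge adjustments (N+ -> 4, O- -> 1, C+/- -> 3, S+ -> 3, ...).
implicit_h <- function(mol) {
  elem <- mol$atoms$elem
  chg <- mol$atoms$charge
  val <- .DEFAULT_VALENCE[elem]
  val[is.na(val)] <- 0            # metals etc.: no implicit hydrogens
  adj <- ifelse(elem %in% c("N", "O", "S", "P"), chg,
                ifelse(elem == "C", -abs(chg), 0))
  pmax(0, round(val + adj - bond_order_sum(mol)))
}

.check_valences <- function(mol) {
  elem <- mol$atoms$elem
  known <- elem %in% names(.DEFAULT_VALENCE)
  over <- bond_order_sum(mol) - (.DEFAULT_VALENCE[elem] +
    ifelse(elem %in% c("N", "O", "P"), mol$atoms$charge, 0))
  # S is allowed hypervalent states (sulfoxide/sulfone), P up to 5
  over[elem == "S"] <- bond_order_sum(mol)[elem == "S"] - 6
  over[elem == "P"] <- bond_order_sum(mol)[elem == "P"] - 5
  bad <- known & over > 1e-6
  if (any(bad))
    stop("valence violation in molecule '", mol$name, "' at atom(s) ",
         paste(which(bad), collapse = ", "))
  invisible(TRUE)
}

# Neighbor lists (indices into atom table).
neighbors <- function(mol) {
  nb <- vector("list", nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
  }
  nb
}

# Element-colored igraph of the molecule (heavy atoms by default). Vertex
# attribute 'aidx' maps back to atom-table indices.
mol_graph <- function(mol, heavy_only = TRUE) {
  keep <- if (heavy_only) heavy_idx(mol) else seq_len(nrow(mol$atoms))
  remap <- match(seq_len(nrow(mol$atoms)), keep)
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, ,
                 drop = FALSE]
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (nrow(b))
    g <- igraph::add_edges(g, rbind(remap[b$a1], remap[b$a2]))
  elems <- mol$atoms$elem[keep]
  igraph::V(g)$color <- as.integer(factor(elems, levels = names(.ATOMIC_WEIGHTS)))
  igraph::V(g)$aidx <- keep
  g
}

# Shortest-ring perception: for every edge that lies on a cycle, the
# smallest cycle through it (BFS in the graph minus the edge). Returns a
# list of atom-index vectors (deduplicated, size <= max_size).
find_rings <- function(mol, max_size = 8) {
  g <- mol_graph(mol, heavy_only = TRUE)
  aidx <- igraph::V(g)$aidx
  rings <- list()
  seen <- character(0)
  for (e in seq_len(igraph::ecount(g))) {
    ends <- igraph::ends(g, e)
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = ends[1],
                                                  to = ends[2]))$vpath[[1]]
    if (length(sp) >= 3 && length(sp) <= max_size) {
      ring <- sort(aidx[as.integer(sp)])
      key <- paste(ring, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- aidx[as.integer(sp)]
      }
    }
  }
  rings
}

# Aromaticity from the input's bond orders, no rearomatization: a 5- or
# 6-ring of C/N/O/S atoms is aromatic when every ring bond has order
# 1, 2 or 4 and each ring atom either carries a double/aromatic ring bond
# or is a heteroatom contributing a lone pair (pyrrole/furan-type).
aromatic_rings <- function(mol) {
  rings <- find_rings(mol, max_size = 6)
  out <- list()
  for (ring in rings) {
    n <- length(ring)
    if (n < 5 || n > 6) next
    if (!all(mol$atoms$elem[ring] %in% c("C", "N", "O", "S"))) next
    rb <- mol$bonds[mol$bonds$a1 %in% ring & mol$bonds$a2 %in% ring, ,
                    drop = FALSE]
    if (nrow(rb) != n) next
    if (!all(rb$order %in% c(1, 2, 4))) next
    ok <- vapply(ring, function(a) {
      mine <- rb[rb$a1 == a | rb$a2 == a, "order"]
      any(mine %in% c(2, 4)) || mol$atoms$elem[a] %in% c("N", "O", "S")
    }, logical(1))
    if (all(ok)) out[[length(out) + 1L]] <- ring
  }
  out
}

ring_centroid_normal <- function(mol, ring) {
  xyz <- as.matrix(mol$atoms[ring, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  nrm <- sv$v[, 3]
  nrm <- nrm / sqrt(sum(nrm^2))
  list(centroid = ctr, normal = nrm)
}

# Rigid transform applied to all atoms.
transform_mol <- function(mol, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}
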