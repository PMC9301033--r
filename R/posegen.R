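# Pose providers: a deterministic toy aligner for desk-scale testing and
# an adapter that parses pose files written by external docking engines.
# No docking engine is ever executed here.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Kabsch superposition: rotation R and translation t mapping moving onto
# fixed (both n x 3) in least-squares sense.
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = as.numeric(cf - R %*% cm))
}

# Maximum-common-substructure style atom mapping between two molecules'
# heavy-atom graphs (element-colored VF2). When one molecule's full heavy
# graph embeds in the other, the lexicographically smallest mapping is
# returned (tie-break by lowest atom rank); otherwise NULL (caller falls
# back to principal axes).
mcs_map <- function(molA, molB) {
  gA <- mol_graph(molA); gB <- mol_graph(molB)
  map_into <- function(pat, tgt) {
    maps <- tryCatch(
      igraph::subgraph_isomorphisms(pattern = pat, target = tgt,
                                    method = "vf2"),
      error = function(e) list())
    if (!length(maps)) return(NULL)
    mats <- vapply(maps, function(m) as.integer(m), integer(igraph::vcount(pat)))
    ord <- do.call(order, as.data.frame(t(mats)))
    mats[, ord[1]]
  }
  if (igraph::vcount(gA) <= igraph::vcount(gB)) {
    m <- map_into(gA, gB)
    if (is.null(m)) return(NULL)
    # atom i of A (heavy) corresponds to atom m[i] of B
    list(a = igraph::V(gA)$aidx, b = igraph::V(gB)$aidx[m])
  } else {
    m <- map_into(gB, gA)
    if (is.null(m)) return(NULL)
    list(a = igraph::V(gA)$aidx[m], b = igraph::V(gB)$aidx)
  }
}

# Principal-axes frame of a coordinate set, with deterministic sign
# convention (largest-magnitude component of each axis positive,
# right-handed).
principal_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:3) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  list(center = ctr, axes = V)
}

#' Generate aligned toy poses for a molecule
#'
#' A deterministic stand-in for a docking engine, used for desk-scale
#' testing: the molecule is given a 3D conformer if it lacks one, mapped
#' onto the reference ligand by common-substructure atom matching
#' (fallback: principal-axes alignment), and rigidly superposed. Pose 1 is
#' the unjittered alignment; poses 2..n add seeded Gaussian coordinate
#' noise.
#'
#' @param molecule a `mol_record` (conformer optional).
#' @param reference the reference ligand `mol_record` with a conformer.
#' @param n number of poses (>= 1).
#' @param seed integer seed for the jitter noise.
#' @param jitter_sigma per-coordinate Gaussian noise, Angstrom.
#' @return list of `n` posed `mol_record`s.
#' @export
toy_align_poses <- function(molecule, reference, n = 1, seed = 1,
                            jitter_sigma = 0.25) {
  stopifnot(n >= 1)
  if (!has_conformer(reference)) stop("reference has no conformer")
  mol <- embed_conformer(molecule)
  map <- mcs_map(mol, reference)
  if (!is.null(map) && length(map$a) >= 3) {
    fit <- kabsch(as.matrix(mol$atoms[map$a, c("x", "y", "z")]),
                  as.matrix(reference$atoms[map$b, c("x", "y", "z")]))
    base <- transform_mol(mol, fit$R, fit$t)
  } else if (!is.null(map)) {
    # fewer than 3 mapped atoms: translate mapped centroid onto reference
    t <- colMeans(as.matrix(reference$atoms[map$b, c("x", "y", "z"),
                                            drop = FALSE])) -
      colMeans(as.matrix(mol$atoms[map$a, c("x", "y", "z"), drop = FALSE]))
    base <- transform_mol(mol, diag(3), t)
  } else {
    fm <- principal_frame(coords(mol, heavy_only = TRUE))
    fr <- principal_frame(coords(reference, heavy_only = TRUE))
    R <- fr$axes %*% t(fm$axes)
    t <- fr$center - as.numeric(R %*% fm$center)
    base <- transform_mol(mol, R, t)
  }
  poses <- vector("list", n)
  poses[[1]] <- base
  if (n > 1) {
    na <- nrow(base$atoms)
    with_seed(seed, {
      for (k in 2:n) {
        p <- base
        p$atoms$x <- p$atoms$x + stats::rnorm(na, 0, jitter_sigma)
        p$atoms$y <- p$atoms$y + stats::rnorm(na, 0, jitter_sigma)
        p$atoms$z <- p$atoms$z + stats::rnorm(na, 0, jitter_sigma)
        poses[[k]] <- p
      }
    })
  }
  for (k in seq_len(n)) poses[[k]]$props$pose_rank <- k
  poses
}

#' Toy pose provider
#'
#' Wraps [toy_align_poses()] in the pose-provider contract consumed by
#' [run_evolution()]: a list with `propose(molecule, receptor, seed)`,
#' `max_poses` and `requires_reference`.
#'
#' @param reference reference ligand `mol_record` with conformer.
#' @param n poses per molecule.
#' @param jitter_sigma jitter, Angstrom.
#' @return a `pose_provider`.
#' @export
toy_pose_provider <- function(reference, n = 10, jitter_sigma = 0.25) {
  structure(list(
    propose = function(molecule, receptor = NULL, seed = 1)
      toy_align_poses(molecule, reference, n = n, seed = seed,
                      jitter_sigma = jitter_sigma),
    max_poses = n,
    requires_reference = TRUE),
    class = "pose_provider")
}

#' Parse poses written by an external docking engine
#'
#' Reads an engine's SDF pose file into posed `mol_record`s, optionally
#' checking each pose against an expected topology.
#'
#' @param path SDF file of poses.
#' @param topology optional `mol_record`; every pose must have the same
#'   atom count.
#' @return list of posed `mol_record`s.
#' @export
read_pose_file <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("pose file not found: ", path)
  poses <- tryCatch(parse_sdf_file(path), error = function(e)
    stop("unparseable pose file '", path, "': ", conditionMessage(e)))
  if (!length(poses)) stop("pose file '", path, "' contains no poses")
  if (!is.null(topology)) {
    for (k in seq_along(poses)) {
      if (nrow(poses[[k]]$atoms) != nrow(topology$atoms))
        stop("pose block ", k, " in '", path, "' has ",
             nrow(poses[[k]]$atoms), " atoms; topology has ",
             nrow(topology$atoms))
    }
  }
  poses
}
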