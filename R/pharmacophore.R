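# Shared-feature pharmacophore model: ligand-side interaction anchors
# (donor / acceptor atoms, aromatic ring centroids) are collected from a
# set of pre-aligned complexes, clustered across complexes, and clusters
# occurring in at least a retention fraction of the complexes become model
# features. Matching is a binary AND gate over all features.

#' Build a shared-feature pharmacophore model
#'
#' For every complex, ligand-side feature points are extracted from its
#' detected contacts: acceptor heavy atoms engaged in protein-donor
#' hydrogen bonds, donor heavy atoms engaged in protein-acceptor hydrogen
#' bonds, and aromatic ring centroids (with normals) engaged in either
#' stacking channel. Points of the same kind are clustered across
#' complexes by single linkage with a merge radius; clusters whose
#' occupancy (fraction of distinct source complexes) reaches the retention
#' threshold become features centered on the cluster centroid.
#'
#' @param complexes list of `list(receptor =, ligand =)` pairs, pre-aligned
#'   to a common frame.
#' @param retention feature-retention fraction in (0, 1]; default 0.5.
#' @param merge_radius single-linkage merge radius, Angstrom.
#' @param feature_radius radius assigned to retained features, Angstrom.
#' @param params [contact_params()] used for contact detection.
#' @return a `pharmacophore_model`: feature data.frame (`kind`, `x`, `y`,
#'   `z`, `radius`, `nx`, `ny`, `nz`, `occupancy`), retention threshold and
#'   source-complex count.
#' @export
build_pharmacophore <- function(complexes, retention = 0.5,
                                merge_radius = 1.5, feature_radius = 1.0,
                                params = contact_params()) {
  if (!length(complexes)) stop("complex list is empty")
  stopifnot(retention > 0, retention <= 1)
  pts <- list()
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    contacts <- detect_contacts(cx$receptor, cx$ligand, params)
    roles <- assign_roles(cx$ligand)
    xyz <- as.matrix(cx$ligand$atoms[, c("x", "y", "z")])
    addpt <- function(kind, p, nrm = c(NA, NA, NA))
      pts[[length(pts) + 1L]] <<- data.frame(
        complex = ci, kind = kind, x = p[1], y = p[2], z = p[3],
        nx = nrm[1], ny = nrm[2], nz = nrm[3])
    for (k in seq_len(nrow(contacts))) {
      ch <- contacts$channel[k]
      lig_atoms <- as.integer(strsplit(contacts$lig_atoms[k], "\\+")[[1]])
      if (ch == 3L) addpt("acceptor", colMeans(xyz[lig_atoms, , drop = FALSE]))
      if (ch == 4L) addpt("donor", colMeans(xyz[lig_atoms, , drop = FALSE]))
      if (ch %in% c(1L, 2L)) {
        # recover the engaged ring from the role assignment
        for (rg in roles$rings) {
          if (all(rg$atoms %in% lig_atoms) && all(lig_atoms %in% rg$atoms))
            addpt("aromatic", rg$centroid, rg$normal)
        }
      }
    }
  }
  if (!length(pts))
    return(structure(list(features = .empty_features(),
                          retention = retention,
                          n_complexes = length(complexes)),
                     class = "pharmacophore_model"))
  pts <- do.call(rbind, pts)
  pts <- unique(pts)
  feats <- list()
  for (kind in unique(pts$kind)) {
    sub <- pts[pts$kind == kind, , drop = FALSE]
    cl <- if (nrow(sub) == 1) 1L
    else stats::cutree(stats::hclust(stats::dist(sub[, c("x", "y", "z")]),
                                     method = "single"), h = merge_radius)
    for (g in unique(cl)) {
      mem <- sub[cl == g, , drop = FALSE]
      occ <- length(unique(mem$complex)) / length(complexes)
      if (occ < retention) next
      nrm <- c(NA_real_, NA_real_, NA_real_)
      if (kind == "aromatic") {
        nm <- as.matrix(mem[, c("nx", "ny", "nz")])
        # align signs to the first member before averaging
        ref <- nm[1, ]
        for (j in seq_len(nrow(nm)))
          if (sum(nm[j, ] * ref) < 0) nm[j, ] <- -nm[j, ]
        nrm <- colMeans(nm)
        nrm <- nrm / sqrt(sum(nrm^2))
      }
      feats[[length(feats) + 1L]] <- data.frame(
        kind = kind, x = mean(mem$x), y = mean(mem$y), z = mean(mem$z),
        radius = feature_radius, nx = nrm[1], ny = nrm[2], nz = nrm[3],
        occupancy = occ)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else .empty_features()
  # deterministic feature order independent of input complex order
  if (nrow(features))
    features <- features[order(features$kind, features$x, features$y,
                               features$z), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(features = features, retention = retention,
                 n_complexes = length(complexes)),
            class = "pharmacophore_model")
}

.empty_features <- function()
  data.frame(kind = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), radius = numeric(0), nx = numeric(0),
             ny = numeric(0), nz = numeric(0), occupancy = numeric(0))

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("<pharmacophore_model> ", nrow(x$features), " feature(s), retention ",
      x$retention, ", built from ", x$n_complexes, " complex(es)\n", sep = "")
  if (nrow(x$features)) print(x$features)
  invisible(x)
}

#' Match a pose against a pharmacophore model
#'
#' All-features-required (AND) semantics: the pose passes only if every
#' feature is satisfied by a ligand point of the matching role within
#' `radius + tolerance` of the feature center; aromatic features
#' additionally require the ring normal within `angle_tolerance` degrees
#' of the feature normal (plane angle, folded to [0, 90]).
#'
#' @param model a `pharmacophore_model`.
#' @param pose a `mol_record` with a conformer, in the model's frame.
#' @param tolerance extra matching distance, Angstrom.
#' @param angle_tolerance aromatic normal tolerance, degrees.
#' @return list with `match` (logical) and `report` (per-feature
#'   data.frame with `kind`, `satisfied`, `best_dist`, `best_angle`).
#' @export
pharm_matches <- function(model, pose, tolerance = 1.0,
                          angle_tolerance = 30) {
  if (!has_conformer(pose)) stop("pose has no conformer")
  roles <- assign_roles(pose)
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")])
  f <- model$features
  sat <- logical(nrow(f)); bd <- rep(NA_real_, nrow(f))
  ba <- rep(NA_real_, nrow(f))
  for (k in seq_len(nrow(f))) {
    ctr <- c(f$x[k], f$y[k], f$z[k])
    lim <- f$radius[k] + tolerance
    if (f$kind[k] == "donor") {
      cand <- vapply(roles$donors, `[[`, numeric(1), "heavy")
      if (length(cand)) {
        d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - ctr)^2))
        bd[k] <- min(d); sat[k] <- bd[k] <= lim
      }
    } else if (f$kind[k] == "acceptor") {
      cand <- roles$acceptors
      if (length(cand)) {
        d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - ctr)^2))
        bd[k] <- min(d); sat[k] <- bd[k] <= lim
      }
    } else {
      for (rg in roles$rings) {
        d <- sqrt(sum((rg$centroid - ctr)^2))
        ang <- .plane_angle(rg$normal, c(f$nx[k], f$ny[k], f$nz[k]))
        if (is.na(bd[k]) || d < bd[k]) { bd[k] <- d; ba[k] <- ang }
        if (d <= lim && ang <= angle_tolerance) sat[k] <- TRUE
      }
    }
  }
  list(match = all(sat),
       report = data.frame(feature = seq_len(nrow(f)), kind = f$kind,
                           satisfied = sat, best_dist = bd,
                           best_angle = ba))
}

#' Serialize / restore a pharmacophore model as JSON
#' @param model a `pharmacophore_model`.
#' @param path file path.
#' @export
write_pharmacophore <- function(model, path) {
  jsonlite::write_json(list(features = model$features,
                            retention = model$retention,
                            n_complexes = model$n_complexes),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(path) {
  raw <- jsonlite::fromJSON(path)
  feats <- as.data.frame(raw$features)
  if (!nrow(feats)) feats <- .empty_features()
  structure(list(features = feats, retention = raw$retention,
                 n_complexes = raw$n_complexes),
            class = "pharmacophore_model")
}
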