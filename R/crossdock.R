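# Cross-docking benchmark analytics: symmetry-corrected heavy-atom RMSD,
# best-pose RMSD matrices, per-receptor success rates at an RMSD
# threshold, and consensus averaging across docking protocols.

# All automorphisms of a molecule's element-colored heavy-atom graph,
# generated by closing the BLISS generator set; capped, with fallback to
# the identity permutation.
graph_automorphisms <- function(mol, max_autos = 10000) {
  g <- mol_graph(mol, heavy_only = TRUE)
  n <- igraph::vcount(g)
  gens <- tryCatch(
    igraph::automorphism_group(g, colors = igraph::V(g)$color),
    error = function(e) list())
  gens <- lapply(gens, as.integer)
  perms <- list(seq_len(n))
  seen <- new.env(hash = TRUE)
  assign(paste(seq_len(n), collapse = ","), TRUE, envir = seen)
  queue <- perms
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (gn in gens) {
      nxt <- cur[gn]
      key <- paste(nxt, collapse = ",")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        if (length(perms) >= max_autos) {
          warning("automorphism count exceeds ", max_autos,
                  "; falling back to identity mapping")
          return(list(seq_len(n)))
        }
        perms[[length(perms) + 1L]] <- nxt
        queue[[length(queue) + 1L]] <- nxt
      }
    }
  }
  perms
}

#' Heavy-atom RMSD between two poses of the same molecule
#'
#' Computed in the docked frame (no re-superposition). With
#' `symmetry = TRUE` the RMSD is minimized over the automorphisms of the
#' element-colored heavy-atom graph, so symmetry-equivalent poses (e.g. a
#' flipped benzene ring) score 0. The automorphism count is capped; beyond
#' the cap the identity mapping is used with a warning.
#'
#' @param a,b posed `mol_record`s with identical heavy-atom topology and
#'   atom ordering.
#' @param symmetry apply graph-automorphism symmetry correction.
#' @param max_autos automorphism cap.
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(a, b, symmetry = TRUE, max_autos = 10000) {
  ia <- heavy_idx(a); ib <- heavy_idx(b)
  if (length(ia) != length(ib) ||
      !identical(a$atoms$elem[ia], b$atoms$elem[ib]))
    stop("topology mismatch between poses '", a$name, "' and '", b$name, "'")
  A <- coords(a, heavy_only = TRUE); B <- coords(b, heavy_only = TRUE)
  rms <- function(perm) sqrt(mean(rowSums((A[perm, , drop = FALSE] - B)^2)))
  if (!symmetry) return(rms(seq_len(nrow(A))))
  perms <- graph_automorphisms(a, max_autos = max_autos)
  min(vapply(perms, rms, numeric(1)))
}

#' Best-pose RMSD of a docking run
#'
#' Minimum heavy-atom RMSD over a list of poses against the crystal
#' reference pose. An empty or fully invalid pose list yields `NA` (a
#' missing matrix cell) with a warning.
#'
#' @param poses list of posed `mol_record`s.
#' @param reference the crystal reference pose.
#' @param ... passed to [heavy_atom_rmsd()].
#' @return RMSD in Angstrom, or `NA`.
#' @export
best_pose_rmsd <- function(poses, reference, ...) {
  if (!length(poses)) {
    warning("no poses; recording missing cell")
    return(NA_real_)
  }
  vals <- vapply(poses, function(p)
    tryCatch(heavy_atom_rmsd(p, reference, ...),
             error = function(e) NA_real_), numeric(1))
  if (all(is.na(vals))) {
    warning("all poses invalid; recording missing cell")
    return(NA_real_)
  }
  min(vals, na.rm = TRUE)
}

#' Build a best-pose RMSD matrix
#'
#' @param ligand_ids,receptor_ids,protocols axis labels.
#' @param values optional numeric vector or array filling the
#'   (ligand, receptor, protocol) cells in ligand-major order; defaults to
#'   all-missing.
#' @return an `rmsd_matrix`: a 3-d array `[ligand, receptor, protocol]`
#'   with `NA` marking missing cells.
#' @export
rmsd_matrix <- function(ligand_ids, receptor_ids, protocols,
                        values = NA_real_) {
  arr <- array(NA_real_,
               dim = c(length(ligand_ids), length(receptor_ids),
                       length(protocols)),
               dimnames = list(ligand = ligand_ids, receptor = receptor_ids,
                               protocol = protocols))
  if (!all(is.na(values))) arr[] <- values
  if (any(arr < 0, na.rm = TRUE)) stop("RMSD values must be >= 0")
  structure(arr, class = c("rmsd_matrix", "array"))
}

#' Enumerate cross-docking jobs
#'
#' Full Cartesian product of ligands x receptors x protocols in stable
#' ligand-major order (ligand varies slowest).
#'
#' @param ligand_ids,receptor_ids,protocols non-empty id vectors.
#' @return data.frame with columns `ligand`, `receptor`, `protocol`.
#' @export
job_matrix <- function(ligand_ids, receptor_ids, protocols) {
  if (!length(ligand_ids) || !length(receptor_ids) || !length(protocols))
    stop("all job axes must be non-empty")
  df <- expand.grid(protocol = protocols, receptor = receptor_ids,
                    ligand = ligand_ids, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  df[, c("ligand", "receptor", "protocol")]
}

#' Success rates of a cross-docking benchmark
#'
#' A docking run is successful when its best-pose RMSD is strictly below
#' the threshold. Reports, per receptor and protocol, the success fraction
#' over non-missing cells, the consensus (arithmetic mean across
#' protocols) per receptor, and a receptor ranking by consensus with ties
#' broken by receptor id. Receptors with no usable cell in some protocol
#' are excluded from the ranking with a warning.
#'
#' @param matrix an `rmsd_matrix` (or plain 3-d array, ligand x receptor x
#'   protocol).
#' @param threshold success threshold, Angstrom (default 2.0; strict `<`).
#' @return a `success_report`: `threshold`, `per_receptor` (receptor,
#'   protocol, fraction), `consensus` (receptor, consensus, rank).
#' @export
success_rate <- function(matrix, threshold = 2.0) {
  if (length(dim(matrix)) != 3) stop("expected a 3-d RMSD array")
  dn <- dimnames(matrix)
  receptors <- dn[[2]]; protocols <- dn[[3]]
  per <- expand.grid(receptor = receptors, protocol = protocols,
                     stringsAsFactors = FALSE)
  per$fraction <- NA_real_
  for (k in seq_len(nrow(per))) {
    cells <- matrix[, per$receptor[k], per$protocol[k]]
    if (any(!is.na(cells)))
      per$fraction[k] <- mean(cells < threshold, na.rm = TRUE)
  }
  cons <- data.frame(receptor = receptors, consensus = NA_real_)
  for (i in seq_along(receptors)) {
    fr <- per$fraction[per$receptor == receptors[i]]
    if (!anyNA(fr)) cons$consensus[i] <- mean(fr)
  }
  if (anyNA(cons$consensus)) {
    warning("receptor(s) with undefined success fraction excluded from ",
            "ranking: ",
            paste(cons$receptor[is.na(cons$consensus)], collapse = ", "))
  }
  ranked <- cons[!is.na(cons$consensus), , drop = FALSE]
  ranked <- ranked[order(-ranked$consensus, ranked$receptor), , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  cons$rank <- ranked$rank[match(cons$receptor, ranked$receptor)]
  structure(list(threshold = threshold, per_receptor = per,
                 consensus = cons),
            class = "success_report")
}

#' @export
print.success_report <- function(x, ...) {
  cat("<success_report> threshold", x$threshold, "A\n")
  print(x$consensus)
  invisible(x)
}

#' Write one protocol slice of an RMSD matrix as CSV
#'
#' The CSV round-trips losslessly via [read_rmsd_csv()]. Values are
#' written in full precision; the 4-Angstrom display clipping used in
#' heatmap exports never touches stored data.
#'
#' @param matrix an `rmsd_matrix`.
#' @param protocol protocol label to export.
#' @param path output path.
#' @export
write_rmsd_csv <- function(matrix, protocol, path) {
  sl <- matrix[, , protocol, drop = FALSE]
  df <- as.data.frame(sl[, , 1, drop = TRUE])
  utils::write.csv(cbind(ligand = dimnames(matrix)[[1]], df), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_rmsd_csv
#' @export
read_rmsd_csv <- function(path, protocol = "p") {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rmsd_matrix(df$ligand, colnames(vals), protocol,
              values = as.numeric(vals))
}
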