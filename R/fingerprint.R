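# Interaction fingerprints and the IFP_CS scoring function.
#
# A pose's contacts are encoded into a bit vector of length 8*r (r =
# number of protein residues); bit 8*i + c is set when residue i (0-based)
# makes a channel-c contact. The IFP_CS score of a query pose against a
# reference complex is minus the cosine similarity of the two vectors:
# -1 means the query reproduces the reference binding mode exactly, 0
# means no overlap at all. More negative is better, matching selection
# machinery that minimizes docking scores.

#' Encode contacts into an interaction fingerprint
#'
#' @param contacts a `contact_set` from [detect_contacts()], or a
#'   data.frame with 0-based `residue` and `channel` columns.
#' @param r residue count; defaults to the `r` attribute of `contacts`.
#' @return an `interaction_fingerprint`: bit vector of length `8 * r` with
#'   bit `8*i + c` (0-based) set iff a (residue i, channel c) contact
#'   exists.
#' @export
encode_fingerprint <- function(contacts, r = attr(contacts, "r")) {
  if (is.null(r)) stop("residue count r must be supplied")
  r <- as.integer(r)
  if (nrow(contacts) && any(contacts$residue >= r | contacts$residue < 0))
    stop("contact residue index out of range (r = ", r, ")")
  bits <- integer(8L * r)
  if (nrow(contacts))
    bits[unique(8L * contacts$residue + contacts$channel) + 1L] <- 1L
  structure(list(bits = bits, r = r, channels = .CHANNEL_NAMES),
            class = "interaction_fingerprint")
}

#' Build a fingerprint from sparse (0-based) bit indices
#' @param idx 0-based set-bit positions.
#' @param r residue count.
#' @return an `interaction_fingerprint`.
#' @export
fp_from_sparse <- function(idx, r) {
  r <- as.integer(r)
  if (length(idx) && (any(idx < 0) || any(idx >= 8L * r)))
    stop("sparse index out of range")
  bits <- integer(8L * r)
  bits[idx + 1L] <- 1L
  structure(list(bits = bits, r = r, channels = .CHANNEL_NAMES),
            class = "interaction_fingerprint")
}

#' @rdname fp_from_sparse
#' @param fp an `interaction_fingerprint`.
#' @return `fp_sparse`: 0-based positions of set bits.
#' @export
fp_sparse <- function(fp) which(fp$bits == 1L) - 1L

#' @export
print.interaction_fingerprint <- function(x, ...) {
  cat("<interaction_fingerprint> r =", x$r, "(length", length(x$bits),
      "), popcount", sum(x$bits), "\n")
  invisible(x)
}

.fp_bits <- function(x) {
  if (inherits(x, "interaction_fingerprint")) x$bits else as.numeric(x)
}

#' Cosine similarity of two fingerprints
#'
#' `dot(A, B) / (|A| * |B|)`, defined as 0 when either vector is all-zero
#' so that poses without any detected interaction remain rankable.
#'
#' @param A,B `interaction_fingerprint`s (or plain 0/1 vectors) of equal
#'   length.
#' @return similarity in [0, 1].
#' @export
cosine_similarity <- function(A, B) {
  a <- .fp_bits(A); b <- .fp_bits(B)
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' IFP_CS score
#'
#' Minus the cosine similarity between a reference complex fingerprint and
#' a query pose fingerprint. Ranges from -1 (query reproduces the
#' reference binding mode) to 0 (no correspondence).
#'
#' @param reference,query `interaction_fingerprint`s of equal length.
#' @return score in [-1, 0]; more negative is better.
#' @export
ifp_cs <- function(reference, query) -cosine_similarity(reference, query)

#' Reference fingerprint of a complex
#'
#' Convenience wrapper computing the fingerprint of a reference
#' crystallographic pose in its receptor; computed once per run and cached
#' by callers.
#'
#' @param receptor a `receptor_structure`.
#' @param ref_pose the reference ligand `mol_record` (posed).
#' @param params [contact_params()].
#' @return an `interaction_fingerprint` with provenance attributes.
#' @export
reference_fingerprint <- function(receptor, ref_pose,
                                  params = contact_params()) {
  fp <- encode_fingerprint(detect_contacts(receptor, ref_pose, params))
  attr(fp, "receptor") <- receptor$source
  attr(fp, "pose") <- ref_pose$name
  fp
}

#' Score a pose with IFP_CS
#'
#' Encodes the pose's contacts in the given receptor and returns the
#' IFP_CS score against the reference fingerprint. The receptor must have
#' the same residue count as the reference fingerprint.
#'
#' @param receptor a `receptor_structure`.
#' @param pose a posed `mol_record`.
#' @param reference_fp the reference `interaction_fingerprint`.
#' @param params [contact_params()].
#' @param receptor_roles optional cached [assign_roles()] output.
#' @return score in [-1, 0].
#' @export
score_pose <- function(receptor, pose, reference_fp,
                       params = contact_params(), receptor_roles = NULL) {
  if (n_residues(receptor) != reference_fp$r)
    stop("receptor residue count (", n_residues(receptor),
         ") does not match reference fingerprint (r = ", reference_fp$r, ")")
  fp <- encode_fingerprint(detect_contacts(receptor, pose, params,
                                           receptor_roles = receptor_roles))
  ifp_cs(reference_fp, fp)
}

#' Build an IFP_CS pose scorer
#'
#' Returns a closure `function(pose) -> score` binding a receptor, its
#' precomputed roles, a reference fingerprint and contact parameters; this
#' is the scorer consumed by [run_evolution()].
#'
#' @inheritParams score_pose
#' @return a scoring function.
#' @export
make_ifpcs_scorer <- function(receptor, reference_fp,
                              params = contact_params()) {
  roles <- assign_roles(receptor)
  function(pose) score_pose(receptor, pose, reference_fp, params,
                            receptor_roles = roles)
}
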