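# OpenBabel-backed conversions (via ChemmineOB) and SDF parsing (via
# ChemmineR). Everything that needs chemistry perception beyond this
# package's scope -- SMILES parsing, canonicalization, 3D embedding,
# Gasteiger charges -- goes through here.

ob_convert <- function(text, from, to, opts = NULL) {
  if (is.null(opts)) ChemmineOB::convertFormat(from, to, source = text)
  else ChemmineOB::convertFormat(from, to, source = text, options = opts)
}

# Parse SDF text into mol_records. Uses ChemmineR for the molblock tables
# and recovers formal charges from the raw "M  CHG" lines, which ChemmineR
# does not expose.
parse_sdf_text <- function(text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sub("\n$", "", text), tf)
  parse_sdf_file(tf)
}

parse_sdf_file <- function(path) {
  if (!any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    out <- list()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  str <- ChemmineR::read.SDFstr(path)
  sdfset <- suppressWarnings(as(str, "SDFset"))
  valid <- ChemmineR::validSDF(sdfset)
  raw <- as(str, "list")
  out <- list()
  n_bad <- 0L
  for (i in seq_along(sdfset)) {
    lines <- raw[[i]]
    if (valid[i]) {
      sdf <- sdfset[[i]]
      ab <- ChemmineR::atomblock(sdf)
      bb <- ChemmineR::bondblock(sdf)
      hdr <- ChemmineR::header(sdf)
      elem <- sub("_[0-9]+$", "", rownames(ab))
      atoms <- data.frame(elem = elem, charge = 0L, partial = NA_real_,
                          x = ab[, 1], y = ab[, 2], z = ab[, 3])
    } else {
      # ChemmineR rejects bond-less molecules; fall back to the raw
      # fixed-width molblock for that degenerate case
      blk <- tryCatch(.parse_molblock_raw(lines), error = function(e) NULL)
      if (is.null(blk)) { n_bad <- n_bad + 1L; next }
      atoms <- blk$atoms; bb <- blk$bonds; hdr <- lines[1:2]
    }
    chg_lines <- grep("^M  CHG", lines, value = TRUE)
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(substring(cl, 7)), "\\s+")[[1]])
      npairs <- f[1]
      for (k in seq_len(npairs))
        atoms$charge[f[2 * k]] <- f[2 * k + 1]
    }
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0)
      data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
    else data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
    name <- trimws(hdr[1])
    if (!nzchar(name)) name <- paste0("mol", i)
    has3d <- grepl("3D", hdr[2], fixed = TRUE) ||
      any(abs(atoms$z) > 1e-8)
    props <- if (valid[i]) as.list(ChemmineR::datablock(sdfset[[i]]))
             else list()
    out[[length(out) + 1L]] <- mol_record(name, atoms, bonds,
                                          props = props, has3d = has3d)
  }
  attr(out, "n_skipped") <- n_bad
  out
}

# Fixed-width V2000 fallback for blocks ChemmineR will not parse
# (bond-less molecules).
.parse_molblock_raw <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stop("bad counts line")
  al <- lines[5:(4 + na)]
  atoms <- data.frame(
    elem = trimws(substr(al, 32, 34)), charge = 0L, partial = NA_real_,
    x = as.numeric(substr(al, 1, 10)), y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30)))
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)),
          as.integer(substr(bl, 7, 9)))
  } else matrix(integer(0), 0, 3)
  list(atoms = atoms, bonds = bonds)
}

# Write a mol_record as an SDF V2000 block (fixed-width formatting).
mol_to_sdf_text <- function(mol) {
  a <- mol$atoms
  x <- ifelse(is.na(a$x), 0, a$x); y <- ifelse(is.na(a$y), 0, a$y)
  z <- ifelse(is.na(a$z), 0, a$z)
  lines <- c(mol$name,
             sprintf(" ifpgrow %s", if (mol$has3d) "3D" else "2D"),
             "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(mol$bonds)))
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            x, y, z, a$elem))
  if (nrow(mol$bonds))
    lines <- c(lines, sprintf("%3d%3d%3d  0", mol$bonds$a1, mol$bonds$a2,
                              as.integer(mol$bonds$order)))
  chg <- which(a$charge != 0)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, a$charge[grp]),
                                      collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  for (p in names(mol$props)) {
    val <- mol$props[[p]]
    if (is.atomic(val) && length(val) >= 1)
      lines <- c(lines, sprintf(">  <%s>", p), as.character(val)[1], "")
  }
  paste0(paste(lines, collapse = "\n"), "\n$$$$\n")
}

mols_to_sdf_text <- function(mols) paste0(vapply(mols, mol_to_sdf_text,
                                                 character(1)), collapse = "")

# Canonical SMILES of one mol_record (round-trips through OpenBabel).
ob_canonical_smiles <- function(mol) {
  out <- ob_convert(mol_to_sdf_text(mol), "SDF", "CAN")
  smi <- strsplit(trimws(out), "[\t ]")[[1]][1]
  if (is.na(smi) || !nzchar(smi))
    stop("canonicalization failed for molecule '", mol$name, "'")
  smi
}

canonicalize_smiles <- function(smiles) {
  out <- ob_convert(paste0(smiles, " x\n", collapse = ""), "SMI", "CAN")
  got <- strsplit(trimws(out), "\n")[[1]]
  if (length(got) != length(smiles))
    stop("canonicalization failed (", length(got), " of ", length(smiles),
         " SMILES survived)")
  vapply(strsplit(got, "[\t ]"), `[`, character(1), 1)
}

# SMILES -> topology-only mol_record (implicit hydrogens, no conformer).
# Invalid SMILES return NULL (OpenBabel aborts a batch at the first bad
# entry, so entries are converted one at a time).
mol_from_smiles <- function(smiles, name = smiles) {
  out <- lapply(seq_along(smiles), function(i) {
    sdf <- tryCatch(ob_convert(paste0(smiles[i], " ", name[i], "\n"),
                               "SMI", "SDF"),
                    error = function(e) "")
    if (!nzchar(trimws(sdf))) return(NULL)
    mols <- parse_sdf_text(sdf)
    if (!length(mols)) return(NULL)
    m <- mols[[1]]
    m$has3d <- FALSE
    m$atoms$x <- NA_real_; m$atoms$y <- NA_real_; m$atoms$z <- NA_real_
    m$smiles <- tryCatch(canonicalize_smiles(smiles[i]),
                         error = function(e) NULL)
    m
  })
  out
}

# Conformer cache: canonical SMILES -> embedded mol_record. Embedding is
# deterministic (fixed per-molecule seed), so caching only saves time.
.embed_cache <- new.env(parent = emptyenv())

# Batch 3D embedding of SMILES (explicit hydrogens) through the bundled
# RDKit ETKDG helper; deterministic per molecule regardless of batch
# composition. All SMILES must be valid (use on internally generated
# ones).
embed_smiles <- function(smiles, names = smiles, strict = TRUE) {
  out <- vector("list", length(smiles))
  hit <- vapply(smiles, function(s)
    exists(s, envir = .embed_cache, inherits = FALSE), logical(1))
  for (i in which(hit)) {
    out[[i]] <- get(smiles[i], envir = .embed_cache)
    out[[i]]$name <- names[i]
  }
  miss <- which(!hit)
  if (length(miss)) {
    script <- system.file("python", "embed_smiles.py", package = "ifpgrow")
    if (!nzchar(script)) stop("bundled embedding helper not found")
    sdf <- suppressWarnings(system2("python", shQuote(script),
                                    input = paste(smiles[miss], names[miss]),
                                    stdout = TRUE, stderr = FALSE))
    mols <- parse_sdf_text(paste0(paste(sdf, collapse = "\n"), "\n"))
    got <- match(names[miss], vapply(mols, `[[`, character(1), "name"))
    if (strict && anyNA(got))
      stop("3D embedding failed for ", sum(is.na(got)),
           " molecule(s) of ", length(miss))
    for (j in seq_along(miss)) {
      if (is.na(got[j])) next
      m <- mols[[got[j]]]
      m$smiles <- NULL
      assign(smiles[miss[j]], m, envir = .embed_cache)
      m$name <- names[miss[j]]
      out[[miss[j]]] <- m
    }
  }
  out
}

#' Embed a 3D conformer for a molecule
#'
#' Generates a single 3D conformer (with explicit hydrogens) for a
#' topology-only molecule using OpenBabel's deterministic builder plus
#' force-field cleanup. Molecules that already have a conformer are
#' returned unchanged.
#'
#' @param mol a `mol_record`.
#' @return a `mol_record` with a conformer.
#' @export
embed_conformer <- function(mol) {
  if (has_conformer(mol)) return(mol)
  smi <- if (!is.null(mol$smiles)) mol$smiles else ob_canonical_smiles(mol)
  m <- tryCatch(embed_smiles(smi, mol$name)[[1]], error = function(e)
    stop("3D embedding failed for molecule '", mol$name, "'"))
  m$smiles <- smi
  m$props <- mol$props
  m
}

#' Assign Gasteiger partial charges
#'
#' Fills the `partial` column of a molecule's atom table with
#' Gasteiger-Marsili partial charges computed by OpenBabel. Existing
#' partial charges are left untouched unless `force = TRUE`.
#'
#' @param mol a `mol_record` with a conformer.
#' @param force recompute even if partial charges are present.
#' @return the molecule with partial charges.
#' @export
assign_gasteiger <- function(mol, force = FALSE) {
  if (!force && !all(is.na(mol$atoms$partial))) return(mol)
  m2 <- ob_convert(mol_to_sdf_text(mol), "SDF", "MOL2",
                   opts = data.frame(names = "partialcharge",
                                     args = "gasteiger"))
  lines <- strsplit(m2, "\n")[[1]]
  a0 <- grep("^@<TRIPOS>ATOM", lines)[1]
  a1 <- grep("^@<TRIPOS>", lines)
  a1 <- min(a1[a1 > a0])
  atom_lines <- lines[(a0 + 1):(a1 - 1)]
  fields <- strsplit(trimws(atom_lines), "\\s+")
  q <- vapply(fields, function(f) as.numeric(f[9]), numeric(1))
  if (length(q) != nrow(mol$atoms))
    stop("charge assignment atom-count mismatch for '", mol$name, "'")
  mol$atoms$partial <- q
  mol
}
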