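# Standard-format I/O: PDB receptors (via bio3d), SMILES/SDF molecule
# files, and JSON run configuration.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE")

new_receptor <- function(residues, het = NULL, source = NA_character_) {
  if (!length(residues)) stop("receptor has zero polymer residues")
  keys <- vapply(residues, function(rr)
    paste(rr$chain, rr$resno, rr$icode, sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate residue key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  structure(list(residues = residues, het = het, source = source),
            class = "receptor_structure")
}

#' Number of polymer residues of a receptor
#' @param receptor a `receptor_structure`.
#' @return integer residue count `r`; residue index `i` in contacts and
#'   fingerprints runs 0..r-1 in file order.
#' @export
n_residues <- function(receptor) length(receptor$residues)

#' @export
print.receptor_structure <- function(x, ...) {
  cat("<receptor_structure> ", n_residues(x), " residues",
      if (!is.null(x$het) && nrow(x$het))
        paste0(", ", nrow(x$het), " non-polymer atoms") else "",
      "\n", sep = "")
  invisible(x)
}

#' Read a receptor structure from a PDB file
#'
#' Polymer residues are defined by ATOM records (plus HETATM records whose
#' residue name is a standard amino acid); all other HETATM entries
#' (waters, ligands, ions) are kept separately in the `het` table. Residue
#' order equals file order and defines the 0-based residue index used by
#' interaction fingerprints. Duplicate (chain, residue number, insertion
#' code) keys are an error because they would corrupt fingerprint indexing.
#'
#' @param path path to a PDB file.
#' @return a `receptor_structure` with fields `residues` (ordered list;
#'   each residue has `chain`, `resno`, `icode`, `resname` and an atom
#'   table), `het` (non-polymer atoms) and `source`.
#' @export
read_receptor <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e)
                    stop("PDB parse error in '", path, "': ",
                         conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || !nrow(at)) stop("no ATOM/HETATM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$elesy[is.na(at$elesy) | !nzchar(at$elesy)] <-
    substr(trimws(at$elety[is.na(at$elesy) | !nzchar(at$elesy)]), 1, 1)
  polymer <- at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% .AA3)
  pol <- at[polymer, , drop = FALSE]
  if (!nrow(pol)) stop("zero polymer residues in ", path,
                       " (first record at line ~", 1, ")")
  key <- paste(pol$chain, pol$resno, pol$insert, sep = "|")
  runs <- rle(key)
  if (anyDuplicated(runs$values))
    stop("duplicate residue key(s) in ", path, ": ",
         paste(unique(runs$values[duplicated(runs$values)]), collapse = ", "))
  idx_end <- cumsum(runs$lengths)
  idx_start <- c(1L, head(idx_end, -1L) + 1L)
  residues <- lapply(seq_along(runs$values), function(i) {
    rows <- pol[idx_start[i]:idx_end[i], , drop = FALSE]
    list(chain = rows$chain[1], resno = rows$resno[1],
         icode = rows$insert[1], resname = rows$resid[1],
         atoms = data.frame(name = trimws(rows$elety),
                            elem = .norm_element(trimws(rows$elesy)),
                            x = rows$x, y = rows$y, z = rows$z))
  })
  hetrows <- at[!polymer, , drop = FALSE]
  het <- if (nrow(hetrows))
    data.frame(resname = hetrows$resid, chain = hetrows$chain,
               resno = hetrows$resno, name = trimws(hetrows$elety),
               elem = .norm_element(trimws(hetrows$elesy)),
               x = hetrows$x, y = hetrows$y, z = hetrows$z)
  else NULL
  new_receptor(residues, het, source = path)
}

#' Write a receptor structure as a PDB file
#' @param receptor a `receptor_structure`.
#' @param path output path.
#' @export
write_receptor <- function(receptor, path) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(receptor$residues)) {
    rr <- receptor$residues[[i]]
    for (j in seq_len(nrow(rr$atoms))) {
      serial <- serial + 1L
      a <- rr$atoms[j, ]
      nm <- a$name
      nm <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, nm, rr$resname, rr$chain, rr$resno, rr$icode,
        a$x, a$y, a$z, toupper(a$elem)))
    }
  }
  if (!is.null(receptor$het) && nrow(receptor$het)) {
    for (j in seq_len(nrow(receptor$het))) {
      serial <- serial + 1L
      a <- receptor$het[j, ]
      nm <- if (nchar(a$name) < 4) sprintf(" %-3s", a$name) else a$name
      lines <- c(lines, sprintf(
        "HETATM%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, nm, a$resname, a$chain, a$resno, a$x, a$y, a$z,
        toupper(a$elem)))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read molecules from a SMILES or SDF file
#'
#' `.smi`/`.txt` files hold one SMILES per line with an optional
#' whitespace-separated name; `.sdf`/`.sd`/`.mol` files are parsed as SDF
#' V2000 with conformers and formal charges preserved. Invalid entries are
#' skipped with a warning; the number skipped is available as
#' `attr(x, "n_skipped")`.
#'
#' @param path input file.
#' @return list of `mol_record`s.
#' @export
read_molecules <- function(path) {
  if (!file.exists(path)) stop("cannot read molecule file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "txt", "ism")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    smi <- vapply(parts, `[`, character(1), 1)
    nms <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1) paste(parts[[i]][-1], collapse = " ")
      else paste0("mol", i), character(1))
    mols <- mol_from_smiles(smi, nms)
    bad <- vapply(mols, is.null, logical(1))
    out <- mols[!bad]
    n_skipped <- sum(bad)
  } else if (ext %in% c("sdf", "sd", "mol")) {
    out <- parse_sdf_file(path)
    n_skipped <- attr(out, "n_skipped")
  } else {
    stop("unrecognized molecule file extension: .", ext)
  }
  if (n_skipped > 0)
    warning(n_skipped, " invalid entr", if (n_skipped == 1) "y" else "ies",
            " skipped in ", path)
  if (!length(out)) stop("no usable molecules in ", path)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write molecules to an SDF file
#' @param mols list of `mol_record`s.
#' @param path output path.
#' @export
write_molecules <- function(mols, path) {
  if (inherits(mols, "mol_record")) mols <- list(mols)
  cat(mols_to_sdf_text(mols), file = path)
  invisible(path)
}

#' Default run configuration
#'
#' @return a `run_config` list with all tunables at their defaults:
#'   de novo mode, 10 generations, 10 mutants + 10 crossovers per
#'   generation, 2 elites, 5 survivors, 10 poses per molecule, IFP_CS
#'   scorer, default contact parameters and pharmacophore tolerances.
#' @export
default_config <- function() {
  structure(list(
    mode = "de_novo",
    generations = 10L,
    n_mutants = 10L,
    n_crossovers = 10L,
    n_elites = 2L,
    n_survivors = 5L,
    n_poses = 10L,
    max_heavy = 40L,
    seed = 1L,
    scorer = "ifp_cs",
    reference_receptor = NA_character_,
    reference_ligand = NA_character_,
    contact_params = as.list(unclass(contact_params())),
    pharm_tolerance = 1.0,
    pharm_angle_tolerance = 30,
    jitter_sigma = 0.25,
    combo_thresholds = c(0.50, 0.75, 1.00)
  ), class = "run_config")
}

#' Load and validate a JSON run configuration
#'
#' Absent optional keys take their defaults from [default_config()];
#' unknown keys produce a warning; invalid values produce an error naming
#' the key.
#'
#' @param path path to a JSON object.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object")
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  for (k in intersect(names(raw), names(cfg))) {
    if (k == "contact_params") {
      cp <- as.list(unclass(contact_params()))
      for (kk in intersect(names(raw[[k]]), names(cp))) cp[[kk]] <- raw[[k]][[kk]]
      cfg[[k]] <- cp
    } else cfg[[k]] <- raw[[k]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk_count <- function(key, min = 0) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min ||
        v != round(v))
      stop("invalid value for config key '", key, "': must be an integer >= ",
           min)
    cfg[[key]] <<- as.integer(v)
  }
  if (!cfg$mode %in% c("de_novo", "lead_opt"))
    stop("invalid value for config key 'mode': must be de_novo or lead_opt")
  chk_count("generations", 0)
  chk_count("n_mutants", 0); chk_count("n_crossovers", 0)
  chk_count("n_elites", 0); chk_count("n_survivors", 1)
  chk_count("n_poses", 1); chk_count("max_heavy", 1); chk_count("seed", 0)
  if (!cfg$scorer %in% c("ifp_cs", "external"))
    stop("invalid value for config key 'scorer'")
  do.call(contact_params, cfg$contact_params)  # validates
  structure(cfg, class = "run_config")
}

# Provenance header written with every run artifact.
provenance <- function(cfg) {
  list(package = "ifpgrow",
       version = as.character(utils::packageVersion("ifpgrow")),
       seed = cfg$seed, config = unclass(cfg),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}
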