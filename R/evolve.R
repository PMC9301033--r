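# The generational fragment-growing loop: fragment-attachment mutation,
# BRICS-style crossover, elitist selection. Operators are deterministic
# under the run seed and work on implicit-hydrogen topology records.

is_skip <- function(x) inherits(x, "skip_signal")

skip_signal <- function(reason) structure(list(reason = reason),
                                          class = "skip_signal")

# Heavy atoms able to accept one more single bond (>= 1 hydrogen, implicit
# or explicit).
attachment_points <- function(mol) {
  imph <- implicit_h(mol)
  nb <- neighbors(mol)
  expl <- vapply(seq_len(nrow(mol$atoms)), function(i)
    sum(mol$atoms$elem[nb[[i]]] == "H"), integer(1))
  which(mol$atoms$elem != "H" & (imph + expl) >= 1)
}

# Join two topologies with a single bond between atom ai of a and atom bi
# of b, consuming one hydrogen on each side (an explicit one if present).
join_molecules <- function(a, ai, b, bi, name = paste0(a$name, "+", b$name)) {
  drop_h <- function(mol, at) {
    nb <- neighbors(mol)
    hs <- nb[[at]][mol$atoms$elem[nb[[at]]] == "H"]
    if (implicit_h(mol)[at] >= 1 || !length(hs)) return(list(mol = mol, at = at))
    keep <- setdiff(seq_len(nrow(mol$atoms)), hs[1])
    remap <- match(seq_len(nrow(mol$atoms)), keep)
    bonds <- mol$bonds[mol$bonds$a1 != hs[1] & mol$bonds$a2 != hs[1], ,
                       drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    list(mol = mol_record(mol$name, mol$atoms[keep, , drop = FALSE], bonds),
         at = remap[at])
  }
  da <- drop_h(a, ai); db <- drop_h(b, bi)
  na <- nrow(da$mol$atoms)
  atoms <- rbind(da$mol$atoms, db$mol$atoms)
  bonds <- rbind(da$mol$bonds,
                 data.frame(a1 = db$mol$bonds$a1 + na,
                            a2 = db$mol$bonds$a2 + na,
                            order = db$mol$bonds$order),
                 data.frame(a1 = da$at, a2 = db$at + na, order = 1))
  rownames(atoms) <- NULL
  mol_record(name, atoms, bonds, has3d = FALSE)
}

#' Grow a molecule by attaching a library fragment
#'
#' The mutation operator: one fragment from the library is attached to the
#' parent by a single bond at a randomly drawn hydrogen-bearing heavy atom
#' on each side (randomness comes from the caller's RNG state). Returns a
#' skip signal when the parent has no attachment point, exceeds the
#' heavy-atom cap, or every drawn combination reproduces the parent.
#'
#' @param parent a `mol_record`.
#' @param fragment_library non-empty list of `mol_record`s.
#' @param max_heavy optional heavy-atom cap for the parent.
#' @param max_tries attachment draws before giving up.
#' @return a child `mol_record` with canonical SMILES, or a skip signal
#'   (test with `is_skip`).
#' @export
mutate_molecule <- function(parent, fragment_library, max_heavy = NULL,
                            max_tries = 10) {
  if (!length(fragment_library)) stop("fragment library is empty")
  if (!is.null(max_heavy) && n_heavy(parent) >= max_heavy)
    return(skip_signal("max_heavy"))
  ap <- attachment_points(parent)
  if (!length(ap)) return(skip_signal("no_attachment_point"))
  p_smi <- if (!is.null(parent$smiles)) parent$smiles
           else ob_canonical_smiles(parent)
  for (try in seq_len(max_tries)) {
    frag <- fragment_library[[sample.int(length(fragment_library), 1)]]
    fap <- attachment_points(frag)
    if (!length(fap)) next
    ai <- ap[sample.int(length(ap), 1)]
    bi <- fap[sample.int(length(fap), 1)]
    child <- join_molecules(parent, ai, frag, bi)
    smi <- tryCatch(ob_canonical_smiles(child), error = function(e) NULL)
    if (is.null(smi) || identical(smi, p_smi)) next
    child$smiles <- smi
    child$props$parent <- parent$name
    return(child)
  }
  skip_signal("no_productive_attachment")
}

# All distinct children from attaching `fragment` to `parent` over every
# (parent atom, fragment atom) pair -- the exhaustive oracle for the
# mutation operator.
enumerate_attachments <- function(parent, fragment) {
  out <- character(0)
  for (ai in attachment_points(parent))
    for (bi in attachment_points(fragment)) {
      smi <- tryCatch(
        ob_canonical_smiles(join_molecules(parent, ai, fragment, bi)),
        error = function(e) NULL)
      if (!is.null(smi)) out <- c(out, smi)
    }
  unique(out)
}

# BRICS-style cleavable bonds: acyclic single bonds between two heavy
# atoms where at least one end is a ring atom, a heteroatom, or adjacent
# to a heteroatom (a reduced synthetic-feasibility rule set).
cleavable_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(integer(0))
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  is_bridge <- seq_len(nrow(mol$bonds)) %in% as.integer(igraph::bridges(g))
  nb <- neighbors(mol)
  elem <- mol$atoms$elem
  near_het <- function(i) !elem[i] %in% c("C", "H") ||
    any(!elem[nb[[i]]] %in% c("C", "H"))
  ring_atom <- rep(FALSE, nrow(mol$atoms))
  for (k in which(!is_bridge)) {
    ring_atom[mol$bonds$a1[k]] <- TRUE
    ring_atom[mol$bonds$a2[k]] <- TRUE
  }
  keep <- integer(0)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (mol$bonds$order[k] != 1) next
    if (elem[a] == "H" || elem[b] == "H") next
    if (!is_bridge[k]) next                   # ring bond: never cleaved
    if (!(ring_atom[a] || ring_atom[b] || near_het(a) || near_het(b))) next
    keep <- c(keep, k)
  }
  keep
}

# Split a molecule on bond k; returns the two fragments with their
# attachment atoms (indices into each fragment's atom table).
split_on_bond <- function(mol, k) {
  a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
  bonds <- mol$bonds[-k, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  comp <- igraph::components(g)$membership
  mk <- function(at) {
    keep <- which(comp == comp[at])
    remap <- match(seq_len(nrow(mol$atoms)), keep)
    bb <- bonds[bonds$a1 %in% keep & bonds$a2 %in% keep, , drop = FALSE]
    bb$a1 <- remap[bb$a1]; bb$a2 <- remap[bb$a2]
    atoms <- mol$atoms[keep, , drop = FALSE]; rownames(atoms) <- NULL
    list(mol = mol_record(paste0(mol$name, "_frag"), atoms, bb,
                          has3d = FALSE),
         at = remap[at])
  }
  list(mk(a), mk(b))
}

#' Recombine two molecules at BRICS-style cut points
#'
#' The crossover operator: each parent is cleaved at one randomly drawn
#' cleavable bond, one fragment of each parent is drawn, and the two
#' fragments are joined by a single bond at the cut atoms. Skip signals
#' are returned when a parent has no cleavable bond.
#'
#' @param a,b parent `mol_record`s.
#' @return a child `mol_record` with canonical SMILES, or a skip signal.
#' @export
crossover_molecules <- function(a, b) {
  ca <- cleavable_bonds(a); cb <- cleavable_bonds(b)
  if (!length(ca) || !length(cb)) return(skip_signal("no_cleavable_bond"))
  fa <- split_on_bond(a, ca[sample.int(length(ca), 1)])
  fb <- split_on_bond(b, cb[sample.int(length(cb), 1)])
  pa <- fa[[sample.int(2, 1)]]
  pb <- fb[[sample.int(2, 1)]]
  child <- mol_record(paste0(a$name, "x", b$name),
                      rbind(pa$mol$atoms, pb$mol$atoms),
                      rbind(pa$mol$bonds,
                            data.frame(a1 = pb$mol$bonds$a1 + nrow(pa$mol$atoms),
                                       a2 = pb$mol$bonds$a2 + nrow(pa$mol$atoms),
                                       order = pb$mol$bonds$order),
                            data.frame(a1 = pa$at,
                                       a2 = pb$at + nrow(pa$mol$atoms),
                                       order = 1)),
                      has3d = FALSE)
  smi <- tryCatch(ob_canonical_smiles(child), error = function(e) NULL)
  if (is.null(smi)) return(skip_signal("recombination_failed"))
  child$smiles <- smi
  child$props$parents <- c(a$name, b$name)
  child
}

# Exhaustive recombinant enumeration (test oracle for crossover).
enumerate_recombinants <- function(a, b) {
  out <- character(0)
  for (ka in cleavable_bonds(a)) for (kb in cleavable_bonds(b)) {
    fa <- split_on_bond(a, ka); fb <- split_on_bond(b, kb)
    for (pa in fa) for (pb in fb) {
      child <- mol_record("x", rbind(pa$mol$atoms, pb$mol$atoms),
                          rbind(pa$mol$bonds,
                                data.frame(a1 = pb$mol$bonds$a1 + nrow(pa$mol$atoms),
                                           a2 = pb$mol$bonds$a2 + nrow(pa$mol$atoms),
                                           order = pb$mol$bonds$order),
                                data.frame(a1 = pa$at,
                                           a2 = pb$at + nrow(pa$mol$atoms),
                                           order = 1)),
                          has3d = FALSE)
      smi <- tryCatch(ob_canonical_smiles(child), error = function(e) NULL)
      if (!is.null(smi)) out <- c(out, smi)
    }
  }
  unique(out)
}

#' Select the fittest members of a generation
#'
#' Keeps the `k` most negative scores; ties are broken by lexicographic
#' canonical SMILES so selection is fully deterministic.
#'
#' @param members data.frame with `score` and `smiles` columns.
#' @param k number of survivors (<= nrow(members)).
#' @return the selected rows, best first.
#' @export
select_survivors <- function(members, k) {
  if (k > nrow(members))
    stop("cannot select ", k, " survivors from ", nrow(members), " members")
  ord <- order(members$score, members$smiles)
  members[ord[seq_len(k)], , drop = FALSE]
}

# Score one molecule: best (most negative) pose score over the provider's
# poses. Returns list(score, pose) or NULL on failure.
score_member <- function(mol, provider, scorer, receptor, pose_seed) {
  poses <- tryCatch(provider$propose(mol, receptor, seed = pose_seed),
                    error = function(e) NULL)
  if (is.null(poses) || !length(poses)) return(NULL)
  scores <- vapply(poses, function(p)
    tryCatch(scorer(p), error = function(e) NA_real_), numeric(1))
  if (all(is.na(scores))) return(NULL)
  best <- which.min(scores)
  list(score = scores[best], pose = poses[[best]])
}

#' Run the generational fragment-growing loop
#'
#' Generation 0 scores the seed molecules; each later generation is built
#' from the previous generation's survivors by mutation and crossover,
#' plus elites carried unchanged. Duplicate children (by canonical SMILES)
#' within a generation are collapsed keeping the first. Members whose
#' posing or scoring fails are dropped with a message; the run stops early
#' if a generation produces nothing but skip signals.
#'
#' @param config a `run_config` (see [default_config()]); uses
#'   `generations`, `n_mutants`, `n_crossovers`, `n_elites`,
#'   `n_survivors`, `max_heavy` and `seed`.
#' @param seeds non-empty list of seed `mol_record`s.
#' @param provider a pose provider, e.g. [toy_pose_provider()].
#' @param scorer pose-scoring function, e.g. [make_ifpcs_scorer()].
#' @param fragment_library fragment library for mutation; defaults to the
#'   seeds.
#' @param receptor optional receptor passed through to the provider.
#' @return an `evolution_run`: list of per-generation data.frames (`name`,
#'   `smiles`, `score`, `lineage`, `parents`, with best poses in attribute
#'   `poses`), plus config and provenance.
#' @export
run_evolution <- function(config, seeds, provider, scorer,
                          fragment_library = seeds, receptor = NULL) {
  if (!length(seeds)) stop("seeds must be non-empty")
  cfg <- validate_config(config)
  gens <- vector("list", cfg$generations + 1L)

  make_record <- function(gen, names, smiles, scores, lineage, parents,
                          poses) {
    df <- data.frame(generation = gen, name = names, smiles = smiles,
                     score = scores, lineage = lineage, parents = parents,
                     stringsAsFactors = FALSE)
    attr(df, "poses") <- poses
    class(df) <- c("generation_record", "data.frame")
    df
  }

  score_all <- function(mols, gen) {
    # batch-embed conformers up front (one helper invocation per generation)
    need <- which(!vapply(mols, has_conformer, logical(1)))
    if (length(need)) {
      smis <- vapply(mols[need], function(m)
        if (!is.null(m$smiles)) m$smiles else ob_canonical_smiles(m),
        character(1))
      emb <- embed_smiles(smis, vapply(mols[need], `[[`, character(1),
                                       "name"), strict = FALSE)
      for (j in seq_along(need)) {
        if (!is.null(emb[[j]])) {
          emb[[j]]$smiles <- smis[j]
          mols[[need[j]]] <- emb[[j]]
        }
      }
    }
    res <- vector("list", length(mols))
    for (j in seq_along(mols)) {
      ps <- (cfg$seed + 7919L * gen + j) %% .Machine$integer.max
      res[[j]] <- score_member(mols[[j]], provider, scorer, receptor, ps)
      if (is.null(res[[j]]))
        message("dropping member '", mols[[j]]$name,
                "' (posing or scoring failed)")
    }
    res
  }

  # generation 0: seeds
  seeds <- lapply(seq_along(seeds), function(j) {
    m <- seeds[[j]]
    if (is.null(m$smiles)) m$smiles <- ob_canonical_smiles(m)
    if (!nzchar(m$name) || m$name == m$smiles) m$name <- paste0("seed", j)
    m
  })
  sc <- score_all(seeds, 0L)
  keep <- !vapply(sc, is.null, logical(1))
  if (!any(keep)) stop("generation 0 is empty: no seed could be scored")
  gens[[1]] <- make_record(0L,
    vapply(seeds[keep], `[[`, character(1), "name"),
    vapply(seeds[keep], `[[`, character(1), "smiles"),
    vapply(sc[keep], `[[`, numeric(1), "score"),
    "seed", "", lapply(sc[keep], `[[`, "pose"))
  topo_cache <- seeds[keep]
  names(topo_cache) <- vapply(topo_cache, `[[`, character(1), "name")

  if (cfg$generations == 0L)
    return(structure(list(generations = gens[1], config = cfg,
                          provenance = provenance(cfg)),
                     class = "evolution_run"))

  with_seed(cfg$seed, {
    for (gen in seq_len(cfg$generations)) {
      prev <- gens[[gen]]
      surv <- select_survivors(prev, min(cfg$n_survivors, nrow(prev)))
      parents <- topo_cache[surv$name]
      children <- list(); child_info <- list(); n_skips <- 0L
      n_ops <- 0L
      for (j in seq_len(cfg$n_mutants)) {
        n_ops <- n_ops + 1L
        p <- parents[[sample.int(length(parents), 1)]]
        ch <- mutate_molecule(p, fragment_library, max_heavy = cfg$max_heavy)
        if (is_skip(ch)) { n_skips <- n_skips + 1L; next }
        ch$name <- sprintf("g%d_mut%d", gen, j)
        children[[length(children) + 1L]] <- ch
        child_info[[length(child_info) + 1L]] <-
          list(lineage = "mutant", parents = p$name)
      }
      for (j in seq_len(cfg$n_crossovers)) {
        n_ops <- n_ops + 1L
        ij <- if (length(parents) >= 2) sample.int(length(parents), 2)
              else c(1L, 1L)
        ch <- crossover_molecules(parents[[ij[1]]], parents[[ij[2]]])
        if (is_skip(ch)) { n_skips <- n_skips + 1L; next }
        ch$name <- sprintf("g%d_x%d", gen, j)
        children[[length(children) + 1L]] <- ch
        child_info[[length(child_info) + 1L]] <-
          list(lineage = "crossover",
               parents = paste(parents[[ij[1]]]$name,
                               parents[[ij[2]]]$name, sep = "|"))
      }
      if (n_ops > 0L && n_skips == n_ops) {
        message("early termination at generation ", gen,
                ": all operators returned skip signals")
        gens <- gens[seq_len(gen)]
        break
      }
      # collapse duplicates (elites first, then children in order)
      elite_n <- min(cfg$n_elites, nrow(surv))
      seen <- surv$smiles[seq_len(elite_n)]
      keep_child <- logical(length(children))
      for (j in seq_along(children)) {
        if (!children[[j]]$smiles %in% seen) {
          keep_child[j] <- TRUE
          seen <- c(seen, children[[j]]$smiles)
        }
      }
      children <- children[keep_child]
      child_info <- child_info[keep_child]
      sc <- score_all(children, gen)
      ok <- !vapply(sc, is.null, logical(1))
      names <- c(surv$name[seq_len(elite_n)],
                 vapply(children[ok], `[[`, character(1), "name"))
      smiles <- c(surv$smiles[seq_len(elite_n)],
                  vapply(children[ok], `[[`, character(1), "smiles"))
      scores <- c(surv$score[seq_len(elite_n)],
                  vapply(sc[ok], `[[`, numeric(1), "score"))
      lineage <- c(rep("elite", elite_n),
                   vapply(child_info[ok], `[[`, character(1), "lineage"))
      par_tag <- c(rep("", elite_n),
                   vapply(child_info[ok], `[[`, character(1), "parents"))
      elite_poses <- attr(prev, "poses")[match(surv$name[seq_len(elite_n)],
                                               prev$name)]
      poses <- c(elite_poses, lapply(sc[ok], `[[`, "pose"))
      if (!length(names)) stop("generation ", gen, " is empty")
      gens[[gen + 1L]] <- make_record(gen, names, smiles, scores, lineage,
                                      par_tag, poses)
      for (m in children[ok]) topo_cache[[m$name]] <- m
    }
  })
  gens <- gens[!vapply(gens, is.null, logical(1))]
  structure(list(generations = gens, config = cfg,
                 provenance = provenance(cfg)),
            class = "evolution_run")
}

#' @export
print.evolution_run <- function(x, ...) {
  cat("<evolution_run> ", length(x$generations), " generation(s), seed ",
      x$config$seed, "\n", sep = "")
  for (g in x$generations)
    cat(sprintf("  gen %d: %d members, best %.4f, mean %.4f\n",
                g$generation[1], nrow(g), min(g$score), mean(g$score)))
  invisible(x)
}

#' Write run artifacts (per-generation SDF + CSV, JSON manifest)
#' @param run an `evolution_run`.
#' @param dir output directory (created if needed).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in run$generations) {
    gen <- g$generation[1]
    utils::write.csv(as.data.frame(g)[, c("name", "smiles", "score",
                                          "lineage", "parents")],
                     file.path(dir, sprintf("generation_%03d.csv", gen)),
                     row.names = FALSE)
    poses <- attr(g, "poses")
    if (length(poses))
      write_molecules(poses, file.path(dir, sprintf("generation_%03d.sdf",
                                                    gen)))
  }
  jsonlite::write_json(run$provenance, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
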