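test_that("mutation children come from the exhaustive attachment set", {
  benz <- smiles_mol("c1ccccc1", "benzene")
  methane <- smiles_mol("C", "methane")
  all_children <- ifpgrow:::enumerate_attachments(benz, methane)
  expect_identical(all_children, "Cc1ccccc1")   # only toluene is reachable
  set.seed(1)
  child <- mutate_molecule(benz, list(methane))
  expect_false(ifpgrow:::is_skip(child))
  expect_true(child$smiles %in% all_children)
})

test_that("mutation respects the heavy-atom cap and determinism", {
  benz <- smiles_mol("c1ccccc1", "benzene")
  methane <- smiles_mol("C", "methane")
  expect_true(ifpgrow:::is_skip(
    mutate_molecule(benz, list(methane), max_heavy = 6)))
  set.seed(5); c1 <- mutate_molecule(benz, list(smiles_mol("CCO", "ethanol")))
  set.seed(5); c2 <- mutate_molecule(benz, list(smiles_mol("CCO", "ethanol")))
  expect_identical(c1$smiles, c2$smiles)
})

test_that("crossover recombines fragments or signals a skip", {
  benz <- smiles_mol("c1ccccc1", "benzene")
  expect_true(ifpgrow:::is_skip(crossover_molecules(benz, benz)))

  tol <- smiles_mol("Cc1ccccc1", "toluene")
  anis <- smiles_mol("COc1ccccc1", "anisole")
  pool <- ifpgrow:::enumerate_recombinants(tol, anis)
  expect_gt(length(pool), 0)
  set.seed(3)
  for (i in 1:5) {
    ch <- crossover_molecules(tol, anis)
    expect_false(ifpgrow:::is_skip(ch))
    expect_true(ch$smiles %in% pool)
  }
})

test_that("a single compatible junction yields the unique recombinant", {
  # ethylbenzene cleaves only at the ring--CH2 junction under the rule set
  # (the terminal ethyl C-C bond has no ring or heteroatom context)
  eb <- smiles_mol("CCc1ccccc1", "ethylbenzene")
  expect_length(ifpgrow:::cleavable_bonds(eb), 1)
  pool <- ifpgrow:::enumerate_recombinants(eb, eb)
  # fragments: ethyl/phenyl x ethyl/phenyl joined pairwise
  expect_setequal(pool, c("CCCC", "CCc1ccccc1", "c1ccc(cc1)c1ccccc1"))
})

test_that("selection keeps the most negative scores with SMILES tie-break", {
  m <- data.frame(score = c(-0.9, -0.2, -0.5), smiles = c("A", "B", "C"))
  sel <- select_survivors(m, 2)
  expect_equal(sel$score, c(-0.9, -0.5))
  ties <- data.frame(score = c(-0.5, -0.5, -0.5), smiles = c("c", "a", "b"))
  expect_equal(select_survivors(ties, 1)$smiles, "a")
  expect_equal(nrow(select_survivors(m, 3)), 3)
  expect_error(select_survivors(m, 4), "cannot select")
})

ga_setup <- function(n_frag = 8, seed = 23) {
  cx <- mk_complex(c(0, 1, 2, 3, 4))
  fp <- reference_fingerprint(cx$receptor, cx$ligand)
  cfg <- default_config()
  cfg$generations <- 3L; cfg$n_mutants <- 5L; cfg$n_crossovers <- 3L
  cfg$n_elites <- 2L; cfg$n_survivors <- 4L; cfg$seed <- seed
  list(cx = cx, fp = fp, cfg = cfg,
       lib = make_fragment_library(n_frag, seed = seed),
       provider = toy_pose_provider(cx$ligand, n = 2, jitter_sigma = 0.3),
       scorer = make_ifpcs_scorer(cx$receptor, fp))
}

test_that("a zero-generation run returns only the scored seeds", {
  s <- ga_setup()
  s$cfg$generations <- 0L
  run <- suppressMessages(run_evolution(s$cfg, s$lib, s$provider, s$scorer))
  expect_length(run$generations, 1)
  expect_true(all(run$generations[[1]]$lineage == "seed"))
  expect_true(all(is.finite(run$generations[[1]]$score)))
})

test_that("elitism makes the best score non-worsening across generations", {
  s <- ga_setup()
  run <- suppressMessages(run_evolution(s$cfg, s$lib, s$provider, s$scorer))
  best <- vapply(run$generations, function(g) min(g$score), numeric(1))
  expect_gte(length(best), 4)
  expect_true(all(diff(best) <= 1e-12))
})

test_that("runs are reproducible from (config, seed)", {
  s <- ga_setup(n_frag = 6, seed = 31)
  r1 <- suppressMessages(run_evolution(s$cfg, s$lib, s$provider, s$scorer))
  r2 <- suppressMessages(run_evolution(s$cfg, s$lib, s$provider, s$scorer))
  expect_length(r1$generations, length(r2$generations))
  for (k in seq_along(r1$generations))
    expect_identical(as.data.frame(r1$generations[[k]]),
                     as.data.frame(r2$generations[[k]]))
})

test_that("generation records carry unique names, lineage and poses", {
  s <- ga_setup()
  run <- suppressMessages(run_evolution(s$cfg, s$lib, s$provider, s$scorer))
  for (g in run$generations) {
    expect_false(anyDuplicated(g$name) > 0)
    expect_false(anyDuplicated(g$smiles) > 0)  # duplicates collapsed
    expect_true(all(g$lineage %in% c("seed", "elite", "mutant", "crossover")))
    expect_length(attr(g, "poses"), nrow(g))
  }
  # every non-seed generation contains its elites
  for (g in run$generations[-1])
    expect_gte(sum(g$lineage == "elite"), 1)
})

test_that("run artifacts are written to disk", {
  s <- ga_setup()
  s$cfg$generations <- 1L
  run <- suppressMessages(run_evolution(s$cfg, s$lib, s$provider, s$scorer))
  d <- withr::local_tempdir()
  write_run(run, d)
  expect_true(file.exists(file.path(d, "generation_000.csv")))
  expect_true(file.exists(file.path(d, "generation_000.sdf")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  man <- jsonlite::fromJSON(file.path(d, "manifest.json"))
  expect_equal(man$seed, s$cfg$seed)
})
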