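test_that("molecular weights match standard atomic weights", {
  expect_equal(molecular_weight(smiles_mol("c1ccccc1", "benzene")), 78.11,
               tolerance = 0.01 / 78)
  expect_equal(molecular_weight(smiles_mol("O", "water")), 18.02,
               tolerance = 0.01 / 18)
  expect_equal(molecular_weight(smiles_mol("CC(=O)[O-]", "acetate")), 59.04,
               tolerance = 0.001)
})

test_that("the fragment library honors the 100-150 Da gate and the seed", {
  lib <- make_fragment_library(50, seed = 17)
  expect_length(lib, 50)
  mw <- vapply(lib, molecular_weight, numeric(1))
  expect_true(all(mw >= 100 & mw <= 150))
  lib2 <- make_fragment_library(50, seed = 17)
  expect_identical(lapply(lib, `[[`, "smiles"), lapply(lib2, `[[`, "smiles"))
  # every fragment carries a valid canonical SMILES
  for (m in lib[1:10])
    expect_identical(ifpgrow:::canonicalize_smiles(m$smiles), m$smiles)
})

# A miniature run whose combos are injected so the arithmetic is exact.
# The first member's pose is the fixture ligand (passes a model built from
# its own complex) unless `all_fail`; the rest sit 30 A away and fail.
fake_run <- function(combos_per_gen, all_fail = FALSE) {
  cx <- mk_complex(c(3, 4, 1, 1))
  gens <- lapply(seq_along(combos_per_gen), function(gi) {
    n <- length(combos_per_gen[[gi]])
    df <- data.frame(generation = gi - 1L, name = paste0("m", seq_len(n)),
                     smiles = "c1ccccc1", score = -0.5,
                     lineage = "seed", parents = "")
    poses <- replicate(n, translate(cx$ligand, c(30, 0, 0)),
                       simplify = FALSE)
    if (!all_fail) poses[[1]] <- cx$ligand
    attr(df, "poses") <- poses
    class(df) <- c("generation_record", "data.frame")
    df
  })
  list(run = structure(list(generations = gens), class = "evolution_run"),
       cx = cx)
}

test_that("enrichment fractions use the whole population", {
  fr <- fake_run(list(c(0.4, 0.6, 0.8, 1.2)))
  model <- build_pharmacophore(list(list(receptor = fr$cx$receptor,
                                         ligand = fr$cx$ligand)))
  gm <- generation_metrics(fr$run, model, combos = list(c(0.4, 0.6, 0.8, 1.2)))
  expect_equal(gm$frac_ge_0.75, 0.5)    # 2 of 4
  expect_equal(gm$frac_ge_0.50, 0.75)
  expect_equal(gm$frac_ge_1.00, 0.25)
  expect_equal(gm$n_pass, 1L)
  expect_false(is.na(gm$mean_mw_pass))
})

test_that("mean MW of passers is NA, not zero, when nothing passes", {
  fr <- fake_run(list(c(0.2, 0.3)), all_fail = TRUE)
  model <- build_pharmacophore(list(list(receptor = fr$cx$receptor,
                                         ligand = fr$cx$ligand)))
  gm <- generation_metrics(fr$run, model, combos = list(c(0.2, 0.3)))
  expect_equal(gm$n_pass, 0L)
  expect_true(is.na(gm$mean_mw_pass))
})

test_that("enrichment fractions are nested across thresholds", {
  set.seed(31)
  combos <- lapply(1:4, function(i) runif(8, 0, 2))
  fr <- fake_run(combos)
  model <- build_pharmacophore(list(list(receptor = fr$cx$receptor,
                                         ligand = fr$cx$ligand)))
  gm <- generation_metrics(fr$run, model, combos = combos)
  for (k in seq_len(nrow(gm))) {
    expect_lte(gm$frac_ge_0.75[k], gm$frac_ge_0.50[k])
    expect_lte(gm$frac_ge_1.00[k], gm$frac_ge_0.75[k])
  }
})

test_that("combo histograms bin on the 0-2 scale", {
  h <- combo_histogram(c(0.05, 0.15, 0.17, 1.95))
  expect_equal(sum(h$count), 4)
  expect_equal(h$count[h$bin_lo == 0.1], 2)
  expect_equal(nrow(h), 20)
})
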