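test_that("receptor reading defines residue indexing from file order", {
  pdb <- minimal_pdb(withr::local_tempfile(fileext = ".pdb"))
  rec <- read_receptor(pdb)
  expect_s3_class(rec, "receptor_structure")
  expect_equal(n_residues(rec), 2L)
  expect_equal(vapply(rec$residues, `[[`, character(1), "resname"),
               c("ALA", "GLY"))
  # determinism: same file read twice gives identical ordering
  rec2 <- read_receptor(pdb)
  expect_identical(lapply(rec$residues, `[`, c("chain", "resno", "icode")),
                   lapply(rec2$residues, `[`, c("chain", "resno", "icode")))
})

test_that("waters and other heteroatoms are excluded from the polymer", {
  pdb <- minimal_pdb(withr::local_tempfile(fileext = ".pdb"),
                     with_water = TRUE)
  rec <- read_receptor(pdb)
  expect_equal(n_residues(rec), 1L)
  expect_equal(nrow(rec$het), 1L)
  expect_equal(rec$het$resname, "HOH")
})

test_that("receptor reading rejects missing files and duplicate keys", {
  expect_error(read_receptor(file.path(tempdir(), "nope.pdb")), "cannot read")
  dup <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  N   GLY A   2       3.000   0.000   0.000  1.00  0.00           N",
    "ATOM      3  CA  ALA A   1       1.450   0.000   0.000  1.00  0.00           C",
    "END"), dup)
  expect_error(read_receptor(dup), "duplicate residue key")
})

test_that("fixture receptors round-trip through PDB unchanged", {
  cx <- mk_complex(c(3, 1))
  d <- withr::local_tempdir()
  paths <- write_fixture(cx, d)
  rec <- read_receptor(paths[["receptor"]])
  expect_equal(n_residues(rec), n_residues(cx$receptor))
  for (i in seq_along(rec$residues)) {
    expect_equal(rec$residues[[i]]$resname, cx$receptor$residues[[i]]$resname)
    expect_equal(as.matrix(rec$residues[[i]]$atoms[, c("x", "y", "z")]),
                 as.matrix(cx$receptor$residues[[i]]$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("SMILES files are read with invalid entries skipped and counted", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "C1CC broken"), f)
  expect_warning(mols <- read_molecules(f), "1 invalid entry")
  expect_length(mols, 1)
  expect_equal(attr(mols, "n_skipped"), 1L)
  expect_equal(mols[[1]]$name, "benzene")
  expect_equal(sum(mols[[1]]$atoms$elem != "H"), 6L)
})

test_that("molecule records round-trip through SDF", {
  cx <- mk_complex(c(3, 4, 5))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(cx$ligand, f)
  back <- read_molecules(f)[[1]]
  expect_equal(nrow(back$atoms), nrow(cx$ligand$atoms))
  expect_equal(back$bonds$order, cx$ligand$bonds$order)
  expect_equal(back$atoms$charge, cx$ligand$atoms$charge)  # M CHG preserved
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(cx$ligand$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # topology survives canonicalization round trip
  expect_identical(ifpgrow:::ob_canonical_smiles(back),
                   ifpgrow:::ob_canonical_smiles(cx$ligand))
})

test_that("empty molecule sets are an error", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines("C1CC broken", f)
  expect_error(suppressWarnings(read_molecules(f)), "no usable molecules")
  expect_error(read_molecules(withr::local_tempfile(fileext = ".xyz")),
               "cannot read|unrecognized")
})

test_that("run configurations load with defaults, warnings and validation", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"mode":"de_novo","generations":30,"seed":12}', f)
  cfg <- load_config(f)
  expect_equal(cfg$generations, 30L)
  expect_equal(cfg$mode, "de_novo")
  expect_equal(cfg$n_survivors, default_config()$n_survivors)

  writeLines('{"mode":"lead_opt","generations":5}', f)
  expect_equal(load_config(f)$generations, 5L)

  writeLines('{"generations":-1}', f)
  expect_error(load_config(f), "generations")

  writeLines('{"generations":2,"not_a_key":1}', f)
  expect_warning(load_config(f), "unknown config key")

  writeLines('{"mode":"bogus"}', f)
  expect_error(suppressWarnings(load_config(f)), "mode")
})
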