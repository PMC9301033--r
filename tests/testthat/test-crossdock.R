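# Brute-force benzene automorphisms: 6 rotations x 2 reflections of the
# cycle, the independent oracle for symmetry-corrected RMSD.
benzene_perms <- function() {
  out <- list()
  for (s in 0:5) {
    out[[length(out) + 1L]] <- ((0:5 + s) %% 6) + 1
    out[[length(out) + 1L]] <- ((s - 0:5) %% 6) + 1
  }
  out
}

test_that("heavy-atom RMSD handles identity, translation and symmetry", {
  b <- benzene_conf()
  expect_equal(heavy_atom_rmsd(b, b), 0)
  expect_equal(heavy_atom_rmsd(b, translate(b, c(3, 0, 0))), 3.0)
  rot <- rotate_z(b, 60)
  expect_gt(heavy_atom_rmsd(b, rot, symmetry = FALSE), 1)
  expect_equal(heavy_atom_rmsd(b, rot, symmetry = TRUE), 0,
               tolerance = 1e-9)
})

test_that("the automorphism closure reproduces the brute-force oracle", {
  b <- benzene_conf()
  autos <- ifpgrow:::graph_automorphisms(b)
  expect_length(autos, 12)
  oracle <- benzene_perms()
  expect_setequal(vapply(autos, paste, character(1), collapse = ","),
                  vapply(oracle, paste, character(1), collapse = ","))
  # minimum over the oracle equals the implementation on a jittered pair
  set.seed(11)
  other <- rotate_z(b, 60)
  other$atoms$x <- other$atoms$x + rnorm(6, 0, 0.2)
  A <- as.matrix(b$atoms[, c("x", "y", "z")])
  B <- as.matrix(other$atoms[, c("x", "y", "z")])
  brute <- min(vapply(oracle, function(p)
    sqrt(mean(rowSums((A[p, ] - B)^2))), numeric(1)))
  expect_equal(heavy_atom_rmsd(b, other), brute, tolerance = 1e-12)
})

test_that("symmetry-corrected RMSD never exceeds the identity mapping", {
  set.seed(21)
  for (i in 1:10) {
    b <- benzene_conf()
    other <- rotate_z(b, sample(0:359, 1))
    other$atoms$x <- other$atoms$x + rnorm(6, 0, 0.5)
    other$atoms$y <- other$atoms$y + rnorm(6, 0, 0.5)
    expect_lte(heavy_atom_rmsd(b, other, symmetry = TRUE),
               heavy_atom_rmsd(b, other, symmetry = FALSE) + 1e-12)
  }
})

test_that("RMSD is invariant under joint rigid motion and checks topology", {
  b <- benzene_conf()
  set.seed(3)
  other <- translate(b, c(1, 2, 0))
  r0 <- heavy_atom_rmsd(b, other)
  R <- random_rotation(5); t <- c(-4, 2, 9)
  expect_equal(heavy_atom_rmsd(ifpgrow:::transform_mol(b, R, t),
                               ifpgrow:::transform_mol(other, R, t)),
               r0, tolerance = 1e-10)
  expect_error(heavy_atom_rmsd(b, smiles_mol("CCO")), "topology mismatch")
})

test_that("best-pose RMSD takes the minimum and flags missing cells", {
  b <- benzene_conf()
  poses <- list(translate(b, c(0.8, 0, 0)), translate(b, c(2.4, 0, 0)),
                translate(b, c(5.1, 0, 0)))
  expect_equal(best_pose_rmsd(poses, b), 0.8)
  expect_equal(best_pose_rmsd(poses[2], b), 2.4)
  expect_warning(v <- best_pose_rmsd(list(), b), "missing cell")
  expect_true(is.na(v))
})

test_that("success rates follow the strict 2 A rule with consensus means", {
  m <- rmsd_matrix(paste0("L", 1:4), "R1", "p",
                   values = c(1.0, 2.5, 0.5, 3.0))
  sr <- success_rate(m)
  expect_equal(sr$per_receptor$fraction, 0.5)   # 2 of 4 below 2.0

  m2 <- rmsd_matrix(paste0("L", 1:3), "R1", "p", values = c(0.5, 1.0, 1.9))
  expect_equal(success_rate(m2)$per_receptor$fraction, 1.0)

  # a boundary cell at exactly 2.0 fails (strictly below the threshold)
  m3 <- rmsd_matrix(paste0("L", 1:2), "R1", "p", values = c(2.0, 1.0))
  expect_equal(success_rate(m3)$per_receptor$fraction, 0.5)

  # consensus = mean over protocols: 40% and 60% -> 50%
  m4 <- rmsd_matrix(paste0("L", 1:5), "R1", c("gold", "plants"))
  m4[, 1, "gold"] <- c(1, 1, 3, 3, 3)
  m4[, 1, "plants"] <- c(1, 1, 1, 3, 3)
  sr4 <- success_rate(m4)
  expect_equal(sr4$consensus$consensus, 0.5)
})

test_that("success fractions are monotone non-decreasing in the threshold", {
  set.seed(13)
  m <- rmsd_matrix(paste0("L", 1:20), paste0("R", 1:3), "p",
                   values = runif(60, 0, 6))
  fr <- vapply(c(0.5, 1, 2, 3, 4, 6),
               function(t) mean(success_rate(m, t)$per_receptor$fraction),
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("receptors without usable cells are excluded from ranking", {
  m <- rmsd_matrix(paste0("L", 1:2), c("R1", "R2"), "p")
  m[, "R1", 1] <- c(1.0, 3.0)
  expect_warning(sr <- success_rate(m), "excluded")
  expect_true(is.na(sr$consensus$rank[sr$consensus$receptor == "R2"]))
  expect_equal(sr$consensus$rank[sr$consensus$receptor == "R1"], 1L)
})

test_that("job enumeration is a ligand-major Cartesian product", {
  expect_equal(nrow(job_matrix(paste0("L", 1:24), paste0("R", 1:24),
                               c("gold", "plants"))), 1152L)
  expect_equal(nrow(job_matrix("a", "b", "c")), 1L)
  jm <- job_matrix(c("l1", "l2"), c("r1", "r2", "r3"), "p")
  expect_equal(nrow(jm), 6L)
  expect_equal(jm$ligand, rep(c("l1", "l2"), each = 3))
  expect_equal(jm$receptor, rep(c("r1", "r2", "r3"), 2))
  expect_error(job_matrix(character(0), "r", "p"), "non-empty")
})

test_that("RMSD matrices round-trip losslessly through CSV", {
  set.seed(9)
  m <- rmsd_matrix(paste0("L", 1:5), paste0("R", 1:3), "gold",
                   values = round(runif(15, 0, 8), 6))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rmsd_csv(m, "gold", f)
  back <- read_rmsd_csv(f, "gold")
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
})
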