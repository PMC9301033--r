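no_contacts <- function()
  data.frame(residue = integer(0), channel = integer(0))

test_that("fingerprint length is 8 bits per residue with fixed indexing", {
  fp <- encode_fingerprint(no_contacts(), r = 5)
  expect_length(fp$bits, 40L)
  expect_true(all(fp$bits == 0L))

  fp2 <- encode_fingerprint(data.frame(residue = 1L, channel = 3L), r = 2)
  expect_length(fp2$bits, 16L)
  expect_equal(fp_sparse(fp2), 11L)          # bit 8*1 + 3
  expect_equal(sum(fp2$bits), 1L)

  expect_error(encode_fingerprint(data.frame(residue = 2L, channel = 0L),
                                  r = 2), "out of range")
})

test_that("fixture fingerprints have one bit per planted interaction", {
  cx <- mk_complex(c(0, 1, 2, 3, 4))
  fp <- reference_fingerprint(cx$receptor, cx$ligand)
  expect_equal(sum(fp$bits), nrow(cx$truth))
  expect_length(fp$bits, 8L * n_residues(cx$receptor))
  expect_setequal(fp_sparse(fp), 8L * cx$truth$residue + cx$truth$channel)
})

test_that("cosine similarity matches hand-computed values", {
  expect_equal(cosine_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(cosine_similarity(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(cosine_similarity(c(1, 0, 0, 0), c(0, 1, 1, 0)), 0.0)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)  # zero-vector rule
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "length mismatch")
})

test_that("ifp_cs spans [-1, 0] with the documented endpoints", {
  expect_equal(ifp_cs(c(1, 1, 0, 0), c(1, 0, 1, 0)), -0.5)
  expect_equal(ifp_cs(c(1, 0, 1), c(1, 0, 1)), -1.0)
  expect_equal(ifp_cs(c(1, 0, 0), c(0, 1, 0)), 0.0)
})

test_that("score bounds, self-score and permutation consistency hold on random fingerprints", {
  set.seed(42)
  for (i in 1:50) {
    r <- sample(2:20, 1)
    a <- fp_from_sparse(sample(0:(8 * r - 1), sample(1:10, 1)), r)
    b <- fp_from_sparse(sample(0:(8 * r - 1), sample(0:10, 1)), r)
    s <- ifp_cs(a, b)
    expect_gte(s, -1); expect_lte(s, 0)
    expect_equal(ifp_cs(a, a), -1)
    expect_equal(ifp_cs(a, b), ifp_cs(b, a))
    # relabeling residues identically in both fingerprints preserves score
    perm <- sample(r)
    relab <- function(fp) {
      idx <- fp_sparse(fp)
      fp_from_sparse(8L * (perm[idx %/% 8L + 1L] - 1L) + idx %% 8L, r)
    }
    expect_equal(ifp_cs(relab(a), relab(b)), s)
  }
})

test_that("sparse and dense representations are interconvertible bit-for-bit", {
  cx <- mk_complex(c(3, 4, 5))
  fp <- reference_fingerprint(cx$receptor, cx$ligand)
  expect_identical(fp_from_sparse(fp_sparse(fp), fp$r)$bits, fp$bits)
})

test_that("pose scoring is self-consistent and bounded", {
  cx <- mk_complex(c(0, 1, 2, 3, 4))
  fp <- reference_fingerprint(cx$receptor, cx$ligand)
  expect_equal(score_pose(cx$receptor, cx$ligand, fp), -1.0)
  expect_equal(score_pose(cx$receptor, translate(cx$ligand, c(50, 0, 0)), fp),
               0.0)
  jit <- cx$ligand
  set.seed(7)
  jit$atoms$x <- jit$atoms$x + rnorm(nrow(jit$atoms), 0, 0.1)
  jit$atoms$y <- jit$atoms$y + rnorm(nrow(jit$atoms), 0, 0.1)
  jit$atoms$z <- jit$atoms$z + rnorm(nrow(jit$atoms), 0, 0.1)
  s <- score_pose(cx$receptor, jit, fp)
  expect_gte(s, -1); expect_lte(s, 0)
  # regression baseline: a 0.1 A jitter keeps the full reference pattern
  expect_equal(s, -1.0)
})

test_that("scoring errors out on residue-count mismatch", {
  cx <- mk_complex(c(3, 4))
  other <- mk_complex(3)
  fp <- reference_fingerprint(cx$receptor, cx$ligand)
  expect_error(score_pose(other$receptor, other$ligand, fp),
               "residue count")
})
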